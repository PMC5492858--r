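test_that("per-frame operation counts follow the cost formulas", {
  unit <- gmm_flop_count(1, 1, 1)
  expect_equal(unlist(unit), c(subtractions = 1, multiplications = 3,
                               additions = 1, total = 5))
  hand <- gmm_flop_count(2, 3, 2)
  expect_equal(unlist(hand), c(subtractions = 12, multiplications = 42,
                               additions = 18, total = 72))
  full <- gmm_flop_count(20, 32, 13)
  expect_equal(full$total,
               full$subtractions + full$multiplications + full$additions)
  expect_error(gmm_flop_count(0, 1, 1), ">= 1")
})

test_that("operation counts are exactly linear in classes and mixtures", {
  base <- gmm_flop_count(5, 8, 13)$total
  expect_equal(gmm_flop_count(20, 8, 13)$total, 4 * base)
  expect_equal(gmm_flop_count(5, 32, 13)$total, 4 * base)
  expect_equal(gmm_flop_count(10, 16, 13)$total, 4 * base)
})

test_that("system throughput scales with sensors and frame rate", {
  expect_equal(system_flops(1, 1, 1), 1)
  expect_equal(system_flops(1000, 0.01, 5), 5e5)
  base <- system_flops(gmm_flop_count(5, 32, 13)$total, 0.015, 30)
  quad <- system_flops(gmm_flop_count(20, 32, 13)$total, 0.015, 30)
  expect_equal(quad, 4 * base)
  expect_error(system_flops(1, 0, 1), "hop_s")
})

test_that("sensor capacity follows the floor of hop over latency", {
  expect_equal(sensor_capacity(throughput_spec()), 30L)
  expect_equal(sensor_capacity(throughput_spec(clock_hz = 5e7)), 15L)
  # latency exactly equal to the hop supports exactly one stream
  expect_equal(sensor_capacity(throughput_spec(cycles_per_frame = 15e5,
                                               clock_hz = 1e8)), 1L)
  expect_warning(
    cap0 <- sensor_capacity(throughput_spec(cycles_per_frame = 16e5,
                                            clock_hz = 1e8)), "capacity 0")
  expect_equal(cap0, 0L)
  # monotonicity: more cycles never increases capacity, faster clock never
  # decreases it
  caps <- vapply(c(2e4, 4e4, 8e4, 16e4), function(cyc)
    sensor_capacity(throughput_spec(cycles_per_frame = cyc)), integer(1))
  expect_true(all(diff(caps) <= 0))
  clocks <- vapply(c(5e7, 1e8, 2e8), function(hz)
    sensor_capacity(throughput_spec(clock_hz = hz)), integer(1))
  expect_true(all(diff(clocks) >= 0))
})

test_that("device catalog and IP requirements load with validation", {
  cat7 <- load_device_catalog()
  expect_length(cat7, 7)
  expect_equal(unname(device_resources("XC7Z020")["dsp"]), 220)
  expect_equal(unname(device_resources("XC7Z020")["lut"]), 53200)
  expect_equal(unname(device_resources("XC7Z100")["lut"]), 277400)
  expect_error(device_resources("XC9Z999"), "unknown device")
  bad <- tempfile(fileext = ".json")
  writeLines('{"schema": "something-else"}', bad)
  expect_error(load_device_catalog(bad), "schema")

  ip <- ip_resource_requirements()
  expect_equal(unname(unclass(ip$total)), c(31, 73, 4489, 7677))
  expect_equal(ip$critical_path_cycles, 49156)
  expect_equal(nrow(ip$components), 7)
})

test_that("resource fit reproduces the printed device percentages", {
  ip <- ip_resource_requirements()$total
  cat7 <- load_device_catalog()
  f20 <- resource_fit(ip, device_resources("XC7Z020"), "XC7Z020")
  expect_equal(unname(f20$percent),
               c(14.09, 52.14, 8.44, 7.22))
  expect_true(f20$fits)
  f10 <- resource_fit(ip, device_resources("XC7Z010"), "XC7Z010")
  expect_gt(f10$percent["bram_blocks"], 100)
  expect_false(f10$fits)
  # boundary inclusive: an IP equal to the device exactly fits
  fb <- resource_fit(ip, ip, "exact")
  expect_equal(unname(fb$percent), rep(100, 4))
  expect_true(fb$fits)
  expect_error(resource_fit(ip, resource_table(0, 1, 1, 1)), "positive")

  # every published cell, at its printed precision, within 0.01
  printed <- list(
    XC7Z010 = c(38.75, 121.66, 25.5, 21.8),
    XC7Z015 = c(19.37, 76.84, 9.7, 8.3),
    XC7Z020 = c(14.09, 52.14, 8.4, 7.2),
    XC7Z030 = c(7.75, 27.5, 5.7, 4.9))
  for (dev in names(printed)) {
    raw <- 100 * unclass(ip) / unclass(device_resources(dev, cat7))
    for (i in 1:4) {
      decimals <- nchar(sub("^[0-9]*\\.?", "", as.character(printed[[dev]][i])))
      expect_lt(abs(round(raw[i], decimals) - printed[[dev]][i]), 0.011,
                label = sprintf("%s resource %d (got %.3f, printed %.2f)",
                                dev, i, raw[i], printed[[dev]][i]))
    }
  }
})

test_that("the budget report assembles the reference operating point", {
  rep <- budget_report()
  expect_equal(rep$ops_per_frame$total, 225920)
  expect_equal(rep$sensor_capacity, 30L)
  expect_equal(rep$system_flops, 451840000)
  expect_true(rep$resource_fit$fits)
  out <- capture.output(print(rep))
  expect_true(any(grepl("30 sensors", out)))
  expect_true(any(grepl("451,840,000", out)))
})
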