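#' Per-frame operation counts of the GMM scoring stage
#'
#' Evaluating `n` mixture likelihoods of `M` full-covariance Gaussians in
#' dimension `d` for one frame costs, per the precomputed-inverse scoring
#' scheme (|S| and S^-1 computed once at training time):
#' subtractions `n M d`, multiplications `n M (d^2 + d + 1)` and additions
#' `n M ((d-1)^2 + d)`. The count is exactly linear in both `n` and `M`.
#'
#' @param n Number of classes (species models).
#' @param M Mixture components per model.
#' @param d Feature dimension.
#' @return List with `subtractions`, `multiplications`, `additions`, `total`.
#' @export
gmm_flop_count <- function(n = 20, M = 32, d = 13) {
  if (any(c(n, M, d) < 1)) stop("n, M and d must all be >= 1")
  subtractions <- n * M * d
  multiplications <- n * M * (d^2 + d + 1)
  additions <- n * M * ((d - 1)^2 + d)
  list(subtractions = subtractions, multiplications = multiplications,
       additions = additions,
       total = subtractions + multiplications + additions)
}

#' System throughput in floating-point operations per second
#'
#' One frame decision costs `per_frame_ops`; a new frame arrives every
#' `hop_s` seconds from each of `n_sensors` sensors.
#'
#' @param per_frame_ops Operations per frame (e.g. `gmm_flop_count()$total`).
#' @param hop_s Frame hop in seconds (0.015 at 30 ms frames, 50% overlap).
#' @param n_sensors Number of sensors streaming concurrently.
#' @return Operations per second.
#' @export
system_flops <- function(per_frame_ops, hop_s, n_sensors) {
  if (hop_s <= 0) stop("hop_s must be positive")
  if (n_sensors < 1) stop("n_sensors must be >= 1")
  per_frame_ops * n_sensors / hop_s
}

#' Throughput specification of the feature-extraction engine
#'
#' @param frame_ms Analysis frame duration in ms (default 30).
#' @param overlap Fractional overlap (default 0.5); the hop is
#'   `frame_ms/1000 * (1 - overlap)`.
#' @param cycles_per_frame Clock cycles to process one frame (default 49156,
#'   the critical-path component of the feature-extraction IP).
#' @param clock_hz System clock in Hz (default 100 MHz).
#' @return A `throughput_spec` list including the derived `hop_s` and
#'   per-frame `latency_s`.
#' @export
throughput_spec <- function(frame_ms = 30, overlap = 0.5,
                            cycles_per_frame = 49156, clock_hz = 1e8) {
  if (cycles_per_frame <= 0 || clock_hz <= 0)
    stop("cycles_per_frame and clock_hz must be positive")
  hop_s <- frame_ms / 1000 * (1 - overlap)
  structure(list(frame_ms = frame_ms, overlap = overlap,
                 cycles_per_frame = cycles_per_frame, clock_hz = clock_hz,
                 hop_s = hop_s,
                 latency_s = cycles_per_frame / clock_hz),
            class = "throughput_spec")
}

#' Real-time sensor capacity
#'
#' Number of independent audio streams one engine can serve in real time:
#' `floor(hop_s / latency_s)` where `latency_s = cycles_per_frame /
#' clock_hz`. A partial sensor is no sensor, hence the floor; with the 49,156
#' cycle / 100 MHz / 15 ms-hop defaults the capacity is 30.
#'
#' @param ts A [throughput_spec()].
#' @return Integer sensor count (0, with a warning, if one frame takes longer
#'   than the hop).
#' @export
sensor_capacity <- function(ts = throughput_spec()) {
  stopifnot(inherits(ts, "throughput_spec"))
  if (ts$latency_s > ts$hop_s * (1 + 1e-12)) {
    warning("per-frame latency ", signif(ts$latency_s, 6),
            " s exceeds the hop ", ts$hop_s, " s: capacity 0")
    return(0L)
  }
  as.integer(floor(ts$hop_s / ts$latency_s + 1e-9))
}

#' FPGA resource table
#'
#' @param dsp DSP slices.
#' @param bram_blocks 36 Kb block-RAM blocks.
#' @param lut Look-up tables.
#' @param ff Flip-flops.
#' @return A named numeric vector of class `resource_table`.
#' @export
resource_table <- function(dsp, bram_blocks, lut, ff) {
  v <- c(dsp = dsp, bram_blocks = bram_blocks, lut = lut, ff = ff)
  if (any(v < 0)) stop("resource counts must be non-negative")
  structure(v, class = c("resource_table", "numeric"))
}

#' Resource-fit percentages of an IP on a device
#'
#' Percentage of each device resource the IP consumes, rounded half-even to
#' two decimals for reporting; `fits` is `TRUE` when every requirement is at
#' most the capacity (boundary inclusive), judged on the unrounded ratios.
#'
#' @param required A [resource_table()] of IP requirements.
#' @param device A [resource_table()] of device capacities (all positive).
#' @param device_name Optional device label carried into the result.
#' @return List with `device`, `percent` (named, 2 decimals), `fits`.
#' @export
resource_fit <- function(required, device, device_name = NULL) {
  req <- unclass(required)[c("dsp", "bram_blocks", "lut", "ff")]
  cap <- unclass(device)[c("dsp", "bram_blocks", "lut", "ff")]
  if (any(cap <= 0)) stop("device capacities must all be positive")
  list(device = device_name,
       percent = round(100 * req / cap, 2),
       fits = all(req <= cap))
}

#' Load a device catalog
#'
#' Reads a JSON catalog of FPGA device capacities (the Zynq-7000 family table
#' ships with the package).
#'
#' @param path Catalog path; default is the packaged Zynq-7000 table.
#' @return Named list of [resource_table()] objects.
#' @export
load_device_catalog <- function(path = system.file("extdata",
                                                   "zynq_devices.json",
                                                   package = "wasnbird")) {
  cat_json <- tryCatch(jsonlite::fromJSON(path),
                       error = function(e) stop("malformed device catalog: ",
                                                path))
  if (!identical(cat_json$schema, "wasnbird-device-catalog/1") ||
      is.null(cat_json$devices))
    stop("device catalog ", path, " does not match the expected schema")
  out <- lapply(cat_json$devices, function(dv) {
    if (!all(c("dsp", "bram_blocks", "lut", "ff") %in% names(dv)))
      stop("device entry missing resource fields in ", path)
    resource_table(dv$dsp, dv$bram_blocks, dv$lut, dv$ff)
  })
  out
}

#' Look up one device from a catalog
#'
#' @param name Device part number, e.g. `"XC7Z020"`.
#' @param catalog A catalog from [load_device_catalog()].
#' @return A [resource_table()].
#' @export
device_resources <- function(name, catalog = load_device_catalog()) {
  if (!name %in% names(catalog))
    stop("unknown device ", name, "; catalog holds: ",
         paste(names(catalog), collapse = ", "))
  catalog[[name]]
}

#' Resource requirements of the feature-extraction IP
#'
#' Packaged-IP totals and per-component figures. The component rows come from
#' blocks implemented separately for inspection and therefore do not sum to
#' the packaged total; fit computations use the total row.
#'
#' @return List with `total` (a [resource_table()]), `components` (data
#'   frame) and `critical_path_cycles`.
#' @export
ip_resource_requirements <- function() {
  path <- system.file("extdata", "mfcc_ip_resources.json",
                      package = "wasnbird")
  j <- jsonlite::fromJSON(path)
  comp <- do.call(rbind, lapply(names(j$components), function(nm) {
    cm <- j$components[[nm]]
    data.frame(component = nm,
               cycles = if (is.null(cm$cycles)) NA_real_ else cm$cycles,
               dsp = cm$dsp, bram_blocks = cm$bram_blocks, lut = cm$lut,
               ff = cm$ff, stringsAsFactors = FALSE)
  }))
  list(total = resource_table(j$total$dsp, j$total$bram_blocks, j$total$lut,
                              j$total$ff),
       components = comp,
       critical_path_cycles = j$critical_path_cycles)
}

#' Full deployment budget report
#'
#' Combines the per-frame operation counts, system throughput, real-time
#' sensor capacity and device resource fit into one report.
#'
#' @param n_classes,mixtures,dim GMM cost parameters (defaults 20/32/13).
#' @param n_sensors Sensors to budget for; `NULL` (default) uses the
#'   real-time capacity.
#' @param frame_ms,overlap,cycles_per_frame,clock_hz Throughput parameters,
#'   see [throughput_spec()].
#' @param device Device part number for the resource fit.
#' @param catalog Device catalog (default the packaged Zynq-7000 table).
#' @return A `budget_report` list.
#' @export
budget_report <- function(n_classes = 20, mixtures = 32, dim = 13,
                          n_sensors = NULL, frame_ms = 30, overlap = 0.5,
                          cycles_per_frame = 49156, clock_hz = 1e8,
                          device = "XC7Z020",
                          catalog = load_device_catalog()) {
  ops <- gmm_flop_count(n_classes, mixtures, dim)
  ts <- throughput_spec(frame_ms, overlap, cycles_per_frame, clock_hz)
  capacity <- sensor_capacity(ts)
  if (is.null(n_sensors)) n_sensors <- capacity
  fit <- resource_fit(ip_resource_requirements()$total,
                      device_resources(device, catalog), device)
  structure(list(ops_per_frame = ops,
                 system_flops = system_flops(ops$total, ts$hop_s, n_sensors),
                 throughput = ts, sensor_capacity = capacity,
                 n_sensors = n_sensors, resource_fit = fit),
            class = "budget_report")
}

#' @export
print.budget_report <- function(x, ...) {
  o <- x$ops_per_frame
  cat("<budget_report>\n")
  cat(sprintf("  per-frame ops: %d sub + %d mul + %d add = %d\n",
              o$subtractions, o$multiplications, o$additions, o$total))
  cat(sprintf("  hop %.1f ms, frame latency %.2f us -> capacity %d sensors\n",
              x$throughput$hop_s * 1000, x$throughput$latency_s * 1e6,
              x$sensor_capacity))
  cat(sprintf("  system load at %d sensors: %s FLOPS\n", x$n_sensors,
              format(x$system_flops, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  %s fit: DSP %.2f%%, BRAM %.2f%%, LUT %.2f%%, FF %.2f%% (%s)\n",
              x$resource_fit$device, x$resource_fit$percent["dsp"],
              x$resource_fit$percent["bram_blocks"],
              x$resource_fit$percent["lut"], x$resource_fit$percent["ff"],
              if (x$resource_fit$fits) "fits" else "does NOT fit"))
  invisible(x)
}
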