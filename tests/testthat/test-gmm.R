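test_that("k-means initialization: closed forms, separation, determinism", {
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60, 3)
  km1 <- kmeans_init(X, M = 1, seed = 2)
  expect_equal(as.vector(km1$centers), colMeans(X))

  X2 <- two_clouds(R = 400, d = 3, sep = 10)
  km2 <- kmeans_init(X2, M = 2, seed = 2)
  ord <- order(km2$centers[, 1])
  expect_true(all(abs(km2$centers[ord[1], ]) < 1))
  expect_true(all(abs(km2$centers[ord[2], ] - 10) < 1))
  expect_identical(km2$assignment, kmeans_init(X2, M = 2, seed = 2)$assignment)
  expect_error(kmeans_init(X[1:3, ], M = 5), "at least M")

  # agreement with the reference Lloyd implementation on separated data
  set.seed(5)
  ref <- stats::kmeans(X2, centers = km2$centers, algorithm = "Lloyd")
  expect_equal(sort(unname(ref$centers[, 1])), sort(km2$centers[, 1]),
               tolerance = 1e-8)
})

test_that("EM recovers parameters of known generating mixtures", {
  set.seed(101)
  d <- 3; R <- 5000
  mu_true <- c(2, -1, 0.5)
  sigma_true <- random_spd(d, seed = 55) / 2
  ch <- chol(sigma_true)
  X <- matrix(rnorm(R * d), R, d) %*% ch +
    matrix(mu_true, R, d, byrow = TRUE)
  fit1 <- fit_gmm(X, "single", gmm_config(M = 1, seed = 0))
  se <- sqrt(diag(sigma_true) / R)
  expect_true(all(abs(fit1$means[1, ] - mu_true) < 3 * se))
  expect_lt(norm(fit1$covs[, , 1] - sigma_true, "F"),
            0.1 * norm(sigma_true, "F"))

  # two components, weights 0.7 / 0.3, means 5 apart
  set.seed(102)
  z <- runif(R) < 0.7
  X2 <- matrix(rnorm(R * 2), R, 2) + ifelse(z, -2.5, 2.5)
  fit2 <- fit_gmm(X2, "pair", gmm_config(M = 2, seed = 0))
  expect_equal(sort(fit2$weights), c(0.3, 0.7), tolerance = 0.05)
  expect_equal(sort(fit2$means[, 1]), c(-2.5, 2.5), tolerance = 0.2)

  # ascent property holds on the recorded trace
  expect_true(all(diff(fit1$metadata$loglik_trace) > -1e-8))
  expect_true(all(diff(fit2$metadata$loglik_trace) > -1e-8))
  expect_error(fit_gmm(X[1:5, ], "tiny", gmm_config(M = 10)), "cannot support")
})

test_that("mixture weights satisfy the simplex constraint after fitting", {
  set.seed(7)
  X <- matrix(rnorm(400 * 2), 400, 2)
  for (M in c(1, 3, 8)) {
    fit <- fit_gmm(X, paste0("m", M), gmm_config(M = M, seed = 1))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
    expect_true(all(fit$weights >= 0))
  }
})

test_that("component log density uses caches and matches naive evaluation", {
  m1 <- species_gmm("std", weights = 1, means = matrix(0, 1, 1),
                    covs = array(1, c(1, 1, 1)))
  expect_equal(exp(component_logpdf(0, m1, 1)), 1 / sqrt(2 * pi))

  d <- 13
  mI <- species_gmm("iso", weights = 1, means = matrix(0, 1, d),
                    covs = array(diag(d), c(d, d, 1)))
  expect_equal(component_logpdf(rep(0, d), mI, 1), -d / 2 * log(2 * pi))

  set.seed(9)
  S <- random_spd(3, seed = 60)
  mu <- rnorm(3)
  m3 <- species_gmm("spd", weights = 1, means = matrix(mu, 1, 3),
                    covs = array(S, c(3, 3, 1)))
  for (i in 1:5) {
    x <- rnorm(3)
    expect_equal(component_logpdf(x, m3, 1), naive_mvn_logpdf(x, mu, S),
                 tolerance = 1e-10)
  }
  if (requireNamespace("mclust", quietly = TRUE)) {
    x <- rnorm(3)
    expect_equal(component_logpdf(x, m3, 1),
                 as.numeric(mclust::dmvnorm(matrix(x, 1), mu, S, log = TRUE)),
                 tolerance = 1e-8)
  }

  broken <- m3
  broken$sigma_inv <- NULL
  expect_error(component_logpdf(rnorm(3), broken, 1), "cache")
  expect_error(component_logpdf(rnorm(5), m3, 1), "length")
  expect_error(species_gmm("bad", 1, matrix(0, 1, 2),
                           array(matrix(c(1, 2, 2, 1), 2), c(2, 2, 1))),
               "positive definite")
})

test_that("mixture log-likelihood: identities and direct-sum oracle", {
  m <- species_gmm("one", weights = 1, means = matrix(1.5, 1, 1),
                   covs = array(0.7, c(1, 1, 1)))
  expect_equal(model_loglik(0.3, m), component_logpdf(0.3, m, 1))

  dup <- species_gmm("dup", weights = c(0.5, 0.5),
                     means = matrix(1.5, 2, 1),
                     covs = array(0.7, c(1, 1, 2)))
  expect_equal(model_loglik(0.3, dup), model_loglik(0.3, m))

  toy <- species_gmm("toy", weights = c(0.25, 0.75),
                     means = matrix(c(-1, 2), 2, 1),
                     covs = array(c(0.5, 2), c(1, 1, 2)))
  for (x in c(-3, 0, 1, 4)) {
    direct <- log(0.25 * exp(naive_mvn_logpdf(x, -1, matrix(0.5))) +
                  0.75 * exp(naive_mvn_logpdf(x, 2, matrix(2))))
    expect_equal(model_loglik(x, toy), direct, tolerance = 1e-12)
  }
})

test_that("a two-dimensional mixture density integrates to one", {
  set.seed(77)
  model <- species_gmm("norm2", weights = c(0.6, 0.4),
                       means = rbind(c(0, 0), c(3, -2)),
                       covs = array(c(diag(2), 2 * diag(2)), c(2, 2, 2)))
  # importance sampling under an inflated-covariance version of the mixture
  N <- 50000
  z <- runif(N) < 0.6
  q_sd <- sqrt(c(2, 4))
  draws <- matrix(rnorm(2 * N), N, 2)
  draws[z, ] <- draws[z, ] * q_sd[1]
  draws[!z, ] <- sweep(draws[!z, , drop = FALSE] * q_sd[2], 2, c(3, -2), `+`)
  q1 <- exp(-rowSums(draws^2) / (2 * 2)) / (2 * pi * 2)
  zc <- sweep(draws, 2, c(3, -2))
  q2 <- exp(-rowSums(zc^2) / (2 * 4)) / (2 * pi * 4)
  q <- 0.6 * q1 + 0.4 * q2
  p <- exp(vapply(seq_len(N), function(i) model_loglik(draws[i, ], model),
                  numeric(1)))
  expect_equal(mean(p / q), 1, tolerance = 0.01)
})

test_that("classification takes the argmax with deterministic tie-breaks", {
  lo <- species_gmm("low", 1, matrix(-10, 1, 1), array(1, c(1, 1, 1)))
  hi <- species_gmm("high", 1, matrix(10, 1, 1), array(1, c(1, 1, 1)))
  bank <- model_bank(list(lo, hi))
  expect_equal(classify_frame(10, bank)$label, "high")
  expect_equal(classify_frame(-10, bank)$label, "low")
  # equidistant from two identical models: first label wins
  twin <- model_bank(list(
    species_gmm("first", 1, matrix(0, 1, 1), array(1, c(1, 1, 1))),
    species_gmm("second", 1, matrix(0, 1, 1), array(1, c(1, 1, 1)))))
  expect_equal(classify_frame(0.7, twin)$label, "first")

  res <- classify_frames(matrix(c(-9, 9, 0.2), 3, 1), bank)
  expect_equal(res$labels, c("low", "high", "high"))
  expect_equal(dim(res$loglik), c(3, 2))
  expect_error(classify_frames(matrix(0, 1, 2), bank), "d = ")

  # argmax is invariant to a common log-domain shift of every model score
  ll <- res$loglik
  expect_equal(max.col(ll + 42, ties.method = "first"),
               max.col(ll, ties.method = "first"))
})

test_that("majority frame label over a bittern clip is the bittern model", {
  cs <- tiny_corpus_spec(clips = 4, clip_duration = 3)
  dat <- corpus_mfcc(cs)
  cfg <- gmm_config(M = 4, seed = 0)
  bank <- model_bank(lapply(levels(dat$labels), function(cl)
    fit_gmm(dat$features[dat$labels == cl, , drop = FALSE], cl, cfg)))
  clip <- wasnbird:::generate_clip(tiny_species()[[1]], 3, 25, 0.4, 48000,
                                   seed = 999)
  feats <- extract_mfcc(clip, mfcc_config(energy_fraction = 0.35))
  pred <- classify_frames(feats$vectors, bank)$labels
  expect_equal(names(which.max(table(pred))), "bittern_surrogate")
})

test_that("model banks survive a JSON round trip at full precision", {
  set.seed(13)
  X <- matrix(rnorm(300 * 2), 300, 2)
  bank <- model_bank(list(fit_gmm(X, "a", gmm_config(M = 2, seed = 1)),
                          fit_gmm(X + 4, "b", gmm_config(M = 2, seed = 1))))
  path <- tempfile(fileext = ".json")
  save_model_bank(bank, path)
  back <- load_model_bank(path)
  probe <- matrix(rnorm(20 * 2), 20, 2)
  expect_identical(classify_frames(probe, bank)$loglik,
                   classify_frames(probe, back)$loglik)

  # tampered weights are rejected on load
  txt <- readLines(path)
  txt <- sub("\"weights\":\\[[^]]*\\]", "\"weights\":[1.0,0.5]", txt)
  bad <- tempfile(fileext = ".json")
  writeLines(txt, bad)
  expect_error(load_model_bank(bad), "sum to")

  # cache fields absent: rebuilt with a message
  txt2 <- readLines(path)
  txt2 <- gsub(",\"log_det\":\\[[^]]*\\]", "", txt2)
  nocache <- tempfile(fileext = ".json")
  writeLines(txt2, nocache)
  expect_message(b2 <- load_model_bank(nocache), "rebuilding")
  expect_equal(classify_frames(probe, b2)$loglik,
               classify_frames(probe, bank)$loglik)

  garbled <- tempfile(fileext = ".json")
  writeLines("{not json", garbled)
  expect_error(load_model_bank(garbled), "corrupted")
  expect_error(load_model_bank(tempfile()), "not found")
})
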