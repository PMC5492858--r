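#' GMM training configuration
#'
#' @param M Number of mixture components per species (default 32).
#' @param seed Seed for the k-means initialization (default 0).
#' @param tol Relative log-likelihood gain below which EM stops (default 1e-6).
#' @param max_iter Maximum EM iterations (default 200).
#' @param reg Ridge added to every covariance each M-step (default 1e-6).
#' @return A list of class `gmm_config`.
#' @export
gmm_config <- function(M = 32, seed = 0, tol = 1e-6, max_iter = 200,
                       reg = 1e-6) {
  structure(list(M = M, seed = seed, tol = tol, max_iter = max_iter,
                 reg = reg), class = "gmm_config")
}

as_feature_rows <- function(features) {
  if (inherits(features, "feature_matrix")) features$vectors
  else as.matrix(features)
}

#' K-means initialization (k-means++ seeding + Lloyd iterations)
#'
#' Estimates M cluster means used to initialize the mixture fit. Seeding
#' follows k-means++ (each new center drawn with probability proportional to
#' squared distance from the nearest chosen center); Lloyd updates run to
#' convergence; a cluster that empties is reseeded at the point farthest from
#' its assigned center.
#'
#' @param features A [feature_matrix()] or numeric matrix (rows = frames).
#' @param M Number of clusters.
#' @param seed Integer seed (default 0).
#' @param max_iter Maximum Lloyd iterations (default 100).
#' @return List with `centers` (M x d), `assignment` (length-R integer) and
#'   `iterations`.
#' @export
kmeans_init <- function(features, M, seed = 0, max_iter = 100) {
  X <- as_feature_rows(features)
  R <- nrow(X)
  if (R < M)
    stop("k-means needs at least M = ", M, " vectors but got R = ", R)
  set.seed(as.integer(seed))
  # k-means++ seeding
  centers <- matrix(0, M, ncol(X))
  centers[1, ] <- X[sample.int(R, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  if (M > 1) for (k in 2:M) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / R, R)
    centers[k, ] <- X[sample.int(R, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
  }
  # Lloyd iterations (distance via the expansion ||x||^2 - 2 x.c + ||c||^2)
  xs <- rowSums(X^2)
  assignment <- integer(R)
  for (it in seq_len(max_iter)) {
    D <- outer(xs, rowSums(centers^2), `+`) - 2 * X %*% t(centers)
    new_assignment <- max.col(-D, ties.method = "first")
    for (k in seq_len(M)) {
      if (!any(new_assignment == k)) {   # reseed empty cluster at farthest point
        far <- which.max(D[cbind(seq_len(R), new_assignment)])
        new_assignment[far] <- k
      }
    }
    if (identical(new_assignment, assignment)) break
    assignment <- new_assignment
    for (k in seq_len(M))
      centers[k, ] <- colMeans(X[assignment == k, , drop = FALSE])
  }
  list(centers = centers, assignment = assignment, iterations = it)
}

make_component_cache <- function(covs) {
  M <- dim(covs)[3]
  d <- dim(covs)[1]
  log_det <- numeric(M)
  sigma_inv <- array(0, c(d, d, M))
  rooti <- array(0, c(d, d, M))
  for (k in seq_len(M)) {
    ch <- tryCatch(chol(covs[, , k]), error = function(e)
      stop("covariance of component ", k, " is not positive definite"))
    log_det[k] <- 2 * sum(log(diag(ch)))
    ri <- backsolve(ch, diag(d))
    rooti[, , k] <- ri
    sigma_inv[, , k] <- ri %*% t(ri)
  }
  list(log_det = log_det, sigma_inv = sigma_inv, rooti = rooti)
}

#' Construct a per-species Gaussian mixture model
#'
#' Validates the mixture invariants (weights sum to one, covariances
#' symmetric positive-definite) and pre-computes the per-component
#' log-determinants and inverse covariances used at scoring time, so that
#' classification never factorizes a covariance per frame.
#'
#' @param label Species label.
#' @param weights Length-M vector of non-negative mixing weights summing to 1.
#' @param means M x d matrix of component means.
#' @param covs d x d x M array of component covariances.
#' @param metadata Optional list of training metadata (seed, iterations,
#'   log-likelihood trace, ...).
#' @return An object of class `species_gmm`.
#' @export
species_gmm <- function(label, weights, means, covs, metadata = list()) {
  means <- as.matrix(means)
  M <- nrow(means)
  if (length(weights) != M || dim(covs)[3] != M)
    stop("weights, means and covariances disagree on M for ", label)
  if (any(weights < 0)) stop("negative mixture weight in ", label)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights of ", label, " sum to ", sum(weights), ", not 1")
  cache <- make_component_cache(covs)
  structure(list(label = label, M = M, d = ncol(means),
                 weights = as.numeric(weights), means = means, covs = covs,
                 log_det = cache$log_det, sigma_inv = cache$sigma_inv,
                 rooti = cache$rooti, metadata = metadata),
            class = "species_gmm")
}

#' @export
print.species_gmm <- function(x, ...) {
  cat(sprintf("<species_gmm> %s: M = %d components, d = %d\n",
              x$label, x$M, x$d))
  invisible(x)
}

#' Fit a per-species GMM by EM
#'
#' Full-covariance mixture fit initialized from k-means (means = cluster
#' means, covariances = cluster scatter + `reg I`, weights = cluster
#' fractions), iterated until the relative log-likelihood gain drops below
#' `tol` or `max_iter` is reached. The log-likelihood trace is recorded and
#' is non-decreasing up to the ridge perturbation (the EM ascent guarantee).
#'
#' @param features A [feature_matrix()] or numeric matrix of training frames.
#' @param label Species label attached to the model (taken from the feature
#'   matrix if absent).
#' @param config A [gmm_config()].
#' @return A [species_gmm()] with `metadata` fields `seed`, `n_iter`,
#'   `converged`, `loglik_trace` and `final_loglik`.
#' @export
fit_gmm <- function(features, label = NULL, config = gmm_config()) {
  X <- as_feature_rows(features)
  if (is.null(label) && inherits(features, "feature_matrix"))
    label <- features$label
  if (is.null(label)) label <- "unlabelled"
  R <- nrow(X); d <- ncol(X); M <- config$M
  if (R < M)
    stop("species ", label, ": R = ", R, " frames cannot support M = ", M,
         " components")
  if (R < M * (d + 1))
    warning("species ", label, ": R = ", R, " frames is low for M = ", M,
            " full-covariance components in d = ", d)
  km <- kmeans_init(X, M, seed = config$seed)
  means <- km$centers
  covs <- array(0, c(d, d, M))
  weights <- numeric(M)
  for (k in seq_len(M)) {
    idx <- km$assignment == k
    weights[k] <- mean(idx)
    Xk <- X[idx, , drop = FALSE]
    S <- if (nrow(Xk) > 1) stats::cov(Xk) * (nrow(Xk) - 1) / nrow(Xk)
         else matrix(0, d, d)
    covs[, , k] <- S + config$reg * diag(d)
  }
  fit <- .gmm_em_cpp(X, means, covs, weights, config$tol, config$max_iter,
                     config$reg)
  species_gmm(label, fit$weights, fit$means, fit$covs,
              metadata = list(seed = config$seed, n_iter = fit$n_iter,
                              converged = fit$converged,
                              loglik_trace = fit$loglik_trace,
                              final_loglik = fit$loglik_trace[fit$n_iter]))
}

#' Log density of one mixture component
#'
#' Evaluates `-d/2 log(2 pi) - 1/2 log|S_k| - 1/2 (x-mu)' S_k^-1 (x-mu)`
#' using the cached log-determinant and inverse covariance; a model without
#' caches is an error rather than a silent refactorization.
#'
#' @param x Numeric d-vector.
#' @param model A [species_gmm()].
#' @param k Component index (1-based).
#' @return Scalar log density.
#' @export
component_logpdf <- function(x, model, k) {
  stopifnot(inherits(model, "species_gmm"))
  if (is.null(model$log_det) || is.null(model$sigma_inv))
    stop("component caches missing; rebuild the model with species_gmm()")
  if (length(x) != model$d)
    stop("x has length ", length(x), " but the model has d = ", model$d)
  z <- x - model$means[k, ]
  -model$d / 2 * log(2 * pi) - 0.5 * model$log_det[k] -
    0.5 * as.numeric(t(z) %*% model$sigma_inv[, , k] %*% z)
}

#' Mixture log-likelihood of one frame under one species model
#'
#' Log of the weighted component-density sum, computed with log-sum-exp so
#' that high-dimensional frames never underflow.
#'
#' @param x Numeric d-vector.
#' @param model A [species_gmm()].
#' @return Scalar `log P(x; theta)`.
#' @export
model_loglik <- function(x, model) {
  stopifnot(inherits(model, "species_gmm"))
  if (all(model$weights == 0)) stop("all mixture weights are zero")
  terms <- vapply(seq_len(model$M), function(k)
    log(model$weights[k]) + component_logpdf(x, model, k), numeric(1))
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

# Batch scorer: R x M log component densities via the cached Cholesky roots.
gmm_logdens_matrix <- function(X, model) {
  R <- nrow(X); d <- model$d
  L <- matrix(0, R, model$M)
  cst <- -d / 2 * log(2 * pi)
  for (k in seq_len(model$M)) {
    Z <- sweep(X, 2, model$means[k, ]) %*% model$rooti[, , k]
    L[, k] <- cst - 0.5 * (model$log_det[k] + rowSums(Z * Z))
  }
  L
}

# Batch mixture log-likelihood for every row of X.
model_loglik_rows <- function(X, model) {
  L <- sweep(gmm_logdens_matrix(X, model), 2, log(model$weights), `+`)
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}

#' Bundle species models into a classification bank
#'
#' @param models List of [species_gmm()] with distinct labels and a shared
#'   feature dimension.
#' @return An object of class `model_bank`.
#' @export
model_bank <- function(models) {
  if (length(models) == 0) stop("model bank must hold at least one model")
  labels <- vapply(models, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("model labels must be unique")
  ds <- vapply(models, `[[`, numeric(1), "d")
  if (length(unique(ds)) != 1)
    stop("all models must share the feature dimension; got ",
         paste(unique(ds), collapse = ", "))
  structure(list(models = models, labels = labels, n = length(models),
                 d = ds[1]), class = "model_bank")
}

#' @export
print.model_bank <- function(x, ...) {
  cat(sprintf("<model_bank> %d species models, d = %d\n", x$n, x$d))
  invisible(x)
}

#' Classify a single frame
#'
#' Scores the frame under every species model and returns the label with the
#' highest mixture log-likelihood; ties go to the lowest species index.
#'
#' @param x Numeric d-vector.
#' @param bank A [model_bank()].
#' @return List with `label` and `loglik` (named per-model vector).
#' @export
classify_frame <- function(x, bank) {
  stopifnot(inherits(bank, "model_bank"))
  ll <- vapply(bank$models, function(m) model_loglik(x, m), numeric(1))
  names(ll) <- bank$labels
  list(label = bank$labels[which.max(ll)], loglik = ll)
}

#' Classify a matrix of frames
#'
#' Vectorized scorer used for evaluation runs: mixture log-likelihood of
#' every frame under every model, argmax per row (ties to the lowest species
#' index).
#'
#' @param X A [feature_matrix()] or R x d numeric matrix.
#' @param bank A [model_bank()].
#' @return List with `labels` (length-R character) and `loglik` (R x n
#'   matrix with one column per species).
#' @export
classify_frames <- function(X, bank) {
  stopifnot(inherits(bank, "model_bank"))
  X <- as_feature_rows(X)
  if (ncol(X) != bank$d)
    stop("features have d = ", ncol(X), " but the bank expects d = ", bank$d)
  LL <- vapply(bank$models, function(m) model_loglik_rows(X, m),
               numeric(nrow(X)))
  LL <- matrix(LL, nrow = nrow(X), dimnames = list(NULL, bank$labels))
  list(labels = bank$labels[max.col(LL, ties.method = "first")], loglik = LL)
}

#' Save / load a model bank as JSON
#'
#' Serialization keeps every parameter at full precision; loading re-validates
#' the mixture invariants and rebuilds the scoring caches (a file without
#' cache fields loads fine, with a message noting the rebuild).
#'
#' @param bank A [model_bank()].
#' @param path Output/input path.
#' @return `save_model_bank`: `path`, invisibly. `load_model_bank`: the
#'   reconstructed [model_bank()].
#' @export
save_model_bank <- function(bank, path) {
  stopifnot(inherits(bank, "model_bank"))
  payload <- list(
    schema = "wasnbird-gmm-bank/1", d = bank$d,
    models = lapply(bank$models, function(m) list(
      label = m$label, M = m$M, d = m$d, weights = m$weights,
      means = m$means, covs = lapply(seq_len(m$M), function(k) m$covs[, , k]),
      log_det = m$log_det)))
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model_bank
#' @export
load_model_bank <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                       simplifyDataFrame = FALSE),
    error = function(e) stop("corrupted model file: ", path,
                             " (", conditionMessage(e), ")"))
  if (!identical(payload$schema, "wasnbird-gmm-bank/1"))
    stop("unknown model bank schema in ", path)
  models <- lapply(payload$models, function(m) {
    d <- m$d
    covs <- array(0, c(d, d, m$M))
    for (k in seq_len(m$M))
      covs[, , k] <- if (is.list(m$covs)) m$covs[[k]] else m$covs[k, , ]
    if (is.null(m$log_det))
      message("model ", m$label, ": caches absent from file, rebuilding")
    species_gmm(m$label, m$weights, matrix(m$means, m$M, d), covs)
  })
  model_bank(models)
}
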