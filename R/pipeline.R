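#' End-to-end pipeline configuration
#'
#' Bundles the frontend, feature, model and evaluation settings with a single
#' master seed that determines every stochastic stage (corpus synthesis,
#' k-means initialization, fold assignment). Defaults are the reference
#' operating point: 30 ms frames, 50% overlap, a 0.35 energy gate, 48
#' filters, 13 coefficients, M = 32 mixtures, 10 folds.
#'
#' @param frame_ms,overlap Framing parameters.
#' @param energy_fraction High-energy frame fraction retained per clip.
#' @param nfft,n_filters,fmin,split_freq,fmax,n_coeffs Feature parameters,
#'   see [mfcc_config()].
#' @param M,tol,max_iter,reg Mixture parameters, see [gmm_config()].
#' @param k Cross-validation folds.
#' @param cv_mode `"frame"` or `"clip"` fold stratification.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(frame_ms = 30, overlap = 0.5,
                            energy_fraction = 0.35, nfft = 2048,
                            n_filters = 48, fmin = 20, split_freq = 1000,
                            fmax = 16000, n_coeffs = 13, M = 32, tol = 1e-6,
                            max_iter = 200, reg = 1e-6, k = 10,
                            cv_mode = "frame", seed = 1) {
  cfg <- list(frame_ms = frame_ms, overlap = overlap,
              energy_fraction = energy_fraction, nfft = nfft,
              n_filters = n_filters, fmin = fmin, split_freq = split_freq,
              fmax = fmax, n_coeffs = n_coeffs, M = M, tol = tol,
              max_iter = max_iter, reg = reg, k = k, cv_mode = cv_mode,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
as_mfcc_config <- function(cfg) {
  mfcc_config(cfg$frame_ms, cfg$overlap, cfg$nfft, cfg$n_filters, cfg$fmin,
              cfg$split_freq, cfg$fmax, cfg$n_coeffs, cfg$energy_fraction)
}

#' @rdname pipeline_config
#' @export
as_gmm_config <- function(cfg) {
  gmm_config(cfg$M, seed = cfg$seed, tol = cfg$tol, max_iter = cfg$max_iter,
             reg = cfg$reg)
}

#' @rdname pipeline_config
#' @param path JSON file to read/write.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

# Short provenance hash of a config, embedded in output headers.
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  substr(unname(tools::md5sum(tf)), 1, 12)
}

#' Synthesize a corpus to disk
#'
#' @param out_dir Output directory for WAV clips and `manifest.csv`.
#' @param species_file Optional JSON file overriding the default species
#'   table (a list of [species_spec()] field sets).
#' @param seed Corpus seed.
#' @param clip_duration,clips_per_species,snr_db,silence_fraction Corpus
#'   parameters, see [corpus_spec()].
#' @return The manifest data frame, invisibly.
#' @export
cmd_synth <- function(out_dir, species_file = NULL, seed = 1,
                      clip_duration = 10, clips_per_species = 30,
                      snr_db = 20, silence_fraction = 0.5) {
  species <- if (is.null(species_file)) default_species_table()
  else {
    raw <- jsonlite::fromJSON(species_file, simplifyDataFrame = FALSE)
    lapply(raw, function(s) do.call(species_spec, s))
  }
  cs <- corpus_spec(species, clip_duration, clips_per_species, snr_db,
                    silence_fraction, seed)
  res <- generate_corpus(cs, out_dir)
  message(sprintf("synthesized %d clips (%.1f s total) into %s",
                  nrow(res$manifest), res$total_duration_s, out_dir))
  invisible(res$manifest)
}

#' Extract features for a directory of WAV clips
#'
#' Reads every clip listed in `manifest.csv` (or all `.wav` files when no
#' manifest exists), applies the energy gate and the feature chain, and
#' writes one CSV per clip (`frame_time`, `c0..c12`, `label`) plus a run log.
#'
#' @param audio_dir Directory of WAV files.
#' @param out_dir Output directory for feature CSVs.
#' @param cfg A [pipeline_config()].
#' @param strict If `TRUE`, an unreadable file aborts; otherwise it is logged
#'   and skipped.
#' @return Data frame run log (file, label, frames_total, frames_kept),
#'   invisibly.
#' @export
cmd_extract <- function(audio_dir, out_dir, cfg = pipeline_config(),
                        strict = FALSE) {
  manifest_path <- file.path(audio_dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    man <- read.csv(manifest_path, stringsAsFactors = FALSE)
    files <- man$path
    labels <- man$species_label
  } else {
    files <- list.files(audio_dir, "\\.wav$", full.names = TRUE)
    labels <- rep(NA_character_, length(files))
  }
  if (length(files) == 0) {
    if (strict) stop("no WAV input found in ", audio_dir)
    message("no WAV input found in ", audio_dir)
    return(invisible(data.frame()))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mcfg <- as_mfcc_config(cfg)
  hash <- config_hash(cfg)
  log_rows <- list()
  for (i in seq_along(files)) {
    res <- tryCatch({
      clip <- load_wav(files[i], label = labels[i])
      fm_all <- frame_signal(clip, cfg$frame_ms, cfg$overlap)
      feats <- extract_mfcc(clip, mcfg)
      out <- data.frame(frame_time = feats$frame_times)
      cmat <- feats$vectors
      colnames(cmat) <- paste0("c", seq_len(ncol(cmat)) - 1)
      out <- cbind(out, cmat)
      out$label <- labels[i]
      out_path <- file.path(out_dir, paste0(
        sub("\\.wav$", "", basename(files[i])), "_mfcc.csv"))
      con <- file(out_path, "w")
      writeLines(sprintf("# wasnbird features, config %s, seed %d", hash,
                         cfg$seed), con)
      write.csv(out, con, row.names = FALSE)
      close(con)
      data.frame(file = files[i], label = labels[i],
                 frames_total = nrow(fm_all$frames),
                 frames_kept = nrow(feats$vectors), stringsAsFactors = FALSE)
    }, error = function(e) {
      if (strict) stop("failed on ", files[i], ": ", conditionMessage(e))
      message("skipping ", files[i], ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) log_rows[[length(log_rows) + 1]] <- res
  }
  log_df <- do.call(rbind, log_rows)
  write.csv(log_df, file.path(out_dir, "extract_log.csv"), row.names = FALSE)
  invisible(log_df)
}

read_feature_dir <- function(features_dir) {
  files <- list.files(features_dir, "_mfcc\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no feature CSVs found in ", features_dir)
  parts <- lapply(files, function(f) read.csv(f, comment.char = "#",
                                              stringsAsFactors = FALSE))
  clip_ids <- rep(seq_along(files), vapply(parts, nrow, 0L))
  df <- do.call(rbind, parts)
  ccols <- grep("^c[0-9]+$", names(df), value = TRUE)
  list(features = as.matrix(df[, ccols]), labels = df$label,
       clip_ids = clip_ids, frame_times = df$frame_time)
}

#' Train a model bank from extracted features
#'
#' @param features_dir Directory of per-clip feature CSVs from
#'   [cmd_extract()].
#' @param model_path Output JSON path for the trained bank.
#' @param cfg A [pipeline_config()].
#' @return The [model_bank()], invisibly.
#' @export
cmd_train <- function(features_dir, model_path, cfg = pipeline_config()) {
  dat <- read_feature_dir(features_dir)
  if (anyNA(dat$labels)) stop("training features must carry species labels")
  gcfg <- as_gmm_config(cfg)
  classes <- sort(unique(dat$labels))
  models <- lapply(classes, function(cl)
    fit_gmm(dat$features[dat$labels == cl, , drop = FALSE], label = cl,
            config = gcfg))
  bank <- model_bank(models)
  save_model_bank(bank, model_path)
  message("trained ", bank$n, " species models (config ", config_hash(cfg),
          ", seed ", cfg$seed, ") -> ", model_path)
  invisible(bank)
}

#' Classify extracted features with a trained bank
#'
#' @param features_dir Directory of per-clip feature CSVs.
#' @param model_path Trained bank JSON from [cmd_train()].
#' @param out_csv Output CSV (frame_time, per-model log-likelihood columns,
#'   predicted_label).
#' @return The predictions data frame, invisibly.
#' @export
cmd_classify <- function(features_dir, model_path, out_csv) {
  dat <- read_feature_dir(features_dir)
  bank <- load_model_bank(model_path)
  res <- classify_frames(dat$features, bank)
  out <- data.frame(frame_time = dat$frame_times)
  out <- cbind(out, as.data.frame(res$loglik))
  out$predicted_label <- res$labels
  write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}

#' Cross-validated evaluation over extracted features
#'
#' @param features_dir Directory of per-clip feature CSVs.
#' @param out_dir Output directory: `cv_accuracy.csv` (fold, class,
#'   accuracy), `confusion_counts.csv`, `confusion_percent.csv`,
#'   `boxplot_stats.csv` and `summary.json`.
#' @param cfg A [pipeline_config()].
#' @return The `cv_report`, invisibly.
#' @export
cmd_evaluate <- function(features_dir, out_dir, cfg = pipeline_config()) {
  dat <- read_feature_dir(features_dir)
  if (anyNA(dat$labels)) stop("evaluation features must carry species labels")
  plan <- make_folds(dat$labels, k = cfg$k, mode = cfg$cv_mode,
                     clip_ids = dat$clip_ids, seed = cfg$seed)
  report <- run_cv(dat$features, dat$labels, plan, as_gmm_config(cfg))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  acc <- data.frame(
    fold = rep(seq_len(cfg$k), times = length(report$labels)),
    class = rep(report$labels, each = cfg$k),
    accuracy = as.vector(report$per_fold_accuracy))
  write.csv(acc, file.path(out_dir, "cv_accuracy.csv"), row.names = FALSE)
  write.csv(report$counts, file.path(out_dir, "confusion_counts.csv"))
  write.csv(format_confusion(report$row_percent),
            file.path(out_dir, "confusion_percent.csv"))
  write.csv(cv_boxplot_stats(report),
            file.path(out_dir, "boxplot_stats.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = config_hash(cfg), seed = cfg$seed, k = cfg$k,
         mode = cfg$cv_mode,
         overall_accuracy = mean(report$actual == report$predicted),
         mean_class_accuracy = mean(report$mean_accuracy),
         em_min_loglik_step = report$em_min_loglik_step),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Print a deployment budget
#'
#' @param ... Passed to [budget_report()].
#' @param json_path Optional path to also write the report as JSON.
#' @return The `budget_report`, invisibly.
#' @export
cmd_budget <- function(..., json_path = NULL) {
  rep <- budget_report(...)
  print(rep)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(ops_per_frame = rep$ops_per_frame,
           system_flops = rep$system_flops,
           sensor_capacity = rep$sensor_capacity,
           n_sensors = rep$n_sensors,
           device = rep$resource_fit$device,
           percent = as.list(rep$resource_fit$percent),
           fits = rep$resource_fit$fits),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' Command-line entry point
#'
#' Dispatches the `synth`, `extract`, `train`, `classify`, `evaluate` and
#' `budget` subcommands; the installed script `inst/cli/wasnbird.R` forwards
#' `commandArgs(TRUE)` here. Exit codes: 0 success, 1 data error, 2 usage or
#' configuration error.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
wasn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: wasnbird <synth|extract|train|classify|evaluate|budget> [options]",
    "  synth    --out DIR [--species-file F] [--seed N] [--clips N] [--snr DB]",
    "  extract  --audio DIR --out DIR [--config F] [--strict]",
    "  train    --features DIR --model F [--config F]",
    "  classify --features DIR --model F --out F",
    "  evaluate --features DIR --out DIR [--config F]",
    "  budget   [--classes N] [--mixtures N] [--dim N] [--sensors N]",
    "           [--device NAME] [--json F]", sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  rest <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 0) default else rest[i + 1]
  }
  has <- function(flag) flag %in% rest
  cfg <- if (!is.null(opt("--config"))) read_pipeline_config(opt("--config"))
  else pipeline_config()
  status <- tryCatch({
    switch(cmd,
      synth = cmd_synth(
        out_dir = opt("--out"), species_file = opt("--species-file"),
        seed = as.integer(opt("--seed", "1")),
        clips_per_species = as.integer(opt("--clips", "30")),
        snr_db = as.numeric(opt("--snr", "20"))),
      extract = cmd_extract(opt("--audio"), opt("--out"), cfg,
                            strict = has("--strict")),
      train = cmd_train(opt("--features"), opt("--model"), cfg),
      classify = cmd_classify(opt("--features"), opt("--model"), opt("--out")),
      evaluate = cmd_evaluate(opt("--features"), opt("--out"), cfg),
      budget = cmd_budget(
        n_classes = as.integer(opt("--classes", "20")),
        mixtures = as.integer(opt("--mixtures", "32")),
        dim = as.integer(opt("--dim", "13")),
        n_sensors = if (is.null(opt("--sensors"))) NULL
                    else as.integer(opt("--sensors")),
        device = opt("--device", "XC7Z020"),
        json_path = opt("--json")),
      { message("unknown subcommand: ", cmd, "\n", usage)
        return(invisible(2L)) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
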