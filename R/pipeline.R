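# End-to-end pipeline: simulate -> train (both directions) -> impute ->
# evaluate, driven by a single nested configuration with strict key
# checking and per-stage seeds derived from the global seed by fixed
# offsets.

#' Default pipeline configuration
#'
#' A fully-defaulted configuration runs a desk-scale demonstration end to
#' end on one CPU: a 16^3 phantom cohort of 6 subjects (2 with a missing
#' timepoint), narrow-width networks, and a few epochs of mpgan training
#' for each prediction direction.
#'
#' @return Nested configuration list of class `run_config`.
#' @export
default_config <- function() {
  cfg <- list(
    seed = 1L,
    verbosity = 1L,
    phantom = list(
      shape = c(16L, 16L, 16L),
      spacing = c(1, 1, 1),
      growth_factor = 1.07,
      smoothing_fwhm = 1
    ),
    cohort = list(
      n_subjects = 6L,
      missing_fraction = 1 / 3,
      split = c(2 / 3, 1 / 6, 1 / 6)
    ),
    train = list(
      variant = "mpgan",
      contrast = "T1w",
      epochs = 3L,
      lr0 = 5e-2,
      warm_epochs = 44L,
      decay_every = 22L,
      decay_base = 0.5,
      extra_epochs = 176L,
      alpha = 25,
      beta = 25,
      feature_layer = 1L,
      adam_beta1 = 0.5,
      adam_beta2 = 0.999,
      encoder_channels = c(4L, 8L, 8L, 16L, 16L, 32L, 32L, 64L),
      decoder_channels = c(32L, 32L, 16L, 16L, 8L, 8L),
      disc_channels = c(8L, 16L, 32L, 64L),
      feat_channels = c(4L, 8L, 16L, 32L)
    ),
    metrics = list(
      refAVD = 5.6,
      refASD = 0.27,
      refTanimotoError = 15.8
    )
  )
  class(cfg) <- "run_config"
  cfg
}

check_known_keys <- function(raw, template, path = character()) {
  for (key in names(raw)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(template))
      stop("unknown configuration key: ", here)
    if (is.list(template[[key]]) && !is.null(names(template[[key]]))) {
      if (!is.list(raw[[key]]))
        stop("configuration key ", here, " must be a section")
      check_known_keys(raw[[key]], template[[key]], c(path, key))
    }
  }
  invisible(NULL)
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], override[[key]])
    } else {
      value <- override[[key]]
      if (is.list(value)) value <- unlist(value)
      base[[key]] <- value
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, YAML text, or a nested list; fills defaults,
#' rejects unknown keys (typo safety), and checks every nested invariant
#' (shape divisibility by 8, non-negative loss weights, split proportions
#' summing to 1, ...) before any computation.
#'
#' @param raw Configuration source; `NULL` gives the defaults.
#' @return Resolved configuration of class `run_config`.
#' @export
validate_config <- function(raw = NULL) {
  base <- default_config()
  if (!is.null(raw)) {
    if (is.character(raw) && length(raw) == 1L) {
      raw <- if (file.exists(raw)) yaml::read_yaml(raw)
             else yaml::yaml.load(raw)
    }
    if (!is.list(raw)) stop("configuration must be a YAML mapping")
    check_known_keys(raw, unclass(base))
    cfg <- merge_config(unclass(base), raw)
  } else {
    cfg <- unclass(base)
  }

  if (length(cfg$phantom$shape) == 1L)
    cfg$phantom$shape <- rep(cfg$phantom$shape, 3L)
  if (any(cfg$phantom$shape %% 8 != 0))
    stop("invalid phantom.shape: every axis must be divisible by 8")
  if (cfg$phantom$growth_factor <= 1)
    stop("invalid phantom.growth_factor: must be > 1")
  if (cfg$train$alpha < 0) stop("invalid train.alpha: must be >= 0")
  if (cfg$train$beta < 0) stop("invalid train.beta: must be >= 0")
  if (!cfg$train$variant %in% VARIANTS)
    stop("invalid train.variant: must be one of ",
         paste(VARIANTS, collapse = ", "))
  if (abs(sum(cfg$cohort$split) - 1) > 1e-9)
    stop("invalid cohort.split: proportions must sum to 1")
  if (cfg$cohort$missing_fraction < 0 || cfg$cohort$missing_fraction >= 1)
    stop("invalid cohort.missing_fraction: must be in [0, 1)")
  if (any(c(cfg$metrics$refAVD, cfg$metrics$refASD,
            cfg$metrics$refTanimotoError) <= 0))
    stop("invalid metrics reference constants: must be > 0")
  class(cfg) <- "run_config"
  cfg
}

config_train_cfg <- function(cfg, direction, seed_offset) {
  tr <- cfg$train
  nc <- if (tr$variant == "mpgan") 2L else 1L
  fc <- as.integer(tr$feat_channels)
  train_config(
    variant = tr$variant, direction = direction,
    weights = loss_weights(tr$alpha, tr$beta, tr$feature_layer),
    contrast = tr$contrast, lr0 = tr$lr0, warm_epochs = tr$warm_epochs,
    decay_every = tr$decay_every, decay_base = tr$decay_base,
    extra_epochs = tr$extra_epochs, epochs = tr$epochs,
    seed = cfg$seed + seed_offset,
    adam_beta1 = tr$adam_beta1, adam_beta2 = tr$adam_beta2,
    gen_spec = generator_spec(
      in_contrasts = nc, out_decoders = nc,
      encoder_channels = tr$encoder_channels,
      decoder_channels = tr$decoder_channels),
    disc_spec = discriminator_spec(channels = tr$disc_channels),
    feat_spec = feature_extractor_spec(block_channels = list(
      c(fc[1], fc[2]), c(fc[2], fc[3]), c(fc[3], fc[4]), c(fc[4], 2L * fc[4])))
  )
}

#' Run the full simulate/train/impute/evaluate pipeline
#'
#' Writes into `out_dir`: the cohort tree with its manifest, a
#' resolved-config snapshot (`config.yaml`), model checkpoints and
#' JSON-lines training logs for both prediction directions, the imputed
#' volumes with an imputation manifest, predicted test-subject images,
#' and a per-structure metric report (`report.csv` + `summary.csv`)
#' comparing intensity-based segmentations of predicted versus
#' ground-truth target images of the test split.
#'
#' @param cfg A configuration from [validate_config()] (or anything it
#'   accepts).
#' @param out_dir Output directory.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(cfg = NULL, out_dir) {
  cfg <- validate_config(if (inherits(cfg, "run_config")) unclass(cfg) else cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  note <- function(...) if (cfg$verbosity > 0) message(sprintf(...))

  note("simulating cohort (%d subjects)", cfg$cohort$n_subjects)
  cohort <- stage("simulate", {
    spec <- phantom_spec(shape = cfg$phantom$shape,
                         spacing = cfg$phantom$spacing,
                         growth_factor = cfg$phantom$growth_factor,
                         smoothing_fwhm = cfg$phantom$smoothing_fwhm,
                         seed = cfg$seed)
    generate_cohort(spec, cfg$cohort$n_subjects,
                    cfg$cohort$missing_fraction, cfg$cohort$split)
  })
  stage("simulate", write_cohort(cohort, file.path(out_dir, "cohort")))

  fits <- list()
  for (direction in c("6to12", "12to6")) {
    note("training %s (%s)", cfg$train$variant, direction)
    offset <- if (direction == "6to12") 100L else 200L
    tcfg <- config_train_cfg(cfg, direction, offset)
    fit <- stage(paste0("train_", direction), fit_model(cohort, tcfg))
    fits[[direction]] <- fit
    stage(paste0("train_", direction), {
      save_bundle(fit$bundle,
                  file.path(out_dir, sprintf("checkpoint_%s.rds", direction)))
      log_path <- file.path(out_dir, sprintf("train_log_%s.jsonl", direction))
      lines <- vapply(seq_len(nrow(fit$history)), function(i)
        as.character(jsonlite::toJSON(as.list(fit$history[i, ]),
                                      auto_unbox = TRUE, digits = NA,
                                      na = "null")), character(1))
      writeLines(lines, log_path)
    })
  }

  note("imputing missing timepoints")
  imp <- stage("impute", impute_cohort(cohort, fits[["6to12"]]$bundle,
                                       fits[["12to6"]]$bundle))
  cohort <- imp$cohort
  utils::write.csv(imp$manifest, file.path(out_dir, "imputation_manifest.csv"),
                   row.names = FALSE)
  stage("impute", write_cohort(cohort, file.path(out_dir, "cohort_completed")))

  note("evaluating on the test split")
  report <- stage("evaluate", {
    bundle <- fits[["6to12"]]$bundle
    test <- split_subjects(cohort, "test", "6to12")
    pred_dir <- file.path(out_dir, "predictions")
    dir.create(pred_dir, showWarnings = FALSE)
    rows <- list()
    for (s in test) {
      tin <- s$timepoints[["6m"]]
      inputs <- stats::setNames(lapply(bundle$contrasts,
                                       function(cn) tin[[cn]]),
                                bundle$contrasts)
      pred <- predict(bundle,
                      if (length(inputs) == 1L) inputs[[1]] else inputs)
      if (inherits(pred, "volume"))
        pred <- stats::setNames(list(pred), bundle$contrasts)
      for (cn in names(pred))
        write_volume(pred[[cn]],
                     file.path(pred_dir,
                               sprintf("%s_12m_%s_pred.nii.gz",
                                       s$subject_id, cn)),
                     sidecar = TRUE)
      seg_pred <- segment_by_intensity(pred, cohort$spec, "12m")
      seg_gt <- segment_by_intensity(s$timepoints[["12m"]], cohort$spec,
                                     "12m")
      rep <- per_structure_report(seg_pred, seg_gt,
                                  metric_refs(cfg$metrics$refAVD,
                                              cfg$metrics$refASD,
                                              cfg$metrics$refTanimotoError))
      rep$subject_id <- s$subject_id
      rows[[length(rows) + 1L]] <- as.data.frame(rep)
    }
    if (length(rows) == 0) stop("no complete test subjects to evaluate")
    do.call(rbind, rows)
  })
  utils::write.csv(report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  ok <- report[report$defined, , drop = FALSE]
  summary_df <- do.call(rbind, lapply(
    c("AVD", "ASD", "Dice", "TanimotoError", "FusedScore"),
    function(cl) data.frame(metric = cl, mean = mean(ok[[cl]]),
                            sd = stats::sd(ok[[cl]]))))
  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  note("pipeline complete: %s", out_dir)
  invisible(out_dir)
}

#' Save a model bundle checkpoint
#'
#' @param bundle A [build_model_bundle()] result.
#' @param path Destination file.
#' @export
save_bundle <- function(bundle, path) {
  values <- lapply(bundle_params(bundle), function(p) p$v)
  saveRDS(list(cfg = bundle$cfg, values = values,
               opt = list(g_t = bundle$opt$g_t, d_t = bundle$opt$d_t)),
          path)
  invisible(path)
}

#' Load a model bundle checkpoint
#'
#' @param path File written by [save_bundle()].
#' @return A reconstructed `model_bundle`.
#' @export
load_bundle <- function(path) {
  ck <- readRDS(path)
  bundle <- build_model_bundle(ck$cfg)
  ps <- bundle_params(bundle)
  if (length(ps) != length(ck$values))
    stop("checkpoint does not match the configuration's architecture")
  for (i in seq_along(ps)) ps[[i]]$v <- ck$values[[i]]
  bundle$opt$g_t <- ck$opt$g_t
  bundle$opt$d_t <- ck$opt$d_t
  bundle
}
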