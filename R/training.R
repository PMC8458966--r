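# Optimization loop: alternating discriminator/generator Adam updates at
# batch size 1, the piecewise-constant halving learning-rate schedule, the
# ablation variants as configurations, and the cohort-imputation workflow.

VARIANTS <- c("unet_lvr", "unet_lvr_lp", "gan", "gan_lvr", "pgan", "mpgan")

variant_terms <- function(variant) {
  list(
    adv = variant %in% c("gan", "gan_lvr", "pgan", "mpgan"),
    vr = variant %in% c("unet_lvr", "unet_lvr_lp", "gan_lvr", "pgan", "mpgan"),
    lp = variant %in% c("unet_lvr_lp", "pgan", "mpgan")
  )
}

#' Training configuration
#'
#' The learning-rate schedule is `lr0` for the first `warm_epochs` epochs,
#' then halved (factor `decay_base`) every `decay_every` epochs for an
#' additional `extra_epochs` epochs; the defaults give 220 epochs total
#' with 8 decays.  `epochs` can truncate a run (desk-scale smoke training)
#' without altering the schedule itself.
#'
#' @param variant One of `"unet_lvr"`, `"unet_lvr_lp"`, `"gan"`,
#'   `"gan_lvr"`, `"pgan"`, `"mpgan"`; determines the active loss terms.
#' @param direction `"6to12"` or `"12to6"`.
#' @param weights A [loss_weights()].
#' @param contrast Input/output contrast for single-contrast variants
#'   (ignored by `"mpgan"`, which uses both).
#' @param lr0 Initial learning rate.
#' @param warm_epochs,decay_every,decay_base,extra_epochs Schedule
#'   parameters.
#' @param epochs Number of epochs actually run (default
#'   `warm_epochs + extra_epochs`).
#' @param batch_size Only 1 is supported (whole-volume batches).
#' @param seed Seed controlling initialization and shuffling.
#' @param adam_beta1,adam_beta2 Adam moment parameters (GAN convention
#'   beta1 = 0.5).
#' @param gen_spec,disc_spec,feat_spec Architecture specifications;
#'   defaults follow the variant.
#' @return An object of class `train_config`.
#' @export
train_config <- function(variant = "mpgan", direction = "6to12",
                         weights = loss_weights(), contrast = "T1w",
                         lr0 = 2e-4, warm_epochs = 44L, decay_every = 22L,
                         decay_base = 0.5, extra_epochs = 176L,
                         epochs = NULL, batch_size = 1L, seed = 1L,
                         adam_beta1 = 0.5, adam_beta2 = 0.999,
                         gen_spec = NULL, disc_spec = discriminator_spec(),
                         feat_spec = feature_extractor_spec()) {
  variant <- match.arg(variant, VARIANTS)
  direction <- match.arg(direction, c("6to12", "12to6"))
  stopifnot(inherits(weights, "loss_weights"))
  if (batch_size != 1L) stop("only batch_size = 1 is supported")
  if (is.null(gen_spec)) {
    nc <- if (variant == "mpgan") 2L else 1L
    gen_spec <- generator_spec(in_contrasts = nc, out_decoders = nc)
  }
  if (variant == "mpgan" &&
      (gen_spec$in_contrasts != 2L || gen_spec$out_decoders != 2L))
    stop("mpgan requires a dual-contrast, dual-decoder generator spec")
  if (variant != "mpgan" && gen_spec$out_decoders != 1L)
    stop("single-contrast variants require a single-decoder generator")
  total <- as.integer(warm_epochs) + as.integer(extra_epochs)
  if (is.null(epochs)) epochs <- total
  structure(
    list(variant = variant, direction = direction, weights = weights,
         contrast = contrast, lr0 = lr0,
         warm_epochs = as.integer(warm_epochs),
         decay_every = as.integer(decay_every), decay_base = decay_base,
         extra_epochs = as.integer(extra_epochs),
         epochs = as.integer(epochs), batch_size = 1L,
         seed = as.integer(seed), adam_beta1 = adam_beta1,
         adam_beta2 = adam_beta2, gen_spec = gen_spec,
         disc_spec = disc_spec, feat_spec = feat_spec),
    class = "train_config"
  )
}

#' Learning rate at a given epoch
#'
#' `lr0` for `epoch < warm_epochs`, thereafter
#' `lr0 * decay_base^(1 + floor((epoch - warm_epochs) / decay_every))`;
#' non-increasing and piecewise constant.
#'
#' @param epoch 0-based epoch index in `[0, warm_epochs + extra_epochs)`.
#' @param cfg A [train_config()].
#' @return Positive learning rate.
#' @export
learning_rate <- function(epoch, cfg) {
  total <- cfg$warm_epochs + cfg$extra_epochs
  if (any(epoch < 0) || any(epoch >= total))
    stop("epoch must be in [0, ", total, ")")
  ifelse(epoch < cfg$warm_epochs, cfg$lr0,
         cfg$lr0 * cfg$decay_base^(1 + (epoch - cfg$warm_epochs) %/%
                                     cfg$decay_every))
}

bundle_contrasts <- function(variant, contrast) {
  if (variant == "mpgan") c("T1w", "T2w") else contrast
}

#' Build a model bundle for a training configuration
#'
#' The bundle holds the generator (shared-encoder dual-decoder for mpgan),
#' one discriminator per output contrast, and the frozen feature
#' extractor.  Sub-network seeds are derived from `cfg$seed` by fixed
#' offsets.
#'
#' @param cfg A [train_config()].
#' @return An object of class `model_bundle`.
#' @export
build_model_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "train_config"))
  cons <- bundle_contrasts(cfg$variant, cfg$contrast)
  G <- build_generator(cfg$gen_spec, seed = cfg$seed)
  D <- stats::setNames(lapply(seq_along(cons), function(i)
    build_discriminator(cfg$disc_spec, in_ch = 1L, seed = cfg$seed + i)),
    cons)
  phi <- build_feature_extractor(cfg$feat_spec, in_ch = 1L,
                                 seed = cfg$seed + 11L)
  opt <- new.env(parent = emptyenv())
  opt$g_t <- 0L
  opt$d_t <- 0L
  structure(
    list(variant = cfg$variant, direction = cfg$direction,
         contrasts = cons, G = G, D = D, phi = phi, cfg = cfg, opt = opt),
    class = "model_bundle"
  )
}

bundle_params <- function(bundle) {
  c(generator_params(bundle$G),
    do.call(c, lapply(bundle$D, discriminator_params)),
    feature_params(bundle$phi))
}

direction_ages <- function(direction) {
  if (direction == "6to12") c(input = "6m", target = "12m")
  else c(input = "12m", target = "6m")
}

# Build the (x, y) pair of one subject for a bundle's direction/contrasts.
make_example <- function(subject, direction, contrasts) {
  ages <- direction_ages(direction)
  tin <- subject$timepoints[[ages["input"]]]
  tout <- subject$timepoints[[ages["target"]]]
  if (is.null(tin) || is.null(tout))
    stop("subject ", subject$subject_id, " lacks a required timepoint")
  x <- as_tensor(lapply(contrasts, function(cn) tin[[cn]]))
  y <- as_tensor(lapply(contrasts, function(cn) tout[[cn]]))
  list(x = x, y = y)
}

#' One alternating discriminator/generator update
#'
#' With an adversarial term active, the discriminator(s) are updated first
#' on (real target, detached generator output), jointly across contrasts;
#' then the generator is updated on the full composite objective.  The
#' feature extractor is frozen throughout.
#'
#' @param bundle A [build_model_bundle()] result (updated in place).
#' @param batch List with tensors `x` and `y` (see `make_example`).
#' @param cfg The [train_config()].
#' @param lr Learning rate for this step.
#' @return The post-update `loss_breakdown`.
#' @export
train_step <- function(bundle, batch, cfg, lr = cfg$lr0) {
  terms <- variant_terms(cfg$variant)
  cons <- bundle$contrasts
  nc <- length(cons)
  w <- cfg$weights
  ycols <- lapply(seq_len(nc), function(i) {
    m <- batch$y[, i, drop = FALSE]
    vdim(m) <- vdim(batch$y)
    m
  })

  adv_d_val <- NA_real_
  if (terms$adv) {
    fake <- generator_forward(bundle$G, batch$x, tape_new(FALSE))
    tp <- tape_new(TRUE)
    dn <- list()
    for (i in seq_len(nc)) {
      dr <- discriminator_forward(bundle$D[[i]], ycols[[i]], tp)
      df <- discriminator_forward(bundle$D[[i]], fake[[i]]$v, tp)
      dn[[length(dn) + 1L]] <- op_mean_sq(tp, dr, center = 1)
      dn[[length(dn) + 1L]] <- op_mean_sq(tp, df, center = 0)
    }
    ld <- op_wsum(tp, dn, rep(1, length(dn)))
    if (!is.finite(ld$v)) stop("training diverged: non-finite adv_D")
    tape_backward(tp, ld)
    bundle$opt$d_t <- bundle$opt$d_t + 1L
    adam_step(do.call(c, lapply(bundle$D, discriminator_params)), lr,
              bundle$opt$d_t, cfg$adam_beta1, cfg$adam_beta2)
    adv_d_val <- ld$v
  }

  tp <- tape_new(TRUE)
  outs <- generator_forward(bundle$G, batch$x, tp)
  nodes <- list()
  wts <- numeric()
  adv_g_val <- 0
  vr_val <- 0
  lp_val <- 0
  if (terms$adv) {
    for (i in seq_len(nc)) {
      df <- disc_apply(bundle$D[[i]], outs[[i]], tp)
      nd <- op_mean_sq(tp, df, center = 1)
      nodes <- c(nodes, list(nd))
      wts <- c(wts, 1)
      adv_g_val <- adv_g_val + nd$v
    }
  }
  if (terms$vr) {
    for (i in seq_len(nc)) {
      nd <- op_l1_mean(tp, outs[[i]], ycols[[i]])
      nodes <- c(nodes, list(nd))
      wts <- c(wts, w$alpha)
      vr_val <- vr_val + nd$v
    }
  }
  if (terms$lp) {
    for (i in seq_len(nc)) {
      ft <- phi_forward(bundle$phi, ycols[[i]], w$feature_layer,
                        tape_new(FALSE))$v
      fp <- phi_apply(bundle$phi, outs[[i]], w$feature_layer, tp)
      nd <- op_l1_mean(tp, fp, ft)
      nodes <- c(nodes, list(nd))
      wts <- c(wts, w$beta)
      lp_val <- lp_val + nd$v
    }
  }
  total <- op_wsum(tp, nodes, wts)
  if (!is.finite(total$v)) stop("training diverged: non-finite total_G")
  tape_backward(tp, total)
  bundle$opt$g_t <- bundle$opt$g_t + 1L
  adam_step(generator_params(bundle$G), lr, bundle$opt$g_t,
            cfg$adam_beta1, cfg$adam_beta2)
  # discriminator grads accumulated through disc_apply are discarded
  zero_grads(do.call(c, lapply(bundle$D, discriminator_params)))

  structure(list(adv_G = adv_g_val, adv_D = adv_d_val, vr = vr_val,
                 perceptual = lp_val, total_G = total$v),
            class = "loss_breakdown")
}

complete_for <- function(subject, direction) {
  ages <- direction_ages(direction)
  !is.null(subject$timepoints[[ages["input"]]]) &&
    !is.null(subject$timepoints[[ages["target"]]])
}

split_subjects <- function(cohort, split, direction) {
  Filter(function(s) s$split %in% split && complete_for(s, direction),
         cohort$subjects)
}

#' Fit a model on a cohort
#'
#' Iterates epochs over the training-split subjects (seed-deterministic
#' shuffling, batch size 1), tracks the per-epoch mean loss breakdown and
#' the validation voxel-wise reconstruction loss, and returns the
#' checkpoint with minimum validation loss (falling back to the final
#' epoch when the validation split is empty).
#'
#' @param cohort A [generate_cohort()] result (possibly imputation-
#'   completed).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `bundle` (the selected checkpoint), `history`
#'   (per-epoch data.frame), and `best_epoch`.
#' @export
fit_model <- function(cohort, cfg, verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"), inherits(cfg, "train_config"))
  cons <- bundle_contrasts(cfg$variant, cfg$contrast)
  train <- split_subjects(cohort, "train", cfg$direction)
  if (length(train) == 0) stop("no complete training subjects for direction ",
                               cfg$direction)
  val <- split_subjects(cohort, "val", cfg$direction)
  bundle <- build_model_bundle(cfg)
  batches <- lapply(train, make_example, direction = cfg$direction,
                    contrasts = cons)
  val_batches <- lapply(val, make_example, direction = cfg$direction,
                        contrasts = cons)

  hist_rows <- vector("list", cfg$epochs)
  best_val <- Inf
  best_epoch <- cfg$epochs - 1L
  best_state <- NULL
  trainable <- c(generator_params(bundle$G),
                 do.call(c, lapply(bundle$D, discriminator_params)))

  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lr <- learning_rate(epoch, cfg)
      ord <- sample.int(length(batches))
      acc <- c(adv_G = 0, adv_D = 0, vr = 0, perceptual = 0, total_G = 0)
      for (i in ord) {
        bd <- train_step(bundle, batches[[i]], cfg, lr)
        acc <- acc + c(bd$adv_G, if (is.na(bd$adv_D)) 0 else bd$adv_D,
                       bd$vr, bd$perceptual, bd$total_G)
      }
      acc <- acc / length(batches)
      val_vr <- if (length(val_batches) > 0) {
        mean(vapply(val_batches, function(b) {
          outs <- generator_forward(bundle$G, b$x, tape_new(FALSE))
          pred <- do.call(cbind, lapply(outs, function(o) o$v))
          sum(colMeans(abs(pred - b$y)))
        }, numeric(1)))
      } else NA_real_
      hist_rows[[epoch + 1L]] <- data.frame(
        epoch = epoch, lr = lr, adv_G = acc[1], adv_D = acc[2], vr = acc[3],
        perceptual = acc[4], total_G = acc[5], val_vr = val_vr,
        row.names = NULL)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  vr %.4f  val_vr %s", epoch, lr,
                        acc[3], format(val_vr)))
      if (!is.na(val_vr) && val_vr < best_val) {
        best_val <- val_vr
        best_epoch <- epoch
        best_state <- lapply(trainable, function(p) p$v)
      }
    }
  })
  if (!is.null(best_state)) {
    for (i in seq_along(trainable)) trainable[[i]]$v <- best_state[[i]]
  }
  history <- do.call(rbind, hist_rows)
  rownames(history) <- NULL
  list(bundle = bundle, history = history, best_epoch = best_epoch)
}

#' Predict the missing-timepoint image(s) for one subject
#'
#' @param object A [build_model_bundle()] result (usually trained by
#'   [fit_model()]).
#' @param newdata A normalized [volume()] (single-contrast bundles) or a
#'   list with elements `T1w` and `T2w` (mpgan).
#' @param ... Unused.
#' @return A [volume()] (one decoder) or named list of volumes (two
#'   decoders), with `age_tag` set to the target timepoint.
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  cons <- object$contrasts
  vols <- if (inherits(newdata, "volume")) list(newdata) else newdata
  if (length(vols) != length(cons))
    stop("bundle expects ", length(cons), " input contrast(s), got ",
         length(vols))
  if (!is.null(names(vols)) && all(nzchar(names(vols))))
    vols <- vols[cons]
  for (v in vols) {
    if (!inherits(v, "volume")) stop("inputs must be volume objects")
    if (!v$normalized) stop("inputs must be intensity-normalized to [-1, 1]")
  }
  ages <- direction_ages(object$direction)
  x <- as_tensor(vols)
  outs <- generator_forward(object$G, x, tape_new(FALSE))
  spacing <- vols[[1]]$spacing
  d <- vdim(x)
  res <- lapply(seq_along(outs), function(i) {
    volume(array(outs[[i]]$v, dim = d), spacing = spacing,
           contrast = cons[min(i, length(cons))], age_tag = ages[["target"]],
           normalized = TRUE)
  })
  if (length(res) == 1L) res[[1]] else stats::setNames(res, cons)
}

#' Complete a cohort by imputing missing timepoints
#'
#' Every subject with a missing timepoint receives predicted volume(s)
#' from the bundle matching the required direction.  Real data is never
#' overwritten; imputed records are flagged and may serve as training
#' examples, but incomplete subjects must live in the training split (an
#' error is raised otherwise, mirroring the rule that imputed data is
#' never used for testing).
#'
#' @param cohort A [generate_cohort()] result.
#' @param bundle_6to12,bundle_12to6 Trained bundles for the two prediction
#'   directions.
#' @return List with the completed `cohort` and an imputation `manifest`
#'   data.frame (subject_id, direction, imputed age_tag, contrasts).
#' @export
impute_cohort <- function(cohort, bundle_6to12, bundle_12to6) {
  rows <- list()
  for (id in names(cohort$subjects)) {
    s <- cohort$subjects[[id]]
    if (is.na(s$missing_tag)) next
    if (length(s$timepoints) == 0 ||
        all(vapply(s$timepoints, is.null, logical(1))))
      stop("subject ", id, " is missing both timepoints")
    if (s$split %in% c("val", "test"))
      stop("subject ", id, " with a missing timepoint is assigned to '",
           s$split, "'; imputed data must stay in the training split")
    if (!is.null(s$timepoints[[s$missing_tag]])) next  # nothing to do
    direction <- if (s$missing_tag == "12m") "6to12" else "12to6"
    bundle <- if (direction == "6to12") bundle_6to12 else bundle_12to6
    if (bundle$direction != direction)
      stop("bundle direction mismatch for subject ", id)
    ages <- direction_ages(direction)
    tin <- s$timepoints[[ages[["input"]]]]
    inputs <- lapply(bundle$contrasts, function(cn) tin[[cn]])
    names(inputs) <- bundle$contrasts
    if (any(vapply(inputs, is.null, logical(1))))
      stop("subject ", id, " lacks the input contrast(s) required")
    pred <- predict(bundle, if (length(inputs) == 1L) inputs[[1]] else inputs)
    if (inherits(pred, "volume")) pred <- stats::setNames(list(pred),
                                                          bundle$contrasts)
    tp <- pred
    tp$labels <- NULL
    tp$imputed <- TRUE
    cohort$subjects[[id]]$timepoints[[s$missing_tag]] <- tp
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = id, direction = direction, age_tag = s$missing_tag,
      contrasts = paste(bundle$contrasts, collapse = "+"),
      stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(subject_id = character(), direction = character(),
               age_tag = character(), contrasts = character(),
               stringsAsFactors = FALSE)
  list(cohort = cohort, manifest = manifest)
}

#' Reassign a subject's split, enforcing the imputation contract
#'
#' Subjects holding imputed data may not be placed in the validation or
#' test split.
#'
#' @param cohort A cohort.
#' @param subject_id Subject to move.
#' @param split `"train"`, `"val"`, or `"test"`.
#' @return The modified cohort.
#' @export
assign_split <- function(cohort, subject_id, split) {
  split <- match.arg(split, c("train", "val", "test"))
  s <- cohort$subjects[[subject_id]]
  if (is.null(s)) stop("unknown subject: ", subject_id)
  has_imputed <- any(vapply(s$timepoints, function(tp)
    isTRUE(tp$imputed), logical(1)))
  if (split %in% c("val", "test") &&
      (has_imputed || !is.na(s$missing_tag)))
    stop("subject ", subject_id,
         " holds imputed data and cannot be assigned to '", split, "'")
  cohort$subjects[[subject_id]]$split <- split
  cohort
}

#' Held-out voxel-wise reconstruction loss of a bundle
#'
#' @param bundle A model bundle.
#' @param cohort A cohort.
#' @param split Which split(s) to evaluate (default `"test"`).
#' @return Mean voxel-wise reconstruction loss over the complete subjects
#'   of the split.
#' @export
heldout_vr <- function(bundle, cohort, split = "test") {
  subs <- split_subjects(cohort, split, bundle$direction)
  if (length(subs) == 0) stop("no complete subjects in split ",
                              paste(split, collapse = "/"))
  mean(vapply(subs, function(s) {
    b <- make_example(s, bundle$direction, bundle$contrasts)
    outs <- generator_forward(bundle$G, b$x, tape_new(FALSE))
    pred <- do.call(cbind, lapply(outs, function(o) o$v))
    sum(colMeans(abs(pred - b$y)))
  }, numeric(1)))
}

#' Copy-input baseline reconstruction loss
#'
#' The loss obtained by predicting the target-age image as an unchanged
#' copy of the input-age image; the natural no-model reference for
#' longitudinal prediction.
#'
#' @param cohort A cohort.
#' @param split Split(s) to evaluate.
#' @param direction `"6to12"` or `"12to6"`.
#' @param contrasts Contrasts to include.
#' @return Mean voxel-wise reconstruction loss of the copy baseline.
#' @export
baseline_copy_vr <- function(cohort, split = "test", direction = "6to12",
                             contrasts = c("T1w", "T2w")) {
  subs <- split_subjects(cohort, split, direction)
  if (length(subs) == 0) stop("no complete subjects in split ",
                              paste(split, collapse = "/"))
  mean(vapply(subs, function(s) {
    b <- make_example(s, direction, contrasts)
    sum(colMeans(abs(b$x - b$y)))
  }, numeric(1)))
}
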