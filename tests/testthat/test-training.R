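test_that("the learning-rate schedule halves every decay interval", {
  cfg <- train_config(variant = "unet_lvr", gen_spec = slim_gen_spec())
  expect_equal(learning_rate(0, cfg), 2e-4)
  expect_equal(learning_rate(43, cfg), 2e-4)
  expect_equal(learning_rate(44, cfg), 1e-4)
  expect_equal(learning_rate(219, cfg), 2e-4 * 0.5^8)
  lrs <- vapply(0:219, learning_rate, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) <= 0))
  # piecewise constant with breakpoints exactly at 44, 66, ..., 198
  breaks <- which(diff(lrs) < 0)  # epoch index before each drop
  expect_equal(breaks, seq(44, 198, by = 22))
  expect_equal(length(breaks), 8L)
  expect_error(learning_rate(-1, cfg), "epoch")
  expect_error(learning_rate(220, cfg), "epoch")
})

test_that("train_step honours the variant's frozen-parameter contracts", {
  co <- cohort16(n = 3, split = c(1, 0, 0), seed = 41)
  batch <- longsynth:::make_example(co$subjects[[1]], "6to12", "T1w")

  cfg <- slim_train_config("unet_lvr", epochs = 1L)
  bundle <- build_model_bundle(cfg)
  d_before <- lapply(longsynth:::discriminator_params(bundle$D[[1]]),
                     function(p) p$v)
  phi_before <- lapply(longsynth:::feature_params(bundle$phi),
                       function(p) p$v)
  bd <- train_step(bundle, batch, cfg, lr = 5e-2)
  expect_identical(lapply(longsynth:::discriminator_params(bundle$D[[1]]),
                          function(p) p$v), d_before)
  expect_true(is.na(bd$adv_D))
  expect_true(is.finite(bd$total_G))

  cfg2 <- slim_train_config("pgan", epochs = 1L)
  bundle2 <- build_model_bundle(cfg2)
  phi_before2 <- lapply(longsynth:::feature_params(bundle2$phi),
                        function(p) p$v)
  d_before2 <- lapply(longsynth:::discriminator_params(bundle2$D[[1]]),
                      function(p) p$v)
  train_step(bundle2, batch, cfg2, lr = 5e-2)
  expect_identical(lapply(longsynth:::feature_params(bundle2$phi),
                          function(p) p$v), phi_before2)
  expect_false(identical(lapply(longsynth:::discriminator_params(bundle2$D[[1]]),
                                function(p) p$v), d_before2))
  expect_identical(lapply(longsynth:::feature_params(bundle$phi),
                          function(p) p$v), phi_before)
})

test_that("a train step is deterministic given seed and batch", {
  co <- cohort16(n = 3, split = c(1, 0, 0), seed = 41)
  batch <- longsynth:::make_example(co$subjects[[1]], "6to12", "T1w")
  cfg <- slim_train_config("pgan", epochs = 1L, seed = 17L)
  run_once <- function() {
    b <- build_model_bundle(cfg)
    train_step(b, batch, cfg, lr = 5e-2)
    lapply(longsynth:::generator_params(b$G), function(p) p$v)
  }
  expect_identical(run_once(), run_once())
})

test_that("with beta = 0 the perceptual variant reduces to gan_lvr at step 1", {
  co <- cohort16(n = 3, split = c(1, 0, 0), seed = 41)
  batch <- longsynth:::make_example(co$subjects[[1]], "6to12", "T1w")
  cfg_g <- slim_train_config("gan_lvr", epochs = 1L, seed = 19L)
  cfg_p <- slim_train_config("pgan", epochs = 1L, seed = 19L,
                             weights = loss_weights(25, 0))
  bg <- build_model_bundle(cfg_g)
  bp <- build_model_bundle(cfg_p)
  train_step(bg, batch, cfg_g, lr = 5e-2)
  train_step(bp, batch, cfg_p, lr = 5e-2)
  expect_identical(lapply(longsynth:::discriminator_params(bg$D[[1]]),
                          function(p) p$v),
                   lapply(longsynth:::discriminator_params(bp$D[[1]]),
                          function(p) p$v))
  expect_equal(lapply(longsynth:::generator_params(bg$G), function(p) p$v),
               lapply(longsynth:::generator_params(bp$G), function(p) p$v),
               tolerance = 1e-12)
})

test_that("fit_model keeps its bookkeeping and determinism promises", {
  co <- cohort16(n = 4, split = c(0.5, 0.25, 0.25), seed = 23)
  cfg <- slim_train_config("pgan", epochs = 3L, seed = 29L)
  fit <- fit_model(co, cfg)
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$total_G)))
  expect_true(all(is.finite(fit$history$val_vr)))
  expect_true(all(diff(fit$history$lr) <= 0))
  fit2 <- fit_model(co, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(
    lapply(longsynth:::generator_params(fit$bundle$G), function(p) p$v),
    lapply(longsynth:::generator_params(fit2$bundle$G), function(p) p$v))

  expect_error(fit_model(generate_cohort(co$spec, 3, 0, c(0, 2 / 3, 1 / 3)),
                         cfg), "training subjects")
})

test_that("short training reduces the reconstruction loss", {
  co <- cohort16(n = 3, split = c(1, 0, 0), seed = 37)
  cfg <- slim_train_config("unet_lvr", epochs = 8L, seed = 31L)
  fit <- fit_model(co, cfg)
  expect_lt(fit$history$vr[8], fit$history$vr[1])
})

test_that("predict enforces the bundle's input contract", {
  co <- cohort16(n = 3, split = c(1, 0, 0), seed = 41)
  cfg <- slim_train_config("mpgan", epochs = 1L)
  bundle <- build_model_bundle(cfg)
  tp6 <- co$subjects[[1]]$timepoints[["6m"]]
  pred <- predict(bundle, list(T1w = tp6$T1w, T2w = tp6$T2w))
  expect_named(pred, c("T1w", "T2w"))
  expect_identical(pred$T1w$age_tag, "12m")
  expect_true(all(abs(pred$T1w$data) < 1))
  expect_true(pred$T2w$normalized)
  # arity and normalization violations
  expect_error(predict(bundle, tp6$T1w), "contrast")
  pg <- build_model_bundle(slim_train_config("pgan", epochs = 1L))
  expect_error(predict(pg, list(T1w = tp6$T1w, T2w = tp6$T2w)), "contrast")
  raw <- volume(array(stats::runif(16^3, 0, 10), c(16, 16, 16)))
  expect_error(predict(pg, raw), "normalized")
})

test_that("impute_cohort completes a cohort under the split contract", {
  co <- cohort16(n = 10, missing_fraction = 0.4, split = c(0.6, 0.2, 0.2),
                 seed = 31)
  b612 <- cached("imp_b612", fit_model(co, slim_train_config(
    "mpgan", "6to12", epochs = 1L, seed = 43L))$bundle)
  b126 <- cached("imp_b126", fit_model(co, slim_train_config(
    "mpgan", "12to6", epochs = 1L, seed = 44L))$bundle)

  untouched <- Filter(function(s) is.na(s$missing_tag), co$subjects)[[1]]
  res <- impute_cohort(co, b612, b126)
  expect_equal(nrow(res$manifest), 4L)
  expect_equal(sort(table(res$manifest$direction), decreasing = TRUE),
               sort(table(c("6to12", "6to12", "12to6", "12to6")),
                    decreasing = TRUE))
  done <- res$cohort$subjects
  expect_true(all(vapply(done, function(s)
    !is.null(s$timepoints[["6m"]]) && !is.null(s$timepoints[["12m"]]),
    logical(1))))
  for (id in res$manifest$subject_id) {
    s <- done[[id]]
    expect_identical(s$split, "train")
    expect_true(isTRUE(s$timepoints[[s$missing_tag]]$imputed))
  }
  # real data untouched
  expect_identical(done[[untouched$subject_id]]$timepoints[["6m"]]$T1w$data,
                   untouched$timepoints[["6m"]]$T1w$data)

  # a complete cohort is a no-op
  co0 <- cohort16(n = 3, split = c(1, 0, 0), seed = 41)
  res0 <- impute_cohort(co0, b612, b126)
  expect_equal(nrow(res0$manifest), 0L)
  expect_identical(res0$cohort$subjects[[1]]$timepoints[["6m"]]$T1w$data,
                   co0$subjects[[1]]$timepoints[["6m"]]$T1w$data)

  # incomplete subject parked in val/test is refused
  bad <- co
  vic <- names(Filter(function(s) !is.na(s$missing_tag), bad$subjects))[1]
  bad$subjects[[vic]]$split <- "test"
  expect_error(impute_cohort(bad, b612, b126), "training split")

  # subject with no data at all is refused
  bad2 <- co
  bad2$subjects[[vic]]$timepoints <- list()
  expect_error(impute_cohort(bad2, b612, b126), "both timepoints")

  # imputed subjects cannot be moved into the test split afterwards
  expect_error(assign_split(res$cohort, res$manifest$subject_id[1], "test"),
               "imputed")
  moved <- assign_split(res$cohort, untouched$subject_id, "val")
  expect_identical(moved$subjects[[untouched$subject_id]]$split, "val")
})
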