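test_that("subject generation is a pure function of (spec, seed)", {
  spec <- phantom_spec(shape = c(16, 16, 16), seed = 2)
  a <- generate_subject(spec, 77, "a")
  b <- generate_subject(spec, 77, "a")
  expect_identical(a$timepoints[["6m"]]$T1w$data, b$timepoints[["6m"]]$T1w$data)
  expect_identical(a$timepoints[["12m"]]$T2w$data, b$timepoints[["12m"]]$T2w$data)
  expect_identical(a$timepoints[["6m"]]$labels$data,
                   b$timepoints[["6m"]]$labels$data)
  c <- generate_subject(spec, 78, "a")
  expect_false(identical(a$timepoints[["6m"]]$T1w$data,
                         c$timepoints[["6m"]]$T1w$data))
})

test_that("12-month brain volume reflects the growth factor", {
  spec <- phantom_spec(shape = c(32, 32, 32), seed = 5)
  s <- cached("growth_subject", generate_subject(spec, 123, "g"))
  n6 <- sum(s$timepoints[["6m"]]$labels$data > 0)
  n12 <- sum(s$timepoints[["12m"]]$labels$data > 0)
  expect_lt(abs(n12 / n6 - spec$growth_factor^3) / spec$growth_factor^3, 0.1)
})

test_that("noise-free unsmoothed intensities equal the per-label means", {
  tp0 <- default_tissue_params()
  tp0$sd[] <- 0
  spec0 <- phantom_spec(shape = c(32, 32, 32), tissue_params = tp0,
                        smoothing_fwhm = 0, seed = 5)
  s0 <- generate_subject(spec0, 7, "nf")
  for (age in c("6m", "12m")) {
    for (con in c("T1w", "T2w")) {
      col <- paste0(if (con == "T1w") "t1_" else "t2_", age)
      raw <- tp0[[col]]
      a <- 2 / (max(raw) - min(raw))
      b <- -1 - a * min(raw)
      lab <- s0$timepoints[[age]]$labels$data
      expected <- ifelse(lab == 0, -1, a * raw[pmax(lab, 1L)] + b)
      expect_equal(max(abs(s0$timepoints[[age]][[con]]$data - expected)), 0)
    }
  }
})

test_that("generated volumes satisfy the container invariants", {
  s <- cached("growth_subject",
              generate_subject(phantom_spec(shape = c(32, 32, 32), seed = 5),
                               123, "g"))
  for (age in c("6m", "12m")) {
    tp <- s$timepoints[[age]]
    for (con in c("T1w", "T2w")) {
      expect_true(tp[[con]]$normalized)
      expect_gte(min(tp[[con]]$data), -1)
      expect_lte(max(tp[[con]]$data), 1)
      expect_identical(dim(tp[[con]]$data), dim(tp$labels$data))
      expect_equal(tp[[con]]$spacing, tp$labels$spacing)
    }
    expect_true(all(sort(unique(as.vector(tp$labels$data))) %in% 0:10))
  }
})

test_that("the T2-like contrast separates WM/cortical GM better at 6 months", {
  # premise of the multi-contrast design: complementary information
  tp <- default_tissue_params()
  nrm <- function(x) 2 * (x - min(x)) / (max(x) - min(x)) - 1
  t1 <- nrm(tp$t1_6m)
  t2 <- nrm(tp$t2_6m)
  i <- match("wm", tp$tissue)
  j <- match("cortical_gm", tp$tissue)
  expect_gt(abs(t2[i] - t2[j]), abs(t1[i] - t1[j]))
})

test_that("cohort missingness and splits follow the contract", {
  co0 <- cohort16(n = 10, missing_fraction = 0, split = c(0.6, 0.2, 0.2),
                  seed = 31)
  expect_true(all(vapply(co0$subjects, function(s)
    is.na(s$missing_tag), logical(1))))
  expect_true(all(vapply(co0$subjects, function(s)
    length(s$timepoints) == 2L, logical(1))))

  co <- cohort16(n = 10, missing_fraction = 0.4, split = c(0.6, 0.2, 0.2),
                 seed = 31)
  miss <- Filter(function(s) !is.na(s$missing_tag), co$subjects)
  expect_length(miss, 4L)
  expect_true(all(vapply(miss, function(s) s$split == "train", logical(1))))
  tags <- sort(unname(vapply(miss, function(s) s$missing_tag, character(1))))
  expect_equal(tags, c("12m", "12m", "6m", "6m"))  # alternating directions
  for (s in miss) expect_null(s$timepoints[[s$missing_tag]])
  splits <- table(vapply(co$subjects, function(s) s$split, character(1)))
  expect_equal(as.vector(splits[c("train", "val", "test")]), c(6L, 2L, 2L))
})

test_that("cohort generation is deterministic", {
  spec <- phantom_spec(shape = c(16, 16, 16), seed = 8)
  a <- generate_cohort(spec, 4, 0.25, c(0.5, 0.25, 0.25))
  b <- generate_cohort(spec, 4, 0.25, c(0.5, 0.25, 0.25))
  expect_identical(vapply(a$subjects, function(s) s$split, character(1)),
                   vapply(b$subjects, function(s) s$split, character(1)))
  expect_identical(vapply(a$subjects, function(s) s$missing_tag, character(1)),
                   vapply(b$subjects, function(s) s$missing_tag, character(1)))
  expect_identical(a$subjects[[1]]$timepoints[["6m"]]$T1w$data,
                   b$subjects[[1]]$timepoints[["6m"]]$T1w$data)
})

test_that("invalid phantom and cohort configurations are rejected", {
  expect_error(phantom_spec(shape = c(30, 32, 32)), "divisible by 8")
  expect_error(phantom_spec(growth_factor = 0.9), "growth_factor")
  tp <- default_tissue_params()
  tp$t1_6m[2] <- tp$t1_6m[1]
  expect_error(phantom_spec(tissue_params = tp), "distinct")
  spec <- phantom_spec(shape = c(16, 16, 16))
  expect_error(generate_cohort(spec, 2, 0, c(1, 0, 0)), ">= 3")
  expect_error(generate_cohort(spec, 5, 0, c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(generate_cohort(spec, 5, 0.9, c(0.2, 0.4, 0.4)),
               "not enough complete")
})

test_that("a cohort writes a complete manifest tree", {
  co <- generate_cohort(phantom_spec(shape = c(16, 16, 16), seed = 3), 3, 0,
                        c(1, 0, 0))
  dir <- tempfile("cohorttree")
  manifest <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 3 * 2 * 3)  # 3 subjects x 2 ages x (T1,T2,labels)
  expect_true(all(file.exists(manifest$path)))
  v <- read_volume(manifest$path[manifest$contrast == "T1w"][1])
  expect_identical(dim(v$data), c(16L, 16L, 16L))

  # and reads back with identical data, splits, and missingness
  co2 <- read_cohort(dir)
  expect_identical(names(co2$subjects), names(co$subjects))
  expect_equal(co2$subjects[[1]]$timepoints[["6m"]]$T1w$data,
               co$subjects[[1]]$timepoints[["6m"]]$T1w$data)
  expect_identical(co2$subjects[[1]]$timepoints[["12m"]]$labels$data,
                   co$subjects[[1]]$timepoints[["12m"]]$labels$data)
  expect_equal(co2$spec$growth_factor, co$spec$growth_factor)
})
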