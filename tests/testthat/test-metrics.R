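cube_mask <- function(d, from, to) {
  m <- array(FALSE, d)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}

test_that("volume difference is the asymmetric reference-relative percent", {
  d <- c(10, 10, 10)
  m100 <- cube_mask(d, c(1, 1, 1), c(5, 5, 4))   # 100 voxels
  m80 <- cube_mask(d, c(1, 1, 1), c(5, 4, 4))    # 80 voxels
  expect_equal(avd(m100, m100), 0)
  expect_equal(avd(m100, m80), 20)
  expect_equal(avd(m80, m100), 25)
  expect_error(avd(array(FALSE, d), m80), "empty")
  # voxel volume cancels: same value under anisotropic spacing
  expect_equal(avd(binary_mask(m100, c(0.5, 2, 1.3)),
                   binary_mask(m80, c(0.5, 2, 1.3))), 20)
})

test_that("border voxels follow the 6-connected face definition", {
  d <- c(9, 9, 9)
  single <- array(FALSE, d)
  single[4, 5, 6] <- TRUE
  expect_identical(border_voxels(binary_mask(single))$data, single)

  solid <- cube_mask(d, c(2, 2, 2), c(6, 6, 6))   # 5^3 cube
  b <- border_voxels(binary_mask(solid))$data
  expect_equal(sum(b), 125 - 27)
  expect_identical(b, brute_border(solid))

  plane <- array(FALSE, d)
  plane[, , 5] <- TRUE
  expect_identical(border_voxels(binary_mask(plane))$data, plane)

  # grid boundary counts as background; only the centre voxel is interior
  full <- array(TRUE, c(3, 3, 3))
  bf <- border_voxels(binary_mask(full))$data
  expect_equal(sum(bf), 26)
  expect_false(bf[2, 2, 2])
})

test_that("surface distance matches closed forms and the O(n^2) oracle", {
  d <- c(12, 12, 12)
  m <- cube_mask(d, c(3, 3, 3), c(8, 8, 8))
  expect_equal(asd(m, m), 0)

  a <- array(FALSE, d)
  a[2, 5, 5] <- TRUE
  b <- array(FALSE, d)
  b[5, 5, 5] <- TRUE
  expect_equal(asd(a, b), 3)
  # anisotropic spacing scales the single-pair distance
  expect_equal(asd(binary_mask(a, c(1.5, 1, 1)), binary_mask(b, c(1.5, 1, 1))),
               4.5)
  expect_error(asd(array(FALSE, d), b), "empty")

  for (seed in 1:6) {
    m1 <- random_mask(d, seed = seed)
    m2 <- random_mask(d, seed = seed + 100)
    sp <- if (seed %% 2 == 0) c(1, 1, 1) else c(1.2, 0.9, 1.5)
    expect_equal(asd(binary_mask(m1, sp), binary_mask(m2, sp)),
                 brute_asd(m1, m2, sp), tolerance = 1e-9)
  }
})

test_that("overlap metrics match exact set-count formulas", {
  d <- c(10, 10, 10)
  m1 <- cube_mask(d, c(1, 1, 1), c(2, 2, 2))          # 8 voxels
  m2 <- cube_mask(d, c(1, 1, 2), c(2, 2, 3))          # 8 voxels, 4 shared
  expect_equal(dice(m1, m1), 1)
  expect_equal(dice(m1, m2), 0.5)
  disj <- cube_mask(d, c(5, 5, 5), c(6, 6, 6))
  expect_equal(dice(m1, disj), 0)
  expect_error(dice(array(FALSE, d), array(FALSE, d)), "empty")

  expect_equal(tanimoto_error(m1, m1), 0)
  expect_equal(tanimoto_error(m1, disj), 100)
  expect_equal(tanimoto_error(m1, m2), (12 - 4) / 12 * 100)
  expect_error(tanimoto_error(array(FALSE, d), array(FALSE, d)), "empty")
})

test_that("metric symmetries and identities hold on random masks", {
  d <- c(12, 12, 12)
  for (seed in 1:8) {
    m1 <- random_mask(d, seed = seed + 200)
    m2 <- random_mask(d, seed = seed + 300)
    expect_equal(dice(m1, m2), dice(m2, m1))
    expect_equal(tanimoto_error(m1, m2), tanimoto_error(m2, m1))
    expect_equal(asd(m1, m2), asd(m2, m1), tolerance = 1e-12)
    # Dice-Tanimoto algebraic identity
    dc <- dice(m1, m2)
    expect_equal(tanimoto_error(m1, m2) / 100, 1 - dc / (2 - dc),
                 tolerance = 1e-12)
  }
  # avd is asymmetric whenever the volumes differ
  m1 <- cube_mask(d, c(1, 1, 1), c(4, 4, 4))
  m2 <- cube_mask(d, c(1, 1, 1), c(4, 4, 3))
  expect_false(isTRUE(all.equal(avd(m1, m2), avd(m2, m1))))
})

test_that("eroding one mask degrades ASD and Dice monotonically", {
  d <- c(14, 14, 14)
  ref <- cube_mask(d, c(3, 3, 3), c(11, 11, 11))
  prev_asd <- 0
  prev_dice <- 1
  for (shrink in 0:3) {
    er <- cube_mask(d, c(3, 3, 3) + shrink, c(11, 11, 11) - shrink)
    cur_asd <- asd(ref, er)
    cur_dice <- dice(ref, er)
    expect_gte(cur_asd, prev_asd)
    expect_lte(cur_dice, prev_dice)
    prev_asd <- cur_asd
    prev_dice <- cur_dice
  }
})

test_that("the fused score is calibrated by the expert reference constants", {
  expect_identical(fused_score(5.6, 0.27, 15.8), 1)
  expect_identical(fused_score(0, 0, 0), 0)
  expect_equal(fused_score(11.2, 0.54, 31.6), 2)
  expect_equal(fused_score(5.6, 0, 0), 1 / 3)
  expect_error(fused_score(-1, 0.2, 5), ">= 0")
  expect_error(metric_refs(0, 0.27, 15.8), "positive")
})

test_that("per-structure reports cover every label and flag empty ones", {
  spec <- phantom_spec(shape = c(16, 16, 16), seed = 9)
  s <- generate_subject(spec, 55, "m")
  lab <- s$timepoints[["6m"]]$labels

  same <- per_structure_report(lab, lab)
  ok <- same[same$defined, ]
  expect_true(all(ok$Dice == 1))
  expect_true(all(ok$AVD == 0 & ok$ASD == 0 & ok$TanimotoError == 0 &
                    ok$FusedScore == 0))

  # shifted copy: every defined row matches per-label brute-force oracles
  shifted <- lab
  shifted$data <- lab$data[c(16, 1:15), , ]
  rep <- per_structure_report(lab, shifted)
  for (i in which(rep$defined)) {
    lb <- rep$label[i]
    m_ref <- shifted$data == lb   # ref_labels argument
    m_prd <- lab$data == lb
    expect_equal(rep$AVD[i],
                 abs(sum(m_ref) - sum(m_prd)) / sum(m_ref) * 100)
    expect_equal(rep$Dice[i],
                 2 * sum(m_ref & m_prd) / (sum(m_ref) + sum(m_prd)))
    expect_equal(rep$ASD[i], brute_asd(m_prd, m_ref), tolerance = 1e-9)
  }
  expect_true(is.data.frame(attr(rep, "summary")))

  # a structure absent from one map is reported undefined, not dropped
  gone <- lab
  gone$data[gone$data == 5L] <- 3L
  rep2 <- per_structure_report(gone, lab)
  row5 <- rep2[rep2$label == 5L, ]
  expect_false(row5$defined)
  expect_true(is.na(row5$Dice))
  expect_equal(nrow(rep2), nrow(same))

  bad <- lab
  names(bad$label_names)[1] <- "99"
  expect_error(per_structure_report(bad, lab), "vocabular")
})
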