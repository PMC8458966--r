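test_that("generator preserves grid shape and bounds output with tanh", {
  g <- build_generator(slim_gen_spec(), seed = 1)
  x <- array(stats::rnorm(32^3, 0, 0.5), c(32, 32, 32))
  outs <- generator_forward(g, x)
  expect_length(outs, 1L)
  expect_identical(longsynth:::vdim(outs[[1]]$v), c(32L, 32L, 32L))
  expect_gt(min(outs[[1]]$v), -1)
  expect_lt(max(outs[[1]]$v), 1)

  # all-zero input also stays strictly inside (-1, 1)
  o0 <- generator_forward(g, array(0, c(16, 16, 16)))[[1]]$v
  expect_true(all(o0 > -1 & o0 < 1))

  expect_error(generator_forward(g, array(0, c(20, 20, 20))), "divisible by 8")
  expect_error(generator_forward(build_generator(slim_gen_spec(2, 2)),
                                 array(0, c(16, 16, 16))),
               "contrast")
})

test_that("the dual-decoder generator has independent decoders over one encoder", {
  g <- build_generator(slim_gen_spec(2, 2), seed = 4)
  x <- matrix(stats::rnorm(16^3 * 2, 0, 0.5), 16^3, 2)
  attr(x, "vdim") <- c(16L, 16L, 16L)
  before <- generator_forward(g, x)
  # zero decoder 2's parameters: output 2 changes, output 1 does not
  for (p in longsynth:::layers_params(g$decoders[[2]]$convs)) p$v <- p$v * 0
  after <- generator_forward(g, x)
  expect_identical(before[[1]]$v, after[[1]]$v)
  expect_false(identical(before[[2]]$v, after[[2]]$v))
})

test_that("both decoders reference the identical shared-encoder parameters", {
  g <- build_generator(slim_gen_spec(2, 2), seed = 4)
  enc <- encoder_params(g)
  p1 <- longsynth:::generator_params(g, decoder = 1)
  p2 <- longsynth:::generator_params(g, decoder = 2)
  for (p in enc) {
    expect_true(any(vapply(p1, identical, logical(1), p)))
    expect_true(any(vapply(p2, identical, logical(1), p)))
  }
  # mutating the shared encoder through one view is seen by the other
  x <- matrix(stats::rnorm(16^3 * 2), 16^3, 2)
  attr(x, "vdim") <- c(16L, 16L, 16L)
  o2_before <- generator_forward(g, x)[[2]]$v
  p1[[1]]$v <- p1[[1]]$v * 0
  o2_after <- generator_forward(g, x)[[2]]$v
  expect_false(identical(o2_before, o2_after))
})

test_that("discriminator maps grids to sigmoid-bounded patch score maps", {
  d <- build_discriminator(slim_disc_spec(), seed = 2)
  s32 <- discriminator_forward(d, array(stats::rnorm(32^3), c(32, 32, 32)))
  expect_identical(longsynth:::vdim(s32$v), c(2L, 2L, 2L))
  expect_gt(min(s32$v), 0)
  expect_lt(max(s32$v), 1)
  s64 <- discriminator_forward(d, array(stats::rnorm(64^3, 0, 0.3),
                                        c(64, 64, 64)))
  expect_identical(longsynth:::vdim(s64$v), c(4L, 4L, 4L))
  expect_error(discriminator_forward(d, array(0, c(8, 8, 8))), "at least 16")
})

test_that("the feature extractor has the documented shapes and is frozen", {
  phi <- build_feature_extractor(slim_feat_spec(), seed = 3)
  x <- array(stats::rnorm(32^3, 0, 0.4), c(32, 32, 32))
  f1 <- phi_features(phi, x, 1)
  expect_identical(longsynth:::vdim(f1), c(16L, 16L, 16L))
  expect_equal(ncol(f1), 8L)     # second channel of block 1
  f4 <- phi_features(phi, x, 4)
  expect_identical(longsynth:::vdim(f4), c(4L, 4L, 4L))
  expect_equal(ncol(f4), 64L)
  # deterministic: same input, same features
  expect_identical(f1, phi_features(phi, x, 1))
  expect_true(all(vapply(longsynth:::feature_params(phi),
                         function(p) isTRUE(p$frozen), logical(1))))
  expect_error(phi_features(phi, x, 5), "1..4")
})

test_that("parameter counts match closed-form arithmetic from the spec", {
  count_gen <- function(spec) {
    e <- spec$encoder_channels
    dch <- spec$decoder_channels
    ein <- c(spec$in_contrasts, e[-8])
    enc <- sum(27 * ein * e + e)
    din <- c(e[8] + e[6], dch[1], dch[2] + e[4], dch[3], dch[4] + e[2], dch[5])
    dec <- sum(27 * din * dch + dch) + (dch[6] * 1 + 1)
    enc + spec$out_decoders * dec
  }
  for (spec in list(generator_spec(), slim_gen_spec(2, 2))) {
    expect_equal(param_count(build_generator(spec, seed = 1)),
                 count_gen(spec))
  }
  # frozen regression values for the default (full-width) builders
  expect_equal(param_count(build_generator(generator_spec(), seed = 1)),
               6374041)
  ch <- c(64, 128, 256, 512)
  expect_equal(param_count(build_discriminator(seed = 1)),
               sum(64 * c(1, ch[-4]) * ch + ch) + (64 * 512 + 1))
  expect_equal(param_count(build_discriminator(seed = 1)), 11047873)
  expect_equal(param_count(build_feature_extractor(seed = 1)), 7024896)
})

test_that("the norm-free convolutional path is shift-equivariant", {
  # instance normalization intentionally breaks strict equivariance
  # (global statistics); the convolutional path is checked without it.
  g <- build_generator(slim_gen_spec(norm = FALSE), seed = 2)
  set.seed(4)
  x <- array(stats::rnorm(32^3, 0, 0.5), c(32, 32, 32))
  xs <- x[c(25:32, 1:24), , ]  # circular shift by one downsampling period
  o1 <- array(generator_forward(g, x)[[1]]$v, c(32, 32, 32))
  o2 <- array(generator_forward(g, xs)[[1]]$v, c(32, 32, 32))[c(9:32, 1:8), , ]
  cc <- 13:20
  expect_lt(max(abs(o1[cc, cc, cc] - o2[cc, cc, cc])), 1e-4)
})

test_that("weight checkpoints round-trip and reject mismatched architectures", {
  g <- build_generator(slim_gen_spec(), seed = 9)
  x <- array(stats::rnorm(16^3, 0, 0.5), c(16, 16, 16))
  o <- generator_forward(g, x)[[1]]$v
  f <- tempfile(fileext = ".rds")
  save_weights(g, f)
  g2 <- build_generator(slim_gen_spec(), seed = 10)
  expect_false(identical(generator_forward(g2, x)[[1]]$v, o))
  load_weights(g2, f)
  expect_identical(generator_forward(g2, x)[[1]]$v, o)
  g3 <- build_generator(generator_spec(), seed = 1)
  expect_error(load_weights(g3, f), "match")
})
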