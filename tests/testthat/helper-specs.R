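# Shared fixtures: narrow-width network specs for desk-scale runs, cached
# phantom cohorts (built once per test run), and independent brute-force
# oracles for the surface-distance metric.

slim_gen_spec <- function(in_contrasts = 1L, out_decoders = 1L, norm = TRUE) {
  generator_spec(in_contrasts, out_decoders,
                 encoder_channels = c(4, 8, 8, 16, 16, 32, 32, 64),
                 decoder_channels = c(32, 32, 16, 16, 8, 8), norm = norm)
}

slim_disc_spec <- function() discriminator_spec(c(8, 16, 32, 64))

slim_feat_spec <- function() {
  feature_extractor_spec(list(c(4, 8), c(8, 16), c(16, 32), c(32, 64)))
}

slim_train_config <- function(variant = "pgan", direction = "6to12",
                              epochs = 2L, seed = 3L, lr0 = 5e-2, ...) {
  nc <- if (variant == "mpgan") 2L else 1L
  train_config(variant = variant, direction = direction, epochs = epochs,
               seed = seed, lr0 = lr0,
               gen_spec = slim_gen_spec(nc, nc),
               disc_spec = slim_disc_spec(),
               feat_spec = slim_feat_spec(), ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

cohort16 <- function(n = 6, missing_fraction = 0,
                     split = c(2 / 3, 1 / 6, 1 / 6), seed = 21L) {
  key <- paste("c16", n, missing_fraction, paste(round(split, 3),
                                                 collapse = "-"), seed)
  cached(key, generate_cohort(
    phantom_spec(shape = c(16, 16, 16), seed = seed), n,
    missing_fraction, split))
}

rand_volume <- function(d = c(16, 16, 16), seed = 1, min = 0.1, max = 5) {
  set.seed(seed)
  volume(array(stats::runif(prod(d), min, max), d))
}

# Independent border oracle: exhaustive 6-neighbour scan.
brute_border <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!m[x, y, z]) next
    nb <- list(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
               c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
    for (p in nb) {
      if (any(p < 1) || p[1] > d[1] || p[2] > d[2] || p[3] > d[3] ||
          !m[p[1], p[2], p[3]]) {
        out[x, y, z] <- TRUE
        break
      }
    }
  }
  out
}

# O(n^2) surface-distance oracle over all border-voxel pairs, computed
# with direct coordinate differences (no |a|^2+|b|^2-2ab expansion, which
# loses precision to cancellation).
brute_asd <- function(m1, m2, spacing = c(1, 1, 1)) {
  b1 <- which(brute_border(m1), arr.ind = TRUE)
  b2 <- which(brute_border(m2), arr.ind = TRUE)
  p1 <- sweep(b1, 2, spacing, "*")
  p2 <- sweep(b2, 2, spacing, "*")
  d12 <- matrix(0, nrow(p1), nrow(p2))
  for (i in seq_len(nrow(p1))) {
    d12[i, ] <- sqrt((p2[, 1] - p1[i, 1])^2 + (p2[, 2] - p1[i, 2])^2 +
                       (p2[, 3] - p1[i, 3])^2)
  }
  (sum(apply(d12, 1, min)) + sum(apply(d12, 2, min))) /
    (nrow(p1) + nrow(p2))
}

random_mask <- function(d = c(12, 12, 12), seed = 1, p = 0.3) {
  set.seed(seed)
  m <- array(stats::runif(prod(d)) < p, d)
  if (!any(m)) m[5, 5, 5] <- TRUE
  m
}
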