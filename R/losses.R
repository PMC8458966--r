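# Composite training objective: least-squares adversarial terms, voxel-wise
# L1 reconstruction, and the perceptual (feature-space L1) loss, combined
# as  total_G = L_adv(G) + alpha * L_vr + beta * L_p.
#
# Expectations are realized as means over the current batch and over the
# spatial positions of the discriminator score map; L1 norms are averaged
# (not summed) over voxels/feature elements so that alpha and beta are
# resolution-independent.  The printed minmax objective has D ascending on
# (1 - D(G(x)))^2 + D(y)^2; the equivalent descent losses implemented here,
# adv_D = mean((1 - D(y))^2) + mean(D(G(x))^2)  and
# adv_G = mean((1 - D(G(x)))^2),
# share its optima (D(real) -> 1, D(fake) -> 0 under a sigmoid-bounded D).
# Set literal_ascent = TRUE for the ascent form as printed.

#' Loss weighting configuration
#'
#' @param alpha Weight of the voxel-wise reconstruction (L1) loss
#'   (default 25).
#' @param beta Weight of the perceptual loss (default 25).
#' @param feature_layer Feature-extractor layer m in 1..4 used for the
#'   perceptual loss (default 1).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 25, beta = 25, feature_layer = 1L) {
  if (!is.finite(alpha) || alpha < 0 || !is.finite(beta) || beta < 0)
    stop("alpha and beta must be finite and >= 0")
  if (!feature_layer %in% 1:4) stop("feature_layer must be in 1..4")
  structure(list(alpha = alpha, beta = beta,
                 feature_layer = as.integer(feature_layer)),
            class = "loss_weights")
}

#' Adversarial loss terms from discriminator score maps
#'
#' @param d_real,d_fake Score maps (numeric arrays/matrices of identical
#'   shape, values in (0, 1)) for the real target and the generated image.
#' @param literal_ascent Return `adv_D` in the ascent form
#'   `mean((1-d_fake)^2) + mean(d_real^2)` exactly as the minmax objective
#'   is written, rather than the equivalent descent form.
#' @return List with non-negative `adv_G` and `adv_D`.
#' @export
adversarial_terms <- function(d_real, d_fake, literal_ascent = FALSE) {
  if (!identical(dim2(d_real), dim2(d_fake)))
    stop("score maps must have identical shapes")
  adv_g <- mean((1 - d_fake)^2)
  adv_d <- if (literal_ascent) {
    mean((1 - d_fake)^2) + mean(d_real^2)
  } else {
    mean((1 - d_real)^2) + mean(d_fake^2)
  }
  list(adv_G = adv_g, adv_D = adv_d)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

loss_values <- function(x) {
  if (inherits(x, "volume")) return(list(x$data))
  if (is.list(x)) return(lapply(x, function(v)
    if (inherits(v, "volume")) v$data else v))
  list(x)
}

#' Voxel-wise reconstruction loss (L1)
#'
#' Mean absolute voxel difference per contrast, summed over contrasts in
#' the dual-contrast form.  Zero iff predicted equals target everywhere.
#'
#' @param predicted,target A [volume()]/array, or a list of them (one per
#'   contrast, matched by position).
#' @return Non-negative scalar.
#' @export
voxel_reconstruction_loss <- function(predicted, target) {
  p <- loss_values(predicted)
  t <- loss_values(target)
  if (length(p) != length(t)) stop("contrast counts differ")
  total <- 0
  for (i in seq_along(p)) {
    if (!identical(dim2(p[[i]]), dim2(t[[i]])))
      stop("predicted and target shapes differ")
    total <- total + mean(abs(p[[i]] - t[[i]]))
  }
  total
}

#' Perceptual loss (feature-space L1)
#'
#' Mean absolute difference between the feature maps phi_m of target and
#' predicted images, summed over contrasts in the dual-contrast form.
#'
#' @param phi A [build_feature_extractor()] result.
#' @param predicted,target Volumes/arrays or per-contrast lists thereof.
#' @param m Feature layer index in 1..4.
#' @return Non-negative scalar.
#' @export
perceptual_loss <- function(phi, predicted, target, m = 1L) {
  if (!m %in% 1:4) stop("feature layer m must be in 1..4")
  p <- loss_values(predicted)
  t <- loss_values(target)
  if (length(p) != length(t)) stop("contrast counts differ")
  total <- 0
  for (i in seq_along(p)) {
    fp <- phi_features(phi, array(p[[i]], dim = dim2(p[[i]])), m)
    ft <- phi_features(phi, array(t[[i]], dim = dim2(t[[i]])), m)
    total <- total + mean(abs(ft - fp))
  }
  total
}

#' Combine loss terms into the total generator objective
#'
#' `total_G = adv_G + alpha * vr + beta * perceptual`.  In the
#' multi-contrast setting `adv_G` is the sum of the per-contrast generator
#' adversarial terms.
#'
#' @param adv_G,adv_D,vr,perceptual Component values computed on the same
#'   batch.
#' @param weights A [loss_weights()].
#' @return A `loss_breakdown` list with the components and `total_G`.
#' @export
total_generator_objective <- function(adv_G, vr, perceptual,
                                      weights = loss_weights(),
                                      adv_D = NA_real_) {
  stopifnot(inherits(weights, "loss_weights"))
  structure(
    list(adv_G = adv_G, adv_D = adv_D, vr = vr, perceptual = perceptual,
         total_G = adv_G + weights$alpha * vr + weights$beta * perceptual),
    class = "loss_breakdown"
  )
}
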