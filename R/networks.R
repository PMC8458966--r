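# Network builders: 3D U-Net generator (single-contrast, and multi-contrast
# with a shared encoder and two independent decoders), the 4-layer stride-2
# patch discriminator, and the encoder-style perceptual feature extractor.
#
# All convolutions use same-padding (kernel 3: pad 1/1; kernel 4 stride 2:
# pad 1/1 halves each axis; kernel 4 stride 1: asymmetric pad 1/2 preserves
# the axis), so the U-Net maps a grid to a grid of identical shape.
# Upsampling is nearest-neighbour followed by a 3x3x3 convolution.  Weights
# are zero-mean Gaussian (sd 0.02), biases zero, seed-controlled.

new_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, plo = 1L, phi = 1L,
                     inorm = TRUE, act = "relu", slope = 0.2) {
  W <- new_leaf(matrix(stats::rnorm(k^3 * in_ch * out_ch, 0, 0.02),
                       k^3 * in_ch, out_ch))
  b <- new_leaf(numeric(out_ch))
  list(W = W, b = b, k = k, stride = stride, plo = plo, phi = phi,
       inorm = inorm, act = act, slope = slope,
       in_ch = in_ch, out_ch = out_ch)
}

conv_apply <- function(tape, x, ly) {
  z <- op_conv3(tape, x, ly$W, ly$b, ly$k, ly$stride, ly$plo, ly$phi)
  if (ly$inorm) z <- op_inorm(tape, z)
  if (ly$act != "none") z <- op_act(tape, z, ly$act, ly$slope)
  z
}

conv_params <- function(ly) list(ly$W, ly$b)

layers_params <- function(layers) {
  do.call(c, lapply(layers, conv_params))
}

#' Generator architecture specification
#'
#' Describes the 3D U-Net generator: an 8-convolution encoder with three
#' 2x max-pool downsamplings, and per decoder six convolutions with three
#' nearest-neighbour upsamplings, skip connections from the pre-pool
#' encoder features, and a final 1x1x1 convolution with tanh.  With
#' `out_decoders = 2` the two decoders share the single encoder (the
#' multi-contrast configuration).
#'
#' @param in_contrasts 1 (single contrast) or 2 (channel-wise concatenated
#'   T1w + T2w input, T1 first).
#' @param out_decoders 1 or 2 independent decoders over the shared encoder.
#' @param encoder_channels Eight output-channel counts of the encoder
#'   convolutions.
#' @param decoder_channels Six output-channel counts of each decoder's
#'   convolutions.
#' @param norm Apply instance normalization after every convolution except
#'   the final one.
#' @param final_activation Only `"tanh"` is supported.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(in_contrasts = 1L, out_decoders = 1L,
                           encoder_channels = c(20, 40, 40, 80, 80, 160, 160, 320),
                           decoder_channels = c(160, 160, 80, 80, 40, 40),
                           norm = TRUE, final_activation = "tanh") {
  if (!in_contrasts %in% 1:2) stop("in_contrasts must be 1 or 2")
  if (!out_decoders %in% 1:2) stop("out_decoders must be 1 or 2")
  if (length(encoder_channels) != 8L)
    stop("encoder_channels must list 8 convolution widths")
  if (length(decoder_channels) != 6L)
    stop("decoder_channels must list 6 convolution widths")
  if (final_activation != "tanh") stop("final_activation must be 'tanh'")
  structure(
    list(in_contrasts = as.integer(in_contrasts),
         out_decoders = as.integer(out_decoders),
         encoder_channels = as.integer(encoder_channels),
         decoder_channels = as.integer(decoder_channels),
         norm = isTRUE(norm), final_activation = final_activation),
    class = "generator_spec"
  )
}

#' Build a U-Net generator
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed for the Gaussian weight initialization.
#' @return An object of class `ls_generator`.  Apply it with
#'   [generator_forward()] or via [predict.model_bundle()].
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  e <- spec$encoder_channels
  dch <- spec$decoder_channels
  nrm <- spec$norm
  with_seed(seed, {
    enc_in <- c(spec$in_contrasts, e[-8])
    enc <- lapply(1:8, function(i) new_conv(enc_in[i], e[i], inorm = nrm))
    decoders <- lapply(seq_len(spec$out_decoders), function(d) {
      list(
        convs = list(
          new_conv(e[8] + e[6], dch[1], inorm = nrm),
          new_conv(dch[1], dch[2], inorm = nrm),
          new_conv(dch[2] + e[4], dch[3], inorm = nrm),
          new_conv(dch[3], dch[4], inorm = nrm),
          new_conv(dch[4] + e[2], dch[5], inorm = nrm),
          new_conv(dch[5], dch[6], inorm = nrm)
        ),
        final = new_conv(dch[6], 1L, k = 1L, plo = 0L, phi = 0L,
                         inorm = FALSE, act = "tanh")
      )
    })
    structure(list(spec = spec, enc = enc, decoders = decoders),
              class = "ls_generator")
  })
}

#' Run a generator forward
#'
#' @param gen An [build_generator()] result.
#' @param x Either a numeric matrix (voxels x contrasts, with a `vdim`
#'   attribute), a 3D array, or a list of [volume()]s / arrays (T1 first,
#'   T2 second) that are concatenated channel-wise.
#' @param tape An autodiff tape; defaults to a non-recording tape
#'   (inference).
#' @return A list of output nodes, one per decoder; each holds a
#'   single-channel tensor of the input grid shape with values in (-1, 1).
#' @keywords internal
#' @export
generator_forward <- function(gen, x, tape = tape_new(FALSE)) {
  x <- as_tensor(x)
  d <- vdim(x)
  if (any(d %% 8L != 0L))
    stop("generator input axes must be divisible by 8, got ",
         paste(d, collapse = "x"))
  if (ncol(x) != gen$spec$in_contrasts)
    stop("generator expects ", gen$spec$in_contrasts,
         " input contrast(s), got ", ncol(x))
  xin <- tp_node(tape, x)
  h1 <- conv_apply(tape, xin, gen$enc[[1]])
  h2 <- conv_apply(tape, h1, gen$enc[[2]])   # skip 1 (full res)
  p1 <- op_maxpool(tape, h2)
  h3 <- conv_apply(tape, p1, gen$enc[[3]])
  h4 <- conv_apply(tape, h3, gen$enc[[4]])   # skip 2
  p2 <- op_maxpool(tape, h4)
  h5 <- conv_apply(tape, p2, gen$enc[[5]])
  h6 <- conv_apply(tape, h5, gen$enc[[6]])   # skip 3
  p3 <- op_maxpool(tape, h6)
  h7 <- conv_apply(tape, p3, gen$enc[[7]])
  h8 <- conv_apply(tape, h7, gen$enc[[8]])
  lapply(gen$decoders, function(dec) {
    u1 <- op_upnn(tape, h8)
    z <- conv_apply(tape, op_concat(tape, u1, h6), dec$convs[[1]])
    z <- conv_apply(tape, z, dec$convs[[2]])
    u2 <- op_upnn(tape, z)
    z <- conv_apply(tape, op_concat(tape, u2, h4), dec$convs[[3]])
    z <- conv_apply(tape, z, dec$convs[[4]])
    u3 <- op_upnn(tape, z)
    z <- conv_apply(tape, op_concat(tape, u3, h2), dec$convs[[5]])
    z <- conv_apply(tape, z, dec$convs[[6]])
    conv_apply(tape, z, dec$final)
  })
}

generator_params <- function(gen, decoder = NULL) {
  ps <- layers_params(gen$enc)
  decs <- if (is.null(decoder)) seq_along(gen$decoders) else decoder
  for (d in decs) {
    dec <- gen$decoders[[d]]
    ps <- c(ps, layers_params(dec$convs), conv_params(dec$final))
  }
  ps
}

#' Encoder parameter set of a generator
#'
#' In the multi-contrast configuration both decoders reference this same
#' set of parameter environments; updating one updates the other.
#'
#' @param gen A generator.
#' @return List of parameter leaves.
#' @export
encoder_params <- function(gen) layers_params(gen$enc)

#' Discriminator architecture specification
#'
#' Four 4x4x4 stride-2 convolutions (no normalization on the first, instance
#' normalization on the rest, LeakyReLU), then a stride-1 4x4x4 convolution
#' to one channel with a sigmoid, yielding a patch score map in (0, 1).
#'
#' @param channels Output channels of the four stride-2 convolutions.
#' @param kernel Convolution kernel size (4).
#' @param leaky_slope Negative slope of the LeakyReLU.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(channels = c(64, 128, 256, 512),
                               kernel = 4L, leaky_slope = 0.2) {
  if (length(channels) != 4L) stop("discriminator needs 4 channel widths")
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 leaky_slope = leaky_slope),
            class = "discriminator_spec")
}

#' Build a patch discriminator
#'
#' @param spec A [discriminator_spec()].
#' @param in_ch Number of input channels (1: the discriminator scores one
#'   contrast and is unconditional).
#' @param seed Weight-initialization seed.
#' @return An object of class `ls_discriminator`.
#' @export
build_discriminator <- function(spec = discriminator_spec(), in_ch = 1L,
                                seed = 1L) {
  ch <- spec$channels
  k <- spec$kernel
  sl <- spec$leaky_slope
  with_seed(seed, {
    layers <- list(
      new_conv(in_ch, ch[1], k = k, stride = 2L, inorm = FALSE,
               act = "lrelu", slope = sl),
      new_conv(ch[1], ch[2], k = k, stride = 2L, act = "lrelu", slope = sl),
      new_conv(ch[2], ch[3], k = k, stride = 2L, act = "lrelu", slope = sl),
      new_conv(ch[3], ch[4], k = k, stride = 2L, act = "lrelu", slope = sl),
      new_conv(ch[4], 1L, k = k, stride = 1L, plo = 1L, phi = 2L,
               inorm = FALSE, act = "sigmoid")
    )
    structure(list(spec = spec, layers = layers), class = "ls_discriminator")
  })
}

#' @keywords internal
#' @export
discriminator_forward <- function(disc, x, tape = tape_new(FALSE)) {
  x <- as_tensor(x)
  disc_apply(disc, tp_node(tape, x), tape)
}

# Chain the discriminator onto an existing tape node (used during training
# so generator gradients flow through D).
disc_apply <- function(disc, node, tape) {
  if (any(vdim(node$v) < 16L))
    stop("discriminator input must be at least 16 voxels per axis")
  z <- node
  for (ly in disc$layers) z <- conv_apply(tape, z, ly)
  z
}

discriminator_params <- function(disc) layers_params(disc$layers)

#' Feature-extractor architecture specification
#'
#' Encoder-style network of four blocks of two 3x3x3 convolutions each
#' (instance normalization + ReLU), with 2x max-pool downsampling after
#' blocks 1-3.  Block m's (post-pool) output is the perceptual feature map
#' phi_m.  Weights are frozen: the extractor is never trained.
#'
#' @param block_channels List of four length-2 channel pairs.
#' @param weights_source `"random-seeded"` (default; a fixed-seed random
#'   frozen encoder) or `"external-file"` to load pretrained weights with
#'   [load_weights()].
#' @return An object of class `feature_extractor_spec`.
#' @export
feature_extractor_spec <- function(block_channels = list(c(32, 64), c(64, 128),
                                                         c(128, 256), c(256, 512)),
                                   weights_source = "random-seeded") {
  if (length(block_channels) != 4L)
    stop("feature extractor needs 4 blocks")
  structure(list(block_channels = lapply(block_channels, as.integer),
                 weights_source = weights_source),
            class = "feature_extractor_spec")
}

#' Build the (frozen) perceptual feature extractor
#'
#' @param spec A [feature_extractor_spec()].
#' @param in_ch Input channels (1).
#' @param seed Weight-initialization seed.
#' @return An object of class `ls_feature_extractor`.
#' @export
build_feature_extractor <- function(spec = feature_extractor_spec(),
                                    in_ch = 1L, seed = 1L) {
  bc <- spec$block_channels
  with_seed(seed, {
    blocks <- vector("list", 4L)
    prev <- in_ch
    for (i in 1:4) {
      blocks[[i]] <- list(new_conv(prev, bc[[i]][1]),
                          new_conv(bc[[i]][1], bc[[i]][2]))
      prev <- bc[[i]][2]
    }
    phi <- structure(list(spec = spec, blocks = blocks),
                     class = "ls_feature_extractor")
    for (p in feature_params(phi)) p$frozen <- TRUE
    phi
  })
}

feature_params <- function(phi) {
  do.call(c, lapply(phi$blocks, layers_params))
}

#' @keywords internal
#' @export
phi_forward <- function(phi, x, m = 1L, tape = tape_new(FALSE)) {
  phi_apply(phi, tp_node(tape, as_tensor(x)), m, tape)
}

phi_apply <- function(phi, node, m, tape) {
  if (!m %in% 1:4) stop("feature layer m must be in 1..4")
  z <- node
  for (i in seq_len(m)) {
    z <- conv_apply(tape, z, phi$blocks[[i]][[1]])
    z <- conv_apply(tape, z, phi$blocks[[i]][[2]])
    if (i <= 3L) z <- op_maxpool(tape, z)
  }
  z
}

#' Extract perceptual features from a volume
#'
#' @param phi A [build_feature_extractor()] result.
#' @param x A [volume()], 3D array, or voxel-by-channel matrix.
#' @param m Feature layer index in 1..4 (phi_m).
#' @return Numeric matrix (voxels x channels) with a `vdim` attribute.
#' @export
phi_features <- function(phi, x, m = 1L) {
  phi_forward(phi, x, m)$v
}

#' Number of trainable parameters of a network
#'
#' @param net A generator, discriminator, feature extractor, or model
#'   bundle.
#' @return Integer parameter count (a pure function of the spec).
#' @export
param_count <- function(net) {
  ps <- switch(class(net)[1],
    ls_generator = generator_params(net),
    ls_discriminator = discriminator_params(net),
    ls_feature_extractor = feature_params(net),
    model_bundle = bundle_params(net),
    stop("unsupported network class: ", class(net)[1])
  )
  sum(vapply(ps, function(p) length(p$v), numeric(1)))
}

# Coerce volumes / arrays / lists of them to a voxel-by-channel matrix.
as_tensor <- function(x) {
  if (is.matrix(x) && !is.null(vdim(x))) return(x)
  if (inherits(x, "volume")) x <- list(x)
  if (is.list(x)) {
    cols <- lapply(x, function(v) {
      a <- if (inherits(v, "volume")) v$data else v
      as.vector(a)
    })
    d <- dim(if (inherits(x[[1]], "volume")) x[[1]]$data else x[[1]])
    out <- do.call(cbind, cols)
    vdim(out) <- d
    return(out)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    out <- matrix(as.vector(x), ncol = 1L)
    vdim(out) <- d
    return(out)
  }
  stop("cannot interpret input as a volumetric tensor")
}

# Weight checkpointing --------------------------------------------------

spec_fingerprint <- function(spec) {
  paste(deparse(spec, control = "all"), collapse = "")
}

net_params <- function(net) {
  switch(class(net)[1],
    ls_generator = generator_params(net),
    ls_discriminator = discriminator_params(net),
    ls_feature_extractor = feature_params(net),
    stop("unsupported network class")
  )
}

#' Save network weights with an embedded spec fingerprint
#'
#' @param net Network object.
#' @param path Destination file.
#' @export
save_weights <- function(net, path) {
  vals <- lapply(net_params(net), function(p) p$v)
  saveRDS(list(fingerprint = spec_fingerprint(net$spec), values = vals), path)
  invisible(path)
}

#' Load network weights, refusing on architecture mismatch
#'
#' @param net Network object to load into (modified in place).
#' @param path Checkpoint written by [save_weights()].
#' @export
load_weights <- function(net, path) {
  ck <- readRDS(path)
  if (!identical(ck$fingerprint, spec_fingerprint(net$spec)))
    stop("weight checkpoint does not match the network architecture")
  ps <- net_params(net)
  if (length(ps) != length(ck$values))
    stop("weight checkpoint does not match the network architecture")
  for (i in seq_along(ps)) {
    if (!identical(dim(ps[[i]]$v), dim(ck$values[[i]])) &&
        length(ps[[i]]$v) != length(ck$values[[i]]))
      stop("weight checkpoint does not match the network architecture")
    ps[[i]]$v <- ck$values[[i]]
  }
  invisible(net)
}
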