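# Convolutional auto-encoder defining the stroke shape space.
#
# The encoder forwards a one-channel shape volume through double-convolution
# blocks (batch norm before each 3x3x3 convolution) interspersed with three
# stride-2 convolutions, and a final single convolution maps the feature map
# to a small spatial bottleneck (10x10x1 for the default 128x128x28 input).
# The bottleneck is linear so that straight lines in latent space are
# meaningful. The decoder mirrors the encoder with transposed convolutions
# replacing the stride-2 convolutions and ends in a sigmoid. Each shape is
# encoded independently; core and core+penumbra are never stacked as
# channels.

#' CAE configuration
#'
#' @param input_dim spatial extent of the shape volumes
#' @param widths encoder channel widths: full-resolution block and the three
#'   blocks following each stride-2 convolution
#' @param bottleneck_channels feature channels of the latent code
#' @param bottleneck_extent spatial extent of the latent code; the final
#'   encoder convolution uses the (per-axis) valid kernel that maps the
#'   post-stride feature map onto this extent
#' @return an object of class `cae_config`
#' @export
cae_config <- function(input_dim = c(128L, 128L, 28L),
                       widths = c(16L, 32L, 64L, 64L),
                       bottleneck_channels = 16L,
                       bottleneck_extent = c(10L, 10L, 1L)) {
  input_dim <- as.integer(input_dim)
  bottleneck_extent <- as.integer(bottleneck_extent)
  stopifnot(length(widths) == 4L, all(widths > 0), bottleneck_channels > 0)
  k3 <- c(3L, 3L, 3L); s2 <- c(2L, 2L, 2L); p1 <- c(1L, 1L, 1L)
  e1 <- conv_out_dims(input_dim, k3, s2, p1)
  e2 <- conv_out_dims(e1, k3, s2, p1)
  e3 <- conv_out_dims(e2, k3, s2, p1)
  kb <- e3 - bottleneck_extent + 1L
  if (any(kb < 1L))
    stop("input ", paste(input_dim, collapse = "x"),
         " cannot reach bottleneck extent ",
         paste(bottleneck_extent, collapse = "x"),
         "; achievable extent after three stride-2 stages is at most ",
         paste(e3, collapse = "x"))
  structure(list(input_dim = input_dim, widths = as.integer(widths),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 bottleneck_extent = bottleneck_extent,
                 stage_dims = list(e1 = e1, e2 = e2, e3 = e3),
                 bottleneck_kernel = kb),
            class = "cae_config")
}

#' Build the convolutional auto-encoder
#'
#' @param config a [cae_config()]
#' @param seed integer seed for deterministic weight initialization
#' @return list with `encoder` and `decoder` models (class `cae_model`)
#' @export
build_cae <- function(config = cae_config(), seed = 1L) {
  set.seed(seed)
  w <- config$widths
  bc <- config$bottleneck_channels
  kb <- config$bottleneck_kernel
  enc <- new.env(); enc$params <- list(); enc$states <- list()
  add_block(enc, "b1", 1L, w[1])
  enc$params[["s1"]] <- init_conv(w[1], w[2])
  add_block(enc, "b2", w[2], w[2])
  enc$params[["s2"]] <- init_conv(w[2], w[3])
  add_block(enc, "b3", w[3], w[3])
  enc$params[["s3"]] <- init_conv(w[3], w[4])
  add_block(enc, "b4", w[4], w[4])
  enc$params[["bottleneck"]] <- init_conv(w[4], bc, k = kb)
  dec <- new.env(); dec$params <- list(); dec$states <- list()
  dec$params[["tbottleneck"]] <- init_tconv(bc, w[4], k = kb)
  add_block(dec, "b4", w[4], w[4])
  dec$params[["t3"]] <- init_tconv(w[4], w[3])
  add_block(dec, "b3", w[3], w[3])
  dec$params[["t2"]] <- init_tconv(w[3], w[2])
  add_block(dec, "b2", w[2], w[2])
  dec$params[["t1"]] <- init_tconv(w[2], w[1])
  # mirrored first block: BN -> conv(w1 -> w1) -> ReLU -> BN -> conv(w1 -> 1)
  dec$params[["out.bn1"]] <- init_bn(w[1])
  dec$params[["out.conv1"]] <- init_conv(w[1], w[1])
  dec$params[["out.bn2"]] <- init_bn(w[1])
  dec$params[["out.conv2"]] <- init_conv(w[1], 1L)
  # start the decoder near-empty: initial reconstructions then satisfy the
  # monotonicity constraint trivially and the overlap terms drive growth
  dec$params[["out.conv2"]]$b[] <- -2
  dec$states[["out.bn1"]] <- new_bn_state(w[1])
  dec$states[["out.bn2"]] <- new_bn_state(w[1])
  structure(list(config = config,
                 encoder = list(params = enc$params, states = enc$states),
                 decoder = list(params = dec$params, states = dec$states)),
            class = "cae_model")
}

k3 <- c(3L, 3L, 3L); s2 <- c(2L, 2L, 2L); s1 <- c(1L, 1L, 1L)
p1 <- c(1L, 1L, 1L); p0 <- c(0L, 0L, 0L)

# encoder forward: (vox x 1) -> (bottleneck_vox x bottleneck_channels)
cae_encode_fw <- function(config, pp, states, x, nbatch = 1L,
                          training = FALSE) {
  d0 <- config$input_dim
  sd_ <- config$stage_dims
  h <- block_fw(pp, states, "b1", x, d0, nbatch, training)
  h <- conv_fw(pp, "s1", h, d0, nbatch, s = s2)
  h <- block_fw(pp, states, "b2", h, sd_$e1, nbatch, training)
  h <- conv_fw(pp, "s2", h, sd_$e1, nbatch, s = s2)
  h <- block_fw(pp, states, "b3", h, sd_$e2, nbatch, training)
  h <- conv_fw(pp, "s3", h, sd_$e2, nbatch, s = s2)
  h <- block_fw(pp, states, "b4", h, sd_$e3, nbatch, training)
  conv_fw(pp, "bottleneck", h, sd_$e3, nbatch,
          k = config$bottleneck_kernel, s = s1, p = p0)
}

# decoder forward: latent code -> (vox x 1) probability volume
cae_decode_fw <- function(config, pp, states, code, nbatch = 1L,
                          training = FALSE) {
  sd_ <- config$stage_dims
  be <- config$bottleneck_extent
  h <- tconv_fw(pp, "tbottleneck", code, be, nbatch, s1, p0, sd_$e3,
                k = config$bottleneck_kernel)
  h <- block_fw(pp, states, "b4", h, sd_$e3, nbatch, training)
  h <- tconv_fw(pp, "t3", h, sd_$e3, nbatch, s2, p1, sd_$e2)
  h <- block_fw(pp, states, "b3", h, sd_$e2, nbatch, training)
  h <- tconv_fw(pp, "t2", h, sd_$e2, nbatch, s2, p1, sd_$e1)
  h <- block_fw(pp, states, "b2", h, sd_$e1, nbatch, training)
  h <- tconv_fw(pp, "t1", h, sd_$e1, nbatch, s2, p1, config$input_dim)
  h <- bn_fw(pp, states, "out.bn1", h, training)
  h <- ag_relu(conv_fw(pp, "out.conv1", h, config$input_dim, nbatch))
  h <- bn_fw(pp, states, "out.bn2", h, training)
  h <- conv_fw(pp, "out.conv2", h, config$input_dim, nbatch)
  ag_sigmoid(h)
}

tconv_fw <- function(pp, name, x, ind, nbatch, s, p, outd, k = k3) {
  pr <- pp[[name]]
  ag_tconv3d(x, pr$W, pr$b, ind, nbatch, k, s, p, outd)
}

#' Encode a shape volume into a latent code
#'
#' Each shape is forwarded independently through the encoder (shapes are
#' never stacked as channels of one pass).
#'
#' @param cae a `cae_model` from [build_cae()] (or a list with `encoder`)
#' @param shape 3D array (or voxel-column matrix) with values in `[0,1]`
#' @param provenance optional tag, e.g. `"y_c"` or `"yhat_cp"`
#' @param encoder which encoder parameters to use when `cae` carries both
#'   (`"E1"` ground-truth shapes, `"E2"` U-Net estimates)
#' @return a `latent_code` matrix (bottleneck voxels x channels)
#' @export
encode <- function(cae, shape, provenance = NULL, encoder = c("E1", "E2")) {
  encoder <- match.arg(encoder)
  enc <- if (encoder == "E2" && !is.null(cae$encoder2)) cae$encoder2
         else cae$encoder
  x <- if (is.matrix(shape)) shape else vol_as_mat(shape)
  if (!all(attr(x, "d") == cae$config$input_dim))
    stop("shape extent ", paste(attr(x, "d"), collapse = "x"),
         " does not match configured input ",
         paste(cae$config$input_dim, collapse = "x"))
  code <- cae_encode_fw(cae$config, enc$params, enc$states, x)
  new_latent_code(code, cae$config, provenance)
}

new_latent_code <- function(values, config, provenance = NULL) {
  structure(values,
            d = config$bottleneck_extent,
            provenance = provenance,
            class = c("latent_code", class(values)))
}

#' Decode a latent code into a shape probability volume
#'
#' @param cae a `cae_model`
#' @param code a `latent_code` (bottleneck voxels x channels)
#' @return 3D array with values in `[0,1]` at the configured input extent
#' @export
decode <- function(cae, code) {
  bc <- cae$config$bottleneck_channels
  if (ncol(code) != bc ||
      nrow(code) != prod(cae$config$bottleneck_extent))
    stop("latent code dimensionality does not match the decoder")
  dec <- cae$decoder
  y <- cae_decode_fw(cae$config, dec$params, dec$states,
                     unclass_code(code))
  mat_as_vol(y, cae$config$input_dim)
}

unclass_code <- function(code) {
  a <- unclass(code)
  attr(a, "provenance") <- NULL
  a
}
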