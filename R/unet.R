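# 3D U-Net for joint core / core+penumbra segmentation from CBV + TTD.
#
# Three resolution levels (two max-poolings), double-convolution blocks with
# a batch-normalization layer before every 3x3x3 convolution, trilinear
# upsampling in the decoder, and an independent sigmoid per output channel
# (core and core+penumbra are nested classes, not mutually exclusive ones).

#' U-Net configuration
#'
#' @param in_channels input channels (CBV and TTD maps)
#' @param out_channels output channels (soft core and core+penumbra)
#' @param channels feature channels for the three resolution levels
#' @param patch_size extent of the training/inference patch core region
#' @param context_pad context voxels added on every side of a patch; the
#'   network sees the padded block and the output is cropped back
#' @param threshold binarization threshold used for evaluation
#' @return an object of class `unet_config`
#' @export
unet_config <- function(in_channels = 2L, out_channels = 2L,
                        channels = c(16L, 32L, 64L),
                        patch_size = c(64L, 64L, 28L),
                        context_pad = 20L, threshold = 0.5) {
  stopifnot(length(channels) == 3L, all(channels > 0), length(patch_size) == 3L,
            context_pad >= 0)
  padded <- patch_size + 2L * context_pad
  if (any(padded %% 4L != 0L))
    stop("padded patch extent ", paste(padded, collapse = "x"),
         " must be divisible by 4 for two pooling levels")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 channels = as.integer(channels),
                 patch_size = as.integer(patch_size),
                 context_pad = as.integer(context_pad),
                 threshold = threshold),
            class = "unet_config")
}

#' Build a 3D U-Net
#'
#' @param config a [unet_config()]
#' @param seed integer seed for deterministic weight initialization
#' @return a `unet_model` list with `config`, `params` and batch-norm `states`
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  set.seed(seed)
  ch <- config$channels
  store <- new.env()
  store$params <- list()
  store$states <- list()
  add_block(store, "enc1", config$in_channels, ch[1])
  add_block(store, "enc2", ch[1], ch[2])
  add_block(store, "enc3", ch[2], ch[3])
  add_block(store, "dec2", ch[2] + ch[3], ch[2])
  add_block(store, "dec1", ch[1] + ch[2], ch[1])
  store$params[["out"]] <- init_conv(ch[1], config$out_channels,
                                     k = c(1L, 1L, 1L))
  structure(list(config = config, params = store$params,
                 states = store$states),
            class = "unet_model")
}

# Forward pass on a (vox x in_channels) feature matrix. `pp` may hold plain
# arrays (evaluation) or tape leaves (training).
unet_fw <- function(config, pp, states, x, ind, nbatch = 1L,
                    training = FALSE) {
  e1 <- block_fw(pp, states, "enc1", x, ind, nbatch, training)
  d1 <- ind
  p1 <- ag_maxpool(e1, d1, nbatch)
  d2 <- dims_of(p1)
  e2 <- block_fw(pp, states, "enc2", p1, d2, nbatch, training)
  p2 <- ag_maxpool(e2, d2, nbatch)
  d3 <- dims_of(p2)
  e3 <- block_fw(pp, states, "enc3", p2, d3, nbatch, training)
  u2 <- ag_resize(e3, d3, nbatch, d2)
  d2b <- block_fw(pp, states, "dec2", ag_concat(e2, u2), d2, nbatch, training)
  u1 <- ag_resize(d2b, d2, nbatch, d1)
  d1b <- block_fw(pp, states, "dec1", ag_concat(e1, u1), d1, nbatch, training)
  conv_fw(pp, "out", d1b, d1, nbatch,
          k = c(1L, 1L, 1L), s = c(1L, 1L, 1L), p = c(0L, 0L, 0L))
}

#' Sample a random training patch from a case
#'
#' Draws a patch position uniformly over all valid placements, extracts the
#' CBV/TTD input block of `patch_size` plus `context_pad` voxels of context
#' on every side (zero-padded beyond the volume), and the core/core+penumbra
#' target masks cropped to the core region.
#'
#' @param case a [perfusion_case()]
#' @param config a [unet_config()]
#' @param seed optional integer seed for a deterministic position
#' @return list with `input` (padded-voxel x 2 matrix), `input_dims`,
#'   `target` (core-voxel x 2 matrix), `core_idx` (rows of the padded block
#'   forming the core region) and `start` (0-based patch origin)
#' @export
sample_training_patch <- function(case, config = unet_config(), seed = NULL) {
  vd <- dim(case$cbv)
  ps <- config$patch_size
  if (any(vd < ps))
    stop("volume ", paste(vd, collapse = "x"), " is smaller than the patch ",
         paste(ps, collapse = "x"), "; use a smaller patch_size")
  if (!is.null(seed)) set.seed(seed)
  start <- vapply(seq_len(3), function(a)
    if (vd[a] == ps[a]) 0L else sample.int(vd[a] - ps[a] + 1L, 1L) - 1L,
    integer(1))
  extract_patch(case, start, ps, config$context_pad)
}

# deterministic patch extraction used by both training and tiling
extract_patch <- function(case, start, ps, pad) {
  vd <- dim(case$cbv)
  pd <- as.integer(ps + 2L * pad)
  block <- function(vol) {
    out <- array(0, dim = pd)
    src_lo <- pmax(start - pad + 1L, 1L)
    src_hi <- pmin(start + ps + pad, vd)
    dst_lo <- src_lo - (start - pad)
    dst_hi <- dst_lo + (src_hi - src_lo)
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      vol[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
    out
  }
  inp <- cbind(as.numeric(block(case$cbv)), as.numeric(block(case$ttd)))
  attr(inp, "d") <- pd
  core_idx <- core_region_rows(pd, pad, ps)
  tgt <- NULL
  if (!is.null(case$core_mask)) {
    sl <- lapply(seq_len(3), function(a) (start[a] + 1L):(start[a] + ps[a]))
    tgt <- cbind(as.numeric(case$core_mask[sl[[1]], sl[[2]], sl[[3]]]),
                 as.numeric(case$core_penumbra_mask[sl[[1]], sl[[2]], sl[[3]]]))
    attr(tgt, "d") <- as.integer(ps)
  }
  list(input = inp, input_dims = pd, target = tgt, core_idx = core_idx,
       start = start, patch_size = as.integer(ps))
}

core_region_rows <- function(pd, pad, ps) {
  ix <- (pad + 1L):(pad + ps[1])
  iy <- (pad + 1L):(pad + ps[2])
  iz <- (pad + 1L):(pad + ps[3])
  idx <- outer(outer(ix, (iy - 1L) * pd[1], "+"),
               (iz - 1L) * pd[1] * pd[2], "+")
  as.integer(idx)
}

#' Patch placements covering a volume for inference
#'
#' End-anchored ceiling-division tiling: starts step by the patch extent and
#' the final placement is anchored at the volume boundary, so every voxel is
#' covered and the default 128x128x28 grid splits into exactly 4
#' non-overlapping 64x64x28 patches.
#'
#' @param dims volume extent
#' @param config a [unet_config()]
#' @return list of placements, each with `start` (0-based) and `size`
#' @export
tile_for_inference <- function(dims, config = unet_config()) {
  dims <- as.integer(dims)
  ps <- pmin(config$patch_size, dims)
  starts_axis <- function(n, p) {
    if (n <= p) return(0L)
    s <- seq(0L, n - p, by = p)
    unique(c(s, n - p))
  }
  sx <- starts_axis(dims[1], ps[1])
  sy <- starts_axis(dims[2], ps[2])
  sz <- starts_axis(dims[3], ps[3])
  placements <- list()
  for (z in sz) for (y in sy) for (x in sx)
    placements[[length(placements) + 1L]] <-
      list(start = c(x, y, z), size = ps)
  placements
}

#' Segment a case with a trained U-Net
#'
#' Runs the network over the inference tiling and reassembles full-volume
#' soft segmentations; voxels covered by several patches are averaged.
#'
#' @param model a `unet_model`
#' @param case a [perfusion_case()] (masks not required)
#' @return list with probability arrays `core` and `core_penumbra`
#' @export
segment <- function(model, case) {
  vd <- dim(case$cbv)
  placements <- tile_for_inference(vd, model$config)
  acc_c <- array(0, vd); acc_p <- array(0, vd); cnt <- array(0, vd)
  for (pl in placements) {
    patch <- extract_patch(case, pl$start, pl$size, model$config$context_pad)
    logits <- unet_fw(model$config, model$params, model$states, patch$input,
                      patch$input_dims, 1L, training = FALSE)
    probs <- ag_sigmoid(ag_rows(logits, patch$core_idx))
    sl <- lapply(seq_len(3), function(a)
      (pl$start[a] + 1L):(pl$start[a] + pl$size[a]))
    pc <- array(probs[, 1], dim = pl$size)
    pp <- array(probs[, 2], dim = pl$size)
    acc_c[sl[[1]], sl[[2]], sl[[3]]] <- acc_c[sl[[1]], sl[[2]], sl[[3]]] + pc
    acc_p[sl[[1]], sl[[2]], sl[[3]]] <- acc_p[sl[[1]], sl[[2]], sl[[3]]] + pp
    cnt[sl[[1]], sl[[2]], sl[[3]]] <- cnt[sl[[1]], sl[[2]], sl[[3]]] + 1
  }
  list(core = acc_c / cnt, core_penumbra = acc_p / cnt)
}
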