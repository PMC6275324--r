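# Objectives and evaluation metrics. All functions accept plain numeric
# arrays (metric/evaluation path) or autograd tensors (training path); the
# arithmetic is written once and dispatches through the tensor's group
# methods.

check_congruent <- function(a, b, what = "volumes") {
  va <- ag_value(a); vb <- ag_value(b)
  da <- dim(va) %||% length(va)
  db <- dim(vb) %||% length(vb)
  if (length(va) != length(vb) || !all(da == db))
    stop(what, " are not congruent: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}

#' Loss configuration
#'
#' @param epsilon smoothing constant of the SoftDice measure; stabilizes
#'   gradients for small or empty shapes
#' @param alpha_switch_epoch epoch (1-based) at which the latent-alignment
#'   weight alpha switches from 0 to 1 during shape-space training
#' @param include_lesion_recon also supervise the lesion reconstruction
#'   `R_l` with a SoftDice term during shape-space training
#' @return an object of class `loss_config`
#' @export
loss_config <- function(epsilon = 1, alpha_switch_epoch = 25L,
                        include_lesion_recon = TRUE) {
  stopifnot(epsilon > 0, alpha_switch_epoch >= 1)
  structure(list(epsilon = epsilon,
                 alpha_switch_epoch = as.integer(alpha_switch_epoch),
                 include_lesion_recon = isTRUE(include_lesion_recon)),
            class = "loss_config")
}

#' SoftDice overlap measure
#'
#' `(2 * sum(A*B) + eps) / (sum(A^2) + sum(B^2) + eps)`; 1 for identical
#' binary volumes, and 1 for two empty volumes (the smoothing constant
#' resolves the 0/0 case).
#'
#' @param a,b congruent volumes with values in `[0,1]`
#' @param epsilon smoothing constant, must be positive
#' @return scalar in (0, 1]
#' @export
soft_dice <- function(a, b, epsilon = 1) {
  stopifnot(epsilon >= 0)
  check_congruent(a, b)
  (2 * sum(a * b) + epsilon) / (sum(a * a) + sum(b * b) + epsilon)
}

#' SoftDice loss
#'
#' `1 - soft_dice(a, b, epsilon)`, in `[0, 1)`.
#' @inheritParams soft_dice
#' @export
soft_dice_loss <- function(a, b, epsilon = 1) 1 - soft_dice(a, b, epsilon)

#' Monotone-growth hinge penalty
#'
#' `sum(max(A_i - B_i, 0))`: zero exactly when `A <= B` voxelwise. Penalizes
#' any part of a decoded core or intermediate lesion that exceeds the
#' decoded core+penumbra.
#'
#' @param a,b congruent volumes
#' @return non-negative scalar
#' @export
mono_penalty <- function(a, b) {
  check_congruent(a, b)
  sum(hinge_pos(a - b))
}

#' Latent L1 distance
#'
#' Mean absolute elementwise difference between two latent codes; the mean
#' (rather than the sum) keeps the scale insensitive to the bottleneck size.
#'
#' @param y,y2 latent codes of identical dimensionality
#' @return non-negative scalar
#' @export
latent_l1 <- function(y, y2) {
  check_congruent(y, y2, "latent codes")
  mean(abs(y - y2))
}

#' Hard Dice coefficient
#'
#' `2|A n B| / (|A| + |B|)` for binary volumes; defined as 1 when both are
#' empty.
#'
#' @param a,b congruent binary volumes
#' @return scalar in `[0, 1]`
#' @export
hard_dice <- function(a, b) {
  check_congruent(a, b)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("hard_dice requires binary volumes; binarize soft maps first")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Shape-space training loss
#'
#' Composite objective of the first CAE phase: SoftDice reconstruction terms
#' for core and core+penumbra (optionally also the lesion), monotonicity
#' hinges tying the decoded core and decoded lesion under the decoded
#' core+penumbra, and (once alpha switches on) an L1 term keeping the lesion
#' code on the straight line between the core and core+penumbra codes.
#'
#' @param recons list with reconstructions `c`, `cp`, `l`
#' @param truths list with ground-truth masks `c`, `cp` (and `l` when the
#'   lesion reconstruction term is enabled)
#' @param codes list with latent codes `l` and `i` (interpolated)
#' @param alpha 0 or 1; weight of the latent alignment term
#' @param config a [loss_config()]
#' @return scalar loss
#' @export
shape_loss <- function(recons, truths, codes, alpha, config = loss_config()) {
  stopifnot(alpha %in% c(0, 1))
  eps <- config$epsilon
  loss <- soft_dice_loss(recons$c, truths$c, eps) +
    soft_dice_loss(recons$cp, truths$cp, eps)
  if (config$include_lesion_recon) {
    if (is.null(truths$l))
      stop("lesion ground truth required when the lesion reconstruction ",
           "term is enabled")
    loss <- loss + soft_dice_loss(recons$l, truths$l, eps)
  }
  loss <- loss + mono_penalty(recons$c, recons$cp) +
    mono_penalty(recons$l, recons$cp)
  if (alpha != 0) loss <- loss + alpha * latent_l1(codes$l, codes$i)
  loss
}

#' Prediction training loss
#'
#' Composite objective of the second phase (training the estimate encoder
#' E2 against the frozen shape space): SoftDice between the decoded
#' interpolation and the true follow-up lesion, monotonicity hinges on the
#' decoded estimates, and L1 terms pulling the estimate codes onto their
#' ground-truth counterparts (the interpolated code is compared against both
#' the lesion code and the ground-truth interpolation).
#'
#' @param pred decoded prediction volume `D(yhat_i)`
#' @param truth follow-up lesion mask `S_l`
#' @param decoded list with decoded estimates `c` = `D(yhat_c)` and
#'   `cp` = `D(yhat_cp)`
#' @param codes list with estimate codes `c` and `i`
#' @param targets list with ground-truth codes `c`, `l`, `i`
#' @param config a [loss_config()]
#' @return scalar loss
#' @export
prediction_loss <- function(pred, truth, decoded, codes, targets,
                            config = loss_config()) {
  eps <- config$epsilon
  soft_dice_loss(pred, truth, eps) +
    mono_penalty(decoded$c, decoded$cp) +
    mono_penalty(pred, decoded$cp) +
    latent_l1(codes$c, targets$c) +
    latent_l1(codes$i, targets$l) +
    latent_l1(codes$i, targets$i)
}
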