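# Time normalization, latent interpolation, follow-up prediction, the
# image-space baseline and the oracle-eta analysis.

#' Normalized time fraction along the growth trajectory
#'
#' `eta = t_imaging_to_treatment / (horizon - t_onset_to_imaging)`, clamped
#' to `[0, 1]`: the method assumes the lesion never grows beyond the
#' core+penumbra extent reached at the horizon.
#'
#' @param t_onset_to_imaging,t_imaging_to_treatment times in hours
#' @param horizon growth horizon T in hours after onset (10 by default;
#'   24 supported for acute-phase normalization)
#' @return fraction in `[0, 1]`
#' @export
compute_eta <- function(t_onset_to_imaging, t_imaging_to_treatment,
                        horizon = 10) {
  if (t_onset_to_imaging < 0 || t_imaging_to_treatment < 0)
    stop("times must be non-negative")
  if (t_onset_to_imaging >= horizon)
    stop("onset-to-imaging time ", t_onset_to_imaging,
         " h reaches the growth horizon of ", horizon,
         " h; the case cannot be admitted under this normalization")
  eta <- t_imaging_to_treatment / (horizon - t_onset_to_imaging)
  min(max(eta, 0), 1)
}

#' Linear interpolation between two latent codes
#'
#' `y_i = y_c + eta * (y_cp - y_c)`; exact at both endpoints.
#'
#' @param y_c,y_cp latent codes of identical dimensionality
#' @param eta fraction in `[0, 1]`
#' @return interpolated latent code (provenance `"i"`)
#' @export
interpolate_latent <- function(y_c, y_cp, eta) {
  check_congruent(y_c, y_cp, "latent codes")
  stopifnot(eta >= 0, eta <= 1)
  # endpoints are returned exactly, not via the (rounding) affine formula
  out <- if (eta == 0) y_c + 0 else if (eta == 1) y_cp + 0
         else y_c + eta * (y_cp - y_c)
  if (!is_tensor(out)) {
    attributes(out) <- attributes(ag_value(y_c))
    attr(out, "provenance") <- "i"
  }
  out
}

#' Voxel-space interpolation baseline
#'
#' The naive alternative to shape-space interpolation: a voxelwise affine
#' blend `S_c + eta * (S_cp - S_c)`. Penumbra-only voxels all share the
#' value `eta`, so the penumbral shell "fades in" uniformly instead of
#' growing outward.
#'
#' @param s_c,s_cp congruent core and core+penumbra volumes (soft or binary)
#' @param eta fraction in `[0, 1]`
#' @param threshold binarization threshold for the reported mask
#' @return a `prediction_result`
#' @export
image_space_interpolate <- function(s_c, s_cp, eta, threshold = 0.5) {
  check_congruent(s_c, s_cp)
  stopifnot(eta >= 0, eta <= 1)
  prob <- s_c + eta * (s_cp - s_c)
  prediction_result(prob, eta, "image_space", threshold)
}

prediction_result <- function(prob, eta, method, threshold = 0.5) {
  mask <- (prob >= threshold) * 1
  structure(list(prob = prob, eta = eta, method = method,
                 mask = mask, volume_voxels = sum(mask),
                 threshold = threshold),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> method=%s eta=%.3f volume=%d voxels\n",
              x$method, x$eta, x$volume_voxels))
  invisible(x)
}

#' Predict the follow-up lesion for a case
#'
#' Encodes the core and core+penumbra shapes (either the U-Net estimates or
#' expert masks), interpolates their latent codes at the case's normalized
#' time, and decodes the result.
#'
#' @param case a [perfusion_case()]
#' @param models list with `unet` (required in `from_estimates` mode) and
#'   `cae` (a trained `cae_model`; must carry `encoder2` for
#'   `from_estimates` mode)
#' @param horizon growth horizon in hours
#' @param mode `"from_estimates"` runs the U-Net and encodes its soft
#'   segmentations with E2; `"from_expert_masks"` encodes the case's manual
#'   masks with E1
#' @param threshold binarization threshold
#' @return a `prediction_result` with the decoded probability volume
#' @export
predict_followup <- function(case, models, horizon = 10,
                             mode = c("from_estimates", "from_expert_masks"),
                             threshold = 0.5) {
  mode <- match.arg(mode)
  cae <- models$cae
  if (is.null(cae)) stop("models$cae is required")
  eta <- compute_eta(case$t_onset_to_imaging, case$t_imaging_to_treatment,
                     horizon)
  if (mode == "from_estimates") {
    if (is.null(models$unet))
      stop("models$unet is required in from_estimates mode")
    if (is.null(cae$encoder2))
      stop("models$cae has no trained estimate encoder (E2); run ",
           "train_prediction_encoder() or use from_expert_masks mode")
    seg <- segment(models$unet, case)
    y_c <- encode(cae, seg$core, "yhat_c", encoder = "E2")
    y_cp <- encode(cae, seg$core_penumbra, "yhat_cp", encoder = "E2")
  } else {
    if (is.null(case$core_mask) || is.null(case$core_penumbra_mask))
      stop("expert masks required in from_expert_masks mode")
    y_c <- encode(cae, case$core_mask, "y_c", encoder = "E1")
    y_cp <- encode(cae, case$core_penumbra_mask, "y_cp", encoder = "E1")
  }
  y_i <- interpolate_latent(y_c, y_cp, eta)
  prob <- decode(cae, new_latent_code(y_i, cae$config, "i"))
  res <- prediction_result(prob, eta, if (mode == "from_estimates")
    "shape_space" else "shape_space_expert", threshold)
  res$codes <- list(c = y_c, cp = y_cp, i = y_i)
  res
}

#' Best-in-hindsight interpolation fraction
#'
#' Searches a grid of eta values for the decoded interpolation with the best
#' hard Dice against the true follow-up lesion. The oracle Dice upper-bounds
#' the fixed-time prediction whenever the actual eta is on the grid; ties
#' break toward smaller eta (less predicted growth).
#'
#' @param y_c,y_cp latent codes of the core and core+penumbra shapes
#' @param cae a trained `cae_model` (its decoder is used)
#' @param s_l binary follow-up lesion mask
#' @param grid eta search grid in `[0, 1]`
#' @param threshold binarization threshold
#' @return list with `eta_star`, `dice_star`, and the per-grid-point `dice`
#' @export
oracle_eta <- function(y_c, y_cp, cae, s_l, grid = seq(0, 1, by = 0.05),
                       threshold = 0.5) {
  if (length(grid) == 0) stop("eta grid must be non-empty")
  stopifnot(all(grid >= 0), all(grid <= 1))
  dice <- vapply(grid, function(eta) {
    pr <- decode(cae, new_latent_code(interpolate_latent(y_c, y_cp, eta),
                                      cae$config, "i"))
    hard_dice((pr >= threshold) * 1, s_l)
  }, numeric(1))
  best <- which(dice == max(dice))[1]  # ties toward smaller eta
  list(eta_star = grid[best], dice_star = dice[best], grid = grid,
       dice = dice)
}
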