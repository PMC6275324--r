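# Synthetic nested-shape CTP case generator.
#
# Each case carries an ellipsoidal brain, a smooth random core blob confined
# to one hemisphere, a perturbed-dilation core+penumbra superset, and a
# follow-up lesion taken from the signed-distance interpolation family
# between the two, indexed so that the lesion's volume fraction along the
# core -> core+penumbra trajectory equals eta^gamma. CBV is depressed inside
# the core, TTD elevated inside core+penumbra (further inside the core), and
# both maps carry additive Gaussian noise. Generation is a pure function of
# (config, case index).

#' Synthetic dataset configuration
#'
#' @param grid volume extent; 64x64x16 is the desk scale, 128x128x28 the
#'   clinical-resolution grid
#' @param n_cases number of cases
#' @param horizon growth horizon T in hours after onset
#' @param core_volume_range core volume as a fraction of brain volume
#' @param penumbra_scale_range radial dilation factor of the core+penumbra
#'   blob relative to the core blob
#' @param t_onset_lognorm,t_treat_lognorm `c(meanlog, sdlog)` of the
#'   log-normal distributions for onset-to-imaging and imaging-to-treatment
#'   hours. The defaults reproduce the clinically reported medians and
#'   interquartile ranges (about 1.7 (1.4-3.4) h and 1.7 (1.4-2.1) h);
#'   onset times are truncated below the horizon and treatment times capped
#'   so the sum never exceeds it
#' @param eta_range optional override: when non-`NULL`, the true normalized
#'   fraction is drawn uniformly from this range and the treatment time is
#'   derived as `eta * (horizon - t_onset)` (useful for sweeping the whole
#'   trajectory evenly)
#' @param noise_sd additive Gaussian noise on both maps (arbitrary units;
#'   maps use baseline 1.0 with contrast steps of 0.5)
#' @param growth_exponent gamma: lesion volume fraction is `eta^gamma`;
#'   1 makes growth linear in eta, other values stress the model's
#'   linear-trajectory assumption
#' @param seed master seed; case `i` uses the substream `seed + i`
#' @return an object of class `synth_config`
#' @export
synth_config <- function(grid = c(64L, 64L, 16L), n_cases = 10L, horizon = 10,
                         core_volume_range = c(0.005, 0.05),
                         penumbra_scale_range = c(1.7, 2.2),
                         t_onset_lognorm = c(log(1.7), 0.66),
                         t_treat_lognorm = c(log(1.7), 0.30),
                         eta_range = NULL,
                         noise_sd = 0.1, growth_exponent = 1, seed = 1L) {
  stopifnot(length(grid) == 3L, all(grid >= 8L), n_cases >= 1, horizon > 0,
            all(core_volume_range > 0), diff(core_volume_range) >= 0,
            all(penumbra_scale_range > 1), noise_sd >= 0,
            growth_exponent > 0,
            length(t_onset_lognorm) == 2L, length(t_treat_lognorm) == 2L)
  if (!is.null(eta_range))
    stopifnot(all(eta_range >= 0), all(eta_range <= 1))
  structure(list(grid = as.integer(grid), n_cases = as.integer(n_cases),
                 horizon = horizon, core_volume_range = core_volume_range,
                 penumbra_scale_range = penumbra_scale_range,
                 t_onset_lognorm = t_onset_lognorm,
                 t_treat_lognorm = t_treat_lognorm, eta_range = eta_range,
                 noise_sd = noise_sd, growth_exponent = growth_exponent,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# smooth directional perturbation: a few von-Mises-like bumps on the sphere
smooth_sphere_noise <- function(u, n_bumps = 6L, kappa = 3) {
  dirs <- matrix(rnorm(3 * n_bumps), n_bumps, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coef <- rnorm(n_bumps, sd = 1 / sqrt(n_bumps))
  dots <- u %*% t(dirs)              # (vox x n_bumps), in [-1,1]
  as.numeric(exp(kappa * (dots - 1)) %*% coef) * exp(kappa / 2)
}

# signed distance: negative inside, positive outside (voxel units; axial
# spacing scaled so the metric is roughly isotropic in physical space)
signed_distance <- function(mask, grid) {
  sp <- c(1, 1, grid[1] / grid[3])
  d_to_mask <- sqrt(.edt3d_sq(as.logical(mask), as.integer(grid), sp))
  d_to_comp <- sqrt(.edt3d_sq(!as.logical(mask), as.integer(grid), sp))
  array(d_to_mask - d_to_comp, dim = grid)
}

#' Generate one synthetic case
#'
#' @param config a [synth_config()]
#' @param index case index in `1..n_cases`
#' @return a [perfusion_case()] with attributes `eta_true` (the normalized
#'   time used to place the lesion) and `hemisphere`
#' @export
generate_case <- function(config, index) {
  stopifnot(inherits(config, "synth_config"))
  if (index < 1 || index > config$n_cases)
    stop("index must lie in 1..n_cases")
  g <- config$grid
  for (attempt in 0:19) {
    set.seed(config$seed + as.integer(index) + attempt * 1000003L)
    case <- try(generate_case_once(config, index), silent = TRUE)
    if (!inherits(case, "try-error")) return(case)
  }
  stop("could not generate a feasible case for index ", index, ": ",
       attr(case, "condition")$message)
}

generate_case_once <- function(config, index) {
  g <- config$grid
  vox <- prod(g)
  ctr <- (g + 1) / 2
  zscale <- g[3] / g[1]  # axial extent relative to in-plane extent
  xs <- (seq_len(g[1]) - ctr[1])
  ys <- (seq_len(g[2]) - ctr[2])
  zs <- (seq_len(g[3]) - ctr[3]) / zscale  # isotropized coordinates
  X <- array(rep(xs, times = g[2] * g[3]), dim = g)
  Y <- array(rep(rep(ys, each = g[1]), times = g[3]), dim = g)
  Z <- array(rep(zs, each = g[1] * g[2]), dim = g)
  ax <- 0.45 * g[1]; ay <- 0.45 * g[2]; az <- 0.42 * g[1]
  brain <- (X / ax)^2 + (Y / ay)^2 + (Z / az)^2 <= 1
  brain_vol <- sum(brain)

  hemi_sign <- if (runif(1) < 0.5) -1 else 1
  hemi <- if (hemi_sign > 0) X > 0 else X < 0

  # core blob: perturbed sphere (in isotropized coordinates)
  frac <- runif(1, config$core_volume_range[1], config$core_volume_range[2])
  r0 <- (3 * frac * brain_vol / (4 * pi * zscale))^(1 / 3)
  cx <- hemi_sign * runif(1, 0.25, 0.55) * ax
  cy <- runif(1, -0.35, 0.35) * ay
  cz <- runif(1, -0.3, 0.3) * az
  dx <- X - cx; dy <- Y - cy; dz <- Z - cz
  rad <- sqrt(dx^2 + dy^2 + dz^2)
  rad[rad == 0] <- 1e-6
  u <- cbind(as.numeric(dx / rad), as.numeric(dy / rad), as.numeric(dz / rad))
  pert1 <- smooth_sphere_noise(u)
  pert2 <- smooth_sphere_noise(u)
  r_core <- r0 * pmax(1 + 0.25 * pert1, 0.4)
  scale_cp <- runif(1, config$penumbra_scale_range[1],
                    config$penumbra_scale_range[2])
  r_cp <- pmax(r0 * scale_cp * pmax(1 + 0.25 * pert2, 0.4), r_core + 1.5)
  core <- array(as.numeric(rad) <= r_core, dim = g) & brain & hemi
  cp <- array(as.numeric(rad) <= r_cp, dim = g) & brain & hemi
  if (sum(core) < 30 || sum(cp) <= sum(core) + 30)
    stop("degenerate blob (core escaped the brain mask); resampling")

  # times and the true normalized fraction
  if (!is.null(config$eta_range)) {
    t_on <- min(stats::rlnorm(1, config$t_onset_lognorm[1],
                              config$t_onset_lognorm[2]),
                0.8 * config$horizon)
    eta <- runif(1, config$eta_range[1], config$eta_range[2])
    t_tr <- eta * (config$horizon - t_on)
  } else {
    t_on <- min(stats::rlnorm(1, config$t_onset_lognorm[1],
                              config$t_onset_lognorm[2]),
                0.8 * config$horizon)
    t_tr <- min(stats::rlnorm(1, config$t_treat_lognorm[1],
                              config$t_treat_lognorm[2]),
                config$horizon - t_on)
    eta <- compute_eta(t_on, t_tr, config$horizon)
  }
  f <- eta^config$growth_exponent

  lesion <- interpolate_masks(core, cp, f, g)

  noise <- function() array(rnorm(vox, sd = config$noise_sd), dim = g)
  cbv <- (1 - 0.5 * core) * brain + noise() * brain
  ttd <- (1 + 0.5 * cp + 0.5 * core) * brain + noise() * brain

  case <- perfusion_case(
    case_id = sprintf("synth%03d", index),
    cbv = cbv, ttd = ttd,
    core_mask = core * 1, core_penumbra_mask = cp * 1,
    lesion_mask = lesion * 1,
    t_onset_to_imaging = t_on, t_imaging_to_treatment = t_tr)
  attr(case, "eta_true") <- eta
  attr(case, "hemisphere") <- if (hemi_sign > 0) "right" else "left"
  case
}

#' Interpolate between two nested masks along their signed-distance family
#'
#' Produces the member of the nested family of level sets
#' `{(1-a) d_core + a d_cp <= 0}` whose volume fraction between `|core|` and
#' `|cp|` equals `f` (found by bisection on `a`). `f = 0` returns the core
#' exactly, `f = 1` the core+penumbra.
#'
#' @param core,cp nested binary arrays (`core` inside `cp`)
#' @param f target volume fraction in `[0, 1]`
#' @param grid volume extent (defaults to `dim(core)`)
#' @return logical array between the two masks
#' @export
interpolate_masks <- function(core, cp, f, grid = dim(core)) {
  stopifnot(f >= 0, f <= 1)
  if (f == 0) return(array(core > 0, dim = grid))
  if (f == 1) return(array(cp > 0, dim = grid))
  d_c <- signed_distance(core, grid)
  d_p <- signed_distance(cp, grid)
  # deterministic micro-jitter breaks the exact ties of symmetric distance
  # shells, so the level-set family grows almost voxel-by-voxel
  jit <- array(1e-4 * (((seq_len(prod(grid)) * 2654435761) %% 1024) / 1024),
               dim = grid)
  jit[core > 0] <- 0
  n_c <- sum(core > 0); n_p <- sum(cp > 0)
  target <- n_c + f * (n_p - n_c)
  lo <- 0; hi <- 1
  for (i in 1:40) {
    a <- (lo + hi) / 2
    n_a <- sum((1 - a) * d_c + a * d_p + jit <= 0)
    if (n_a < target) lo <- a else hi <- a
  }
  m_lo <- (1 - lo) * d_c + lo * d_p + jit <= 0
  m_hi <- (1 - hi) * d_c + hi * d_p + jit <= 0
  if (abs(sum(m_hi) - target) < abs(sum(m_lo) - target)) m_hi else m_lo
}

#' Generate and write a synthetic dataset
#'
#' Writes `n_cases` cases as NIfTI volumes plus a manifest CSV consumable by
#' [read_manifest()]/[load_cases()]. Bit-exactly reproducible from the
#' configuration.
#'
#' @param config a [synth_config()]
#' @param out_dir output directory (created if missing)
#' @return the manifest data frame, invisibly; attribute `eta_true` carries
#'   the per-case true normalized times
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  etas <- numeric(config$n_cases)
  for (i in seq_len(config$n_cases)) {
    case <- generate_case(config, i)
    etas[i] <- attr(case, "eta_true")
    fn <- function(tag) paste0(case$case_id, "_", tag, ".nii.gz")
    write_volume(case$cbv, file.path(out_dir, fn("cbv")), datatype = "float")
    write_volume(case$ttd, file.path(out_dir, fn("ttd")), datatype = "float")
    write_volume(case$core_mask, file.path(out_dir, fn("core")),
                 datatype = "uint8")
    write_volume(case$core_penumbra_mask, file.path(out_dir, fn("cp")),
                 datatype = "uint8")
    write_volume(case$lesion_mask, file.path(out_dir, fn("lesion")),
                 datatype = "uint8")
    rows[[i]] <- data.frame(
      case_id = case$case_id, cbv = fn("cbv"), ttd = fn("ttd"),
      core = fn("core"), core_penumbra = fn("cp"), lesion = fn("lesion"),
      t_onset_to_imaging = case$t_onset_to_imaging,
      t_imaging_to_treatment = case$t_imaging_to_treatment,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "dir") <- normalizePath(out_dir)
  attr(manifest, "eta_true") <- etas
  invisible(manifest)
}

#' Generate a list of in-memory synthetic cases
#'
#' Convenience wrapper over [generate_case()] for workflows that do not need
#' files on disk.
#'
#' @param config a [synth_config()]
#' @return list of [perfusion_case()] objects
#' @export
generate_cases <- function(config) {
  lapply(seq_len(config$n_cases), function(i) generate_case(config, i))
}
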