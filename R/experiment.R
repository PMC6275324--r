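# Evaluation metrics and the end-to-end synthetic experiment.

#' Evaluate trained models on a set of cases
#'
#' Computes per-case hard Dice for the U-Net segmentations, the CAE
#' reconstructions, and the follow-up lesion predicted by shape-space
#' interpolation (automatic and expert-mask variants), the image-space
#' baseline, and the oracle-eta upper bound, plus growth-monotonicity
#' statistics across an eta sweep.
#'
#' @param cases list of [perfusion_case()] with ground-truth masks
#' @param unet trained `unet_model` (or `NULL` to skip estimate-based rows)
#' @param cae trained `cae_model`
#' @param horizon growth horizon in hours
#' @param eta_grid grid for the oracle search
#' @param sweep_grid eta values for the monotonicity sweep
#' @param threshold binarization threshold
#' @return data frame with one row per case
#' @export
evaluate_cases <- function(cases, unet, cae, horizon = 10,
                           eta_grid = seq(0, 1, by = 0.05),
                           sweep_grid = c(0, 0.25, 0.5, 0.75, 1),
                           threshold = 0.5) {
  rows <- lapply(cases, function(case) {
    eta <- case_eta(case, horizon)
    y_c <- encode(cae, case$core_mask, "y_c")
    y_cp <- encode(cae, case$core_penumbra_mask, "y_cp")
    r_c <- (decode(cae, y_c) >= threshold) * 1
    r_cp <- (decode(cae, y_cp) >= threshold) * 1
    pred_exp <- decode(cae, new_latent_code(
      interpolate_latent(y_c, y_cp, eta), cae$config, "i"))
    dice_exp <- if (!is.null(case$lesion_mask))
      hard_dice((pred_exp >= threshold) * 1, case$lesion_mask) else NA_real_
    orc <- if (!is.null(case$lesion_mask))
      oracle_eta(y_c, y_cp, cae, case$lesion_mask,
                 sort(unique(c(eta_grid, eta))), threshold)
      else list(eta_star = NA_real_, dice_star = NA_real_)
    # monotonicity of decoded growth along the trajectory
    sweep_masks <- lapply(sweep_grid, function(e)
      (decode(cae, new_latent_code(interpolate_latent(y_c, y_cp, e),
                                   cae$config, "i")) >= threshold) * 1)
    viol <- vapply(seq_len(length(sweep_masks) - 1L), function(i) {
      prev <- sweep_masks[[i]]; nxt <- sweep_masks[[i + 1L]]
      sum(prev > nxt) / max(1, sum(prev))
    }, numeric(1))
    out <- data.frame(
      case_id = case$case_id, eta = eta,
      eta_true = attr(case, "eta_true") %||% NA_real_,
      dice_recon_core = hard_dice(r_c, case$core_mask),
      dice_recon_cp = hard_dice(r_cp, case$core_penumbra_mask),
      dice_lesion_expert = dice_exp,
      eta_star = orc$eta_star, dice_lesion_oracle = orc$dice_star,
      mono_violation = max(viol),
      mono_decoded = mono_penalty(decode(cae, y_c), decode(cae, y_cp)) /
        max(1, sum(case$core_penumbra_mask)),
      stringsAsFactors = FALSE)
    if (!is.null(unet)) {
      seg <- segment(unet, case)
      out$dice_core <- hard_dice((seg$core >= threshold) * 1, case$core_mask)
      out$dice_cp <- hard_dice((seg$core_penumbra >= threshold) * 1,
                               case$core_penumbra_mask)
      base <- image_space_interpolate(seg$core, seg$core_penumbra, eta,
                                      threshold)
      out$dice_lesion_image <- if (!is.null(case$lesion_mask))
        hard_dice(base$mask, case$lesion_mask) else NA_real_
      if (!is.null(cae$encoder2)) {
        pr <- predict_followup(case, list(unet = unet, cae = cae), horizon,
                               mode = "from_estimates", threshold = threshold)
        out$dice_lesion_shape <- if (!is.null(case$lesion_mask))
          hard_dice(pr$mask, case$lesion_mask) else NA_real_
        yh_cp <- encode(cae, seg$core_penumbra, "yhat_cp", encoder = "E2")
        yh_c <- encode(cae, seg$core, "yhat_c", encoder = "E2")
        out$dice_recon_cp_e2 <- hard_dice(
          (decode(cae, yh_cp) >= threshold) * 1, case$core_penumbra_mask)
        out$dice_recon_core_e2 <- hard_dice(
          (decode(cae, yh_c) >= threshold) * 1, case$core_mask)
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname evaluate_cases
#' @param metrics a data frame from [evaluate_cases()]
#' @export
summarize_metrics <- function(metrics) {
  num <- vapply(metrics, is.numeric, logical(1))
  colMeans(metrics[, num, drop = FALSE], na.rm = TRUE)
}

#' Desk-scale default configurations
#'
#' Model and training settings for the 64x64x16 synthetic study: a narrower
#' U-Net (4/8/16 channels, 32x32x16 patches with 4 voxels of context) and
#' CAE (widths 2/6/12/12, 5x5x2 bottleneck with 12 channels), with the
#' three-phase epoch schedule scaled to one fifth of the clinical-scale
#' defaults (U-Net 20, shape space 40 with the alignment switch at 5,
#' prediction encoder 10), batch size 1, no elastic augmentation, the
#' monotonicity hinges deferred beyond the schedule, and a learning-rate
#' decay over the last quarter of shape-space training. These sizes keep
#' the full experiment tractable on a single CPU while preserving every
#' architectural element of the full-scale models; the rationale for each
#' choice is laid out in the package vignette.
#'
#' @param grid volume extent of the synthetic cases
#' @param seed integer seed
#' @return list with `unet`, `cae`, `train` and `loss` configurations
#' @export
desk_configs <- function(grid = c(64L, 64L, 16L), seed = 1L) {
  list(
    unet = unet_config(channels = c(4L, 8L, 16L),
                       patch_size = as.integer(grid / 2),
                       context_pad = 2L),
    cae = cae_config(input_dim = grid, widths = c(2L, 6L, 12L, 12L),
                     bottleneck_channels = 12L,
                     bottleneck_extent = pmax(1L, as.integer(round(
                       grid * c(5 / 64, 5 / 64, 2 / 16))))),
    train = train_config(scale = 0.2, batch_size = 1L,
                         mono_switch_epoch = Inf, lr_decay_epoch = 31L,
                         finetune_lr = 1e-4, elastic_sd = 0, val_every = 2L,
                         seed = seed),
    loss = loss_config(alpha_switch_epoch = 5L)
  )
}

#' Run the end-to-end synthetic experiment
#'
#' Generates a synthetic cohort, trains all three phases on a train/
#' validation split, and evaluates the held-out test cases: U-Net and CAE
#' reconstruction quality, shape-space vs image-space lesion prediction,
#' the oracle-eta bound and recovery of the generative eta, and growth
#' monotonicity.
#'
#' @param seed master seed for generation and training
#' @param n_train,n_test cohort sizes (about a quarter of the training pool
#'   is held out for validation-based model selection)
#' @param grid volume extent
#' @param horizon growth horizon in hours
#' @param configs configurations from [desk_configs()] (or compatible)
#' @param verbose print progress
#' @return list with `unet`, `cae`, per-test-case `metrics`, `summary` and
#'   `elapsed` seconds per stage
#' @export
run_synthetic_experiment <- function(seed = 1L, n_train = 60L, n_test = 20L,
                                     grid = c(64L, 64L, 16L), horizon = 10,
                                     configs = desk_configs(grid, seed),
                                     verbose = FALSE) {
  t_all <- proc.time()[3]
  sc <- synth_config(grid = grid, n_cases = n_train + n_test,
                     horizon = horizon, seed = seed)
  cases <- generate_cases(sc)
  names(cases) <- vapply(cases, function(x) x$case_id, "")
  set.seed(seed + 17L)
  val_idx <- sort(sample.int(n_train, max(1L, round(n_train / 4))))
  train_cases <- cases[setdiff(seq_len(n_train), val_idx)]
  val_cases <- cases[val_idx]
  test_cases <- cases[n_train + seq_len(n_test)]
  elapsed <- c(generate = proc.time()[3] - t_all)

  t0 <- proc.time()[3]
  unet <- train_unet(train_cases, val_cases, configs$unet, configs$train,
                     configs$loss, verbose = verbose)
  elapsed["unet"] <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  cae <- train_shape_space(train_cases, val_cases, configs$cae,
                           configs$train, configs$loss, horizon,
                           verbose = verbose)
  elapsed["shape"] <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  cae <- train_prediction_encoder(train_cases, val_cases, unet, cae,
                                  configs$train, configs$loss, horizon,
                                  verbose = verbose)
  elapsed["prediction"] <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  metrics <- evaluate_cases(test_cases, unet, cae, horizon = horizon)
  elapsed["evaluate"] <- proc.time()[3] - t0
  elapsed["total"] <- proc.time()[3] - t_all

  list(unet = unet, cae = cae, metrics = metrics,
       summary = summarize_metrics(metrics), elapsed = elapsed)
}
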