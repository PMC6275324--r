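# Three-phase training: (1) U-Net segmentation with SoftDice losses on
# randomly positioned patches; (2) shape-space learning of E1 and the
# decoder D with the composite shape loss; (3) the estimate encoder E2
# fitted to the frozen shape space with the prediction loss. Each phase
# selects the checkpoint with the lowest validation loss.

#' Training configuration
#'
#' @param lr Adam learning rate
#' @param batch_size cases (or patches) per optimizer step
#' @param epochs_unet,epochs_shape,epochs_prediction epochs per phase
#' @param alpha_switch_epoch epoch at which the latent-alignment weight
#'   switches on during shape-space training; scales together with the
#'   epoch counts when `scale` shrinks the schedule
#' @param mono_switch_epoch epoch from which the monotonicity hinges enter
#'   the composite objectives (1 = from the start, the clinical-scale
#'   default; `Inf` withholds them). The hinge's voxel-sum gradients dwarf
#'   the overlap terms' by orders of magnitude, so short desk-scale
#'   schedules learn reconstruction without it — ordering of decoded
#'   nested shapes emerges from the data; does not rescale with `scale`
#' @param lr_decay_epoch epoch at which the learning rate drops to
#'   `finetune_lr` (`NULL` disables the decay)
#' @param finetune_lr learning rate used from `lr_decay_epoch` onward
#' @param scale single factor applied to all epoch counts (desk-scale runs)
#' @param patience early-stopping patience (epochs without validation
#'   improvement) for the U-Net phase; `Inf` disables early stopping
#' @param elastic_sd,elastic_spacing displacement standard deviation
#'   (voxels) and coarse-grid spacing of the elastic augmentation applied to
#'   CAE training shapes; `elastic_sd = 0` disables augmentation
#' @param val_every validate (and consider checkpoints) every this many
#'   shape-space epochs; the final epoch is always validated
#' @param seed integer seed controlling initialization, patch positions and
#'   augmentation
#' @return an object of class `train_config`
#' @export
train_config <- function(lr = 1e-3, batch_size = 4L, epochs_unet = 100L,
                         epochs_shape = 200L, epochs_prediction = 50L,
                         alpha_switch_epoch = 25L, mono_switch_epoch = 1,
                         lr_decay_epoch = NULL, finetune_lr = NULL,
                         scale = 1,
                         patience = 20L, elastic_sd = 1.5,
                         elastic_spacing = 16L, val_every = 1L, seed = 1L) {
  stopifnot(batch_size >= 1, lr > 0, scale > 0)
  sc <- function(e) max(1L, as.integer(round(e * scale)))
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs_unet = sc(epochs_unet),
                 epochs_shape = sc(epochs_shape),
                 epochs_prediction = sc(epochs_prediction),
                 alpha_switch_epoch = sc(alpha_switch_epoch),
                 mono_switch_epoch = mono_switch_epoch,
                 lr_decay_epoch = lr_decay_epoch,
                 finetune_lr = finetune_lr,
                 patience = patience, elastic_sd = elastic_sd,
                 elastic_spacing = as.integer(elastic_spacing),
                 val_every = as.integer(val_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Elastic deformation of congruent volumes
#'
#' Draws one smooth random displacement field (Gaussian displacements on a
#' coarse control grid, trilinearly upsampled) and applies it identically to
#' every volume in the list, so paired masks deform together and nesting is
#' preserved almost everywhere. Volumes containing only 0/1 are re-binarized
#' at 0.5 after interpolation.
#'
#' @param volumes list of congruent 3D arrays
#' @param sd displacement standard deviation in voxels
#' @param spacing coarse control-grid spacing in voxels
#' @param seed optional seed for a reproducible field
#' @param max_disp displacements beyond this cap are clipped with a warning
#' @return list of deformed volumes
#' @export
elastic_deform <- function(volumes, sd = 1.5, spacing = 16L, seed = NULL,
                           max_disp = NULL) {
  stopifnot(length(volumes) >= 1)
  d <- dim(volumes[[1]])
  for (v in volumes) stopifnot(all(dim(v) == d))
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(volumes)
  cd <- pmax(2L, as.integer(ceiling(d / spacing)) + 1L)
  disp_c <- matrix(rnorm(prod(cd) * 3, sd = sd), ncol = 3)
  # displacements beyond the control-grid spacing would let the field fold
  if (is.null(max_disp)) max_disp <- spacing
  if (any(abs(disp_c) > max_disp)) {
    warning("elastic displacement exceeded ", max_disp, " voxels; clipping")
    disp_c <- pmin(pmax(disp_c, -max_disp), max_disp)
  }
  disp <- .resize3d(disp_c, cd, 1L, as.integer(d), FALSE)
  stack <- do.call(cbind, lapply(volumes, as.numeric))
  warped <- .warp3d(stack, as.integer(d), disp)
  out <- lapply(seq_along(volumes), function(i) {
    v <- array(warped[, i], dim = d)
    if (all(volumes[[i]] %in% c(0, 1))) v <- (v >= 0.5) * 1
    v
  })
  names(out) <- names(volumes)
  out
}

make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  unname(split(idx, ceiling(seq_along(idx) / batch_size)))
}

new_history <- function() {
  data.frame(epoch = integer(), train = numeric(), val = numeric())
}

#' Train the U-Net segmenter
#'
#' Optimizes `L_SoftDice(core) + L_SoftDice(core+penumbra)` on randomly
#' positioned patches with Adam, evaluates the same loss on a central patch
#' of each validation case every epoch, and returns the parameters with the
#' lowest validation loss. Training stops early when the validation loss has
#' not improved for `patience` epochs.
#'
#' @param train_cases,val_cases lists of [perfusion_case()] with masks
#' @param unet_cfg a [unet_config()]
#' @param config a [train_config()]
#' @param loss_cfg a [loss_config()]
#' @param verbose print per-epoch losses
#' @return a `unet_model`; attribute `history` holds per-epoch train/val
#'   losses and the selected epoch
#' @export
train_unet <- function(train_cases, val_cases, unet_cfg = unet_config(),
                       config = train_config(), loss_cfg = loss_config(),
                       verbose = FALSE) {
  if (length(train_cases) == 0) stop("empty training set")
  model <- build_unet(unet_cfg, seed = config$seed)
  opt <- adam_init(model$params, lr = config$lr)
  eps <- loss_cfg$epsilon
  hist <- new_history()
  best <- list(val = Inf, params = NULL, states = NULL, epoch = 0L)
  patch_loss <- function(pp, patch, training) {
    logits <- unet_fw(unet_cfg, pp, model$states, patch$input,
                      patch$input_dims, 1L, training = training)
    probs <- ag_sigmoid(ag_rows(logits, patch$core_idx))
    soft_dice_loss(ag_cols(probs, 1L), patch$target[, 1, drop = FALSE], eps) +
      soft_dice_loss(ag_cols(probs, 2L), patch$target[, 2, drop = FALSE], eps)
  }
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$epochs_unet)) {
    tr_loss <- 0; nb <- 0
    for (batch in make_batches(length(train_cases), config$batch_size)) {
      tape <- ag_tape()
      pp <- wrap_params(tape, model$params)
      loss <- NULL
      for (ci in batch) {
        patch <- sample_training_patch(train_cases[[ci]], unet_cfg)
        l <- patch_loss(pp, patch, TRUE)
        loss <- if (is.null(loss)) l else loss + l
      }
      loss <- loss / length(batch)
      ag_backward(loss)
      st <- adam_step(opt, model$params, collect_grads(pp))
      opt <- st$opt; model$params <- st$params
      tr_loss <- tr_loss + ag_value(loss); nb <- nb + 1
    }
    val_loss <- mean(vapply(val_cases, function(case) {
      patch <- central_patch(case, unet_cfg)
      ag_value(patch_loss(model$params, patch, FALSE))
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, train = tr_loss / nb,
                                   val = val_loss))
    if (val_loss < best$val)
      best <- list(val = val_loss, params = copy_params(model$params),
                   states = copy_states(model$states), epoch = epoch)
    if (verbose)
      message(sprintf("unet epoch %d train %.4f val %.4f", epoch,
                      tr_loss / nb, val_loss))
    if (is.finite(config$patience) && epoch - best$epoch >= config$patience)
      break
  }
  model$params <- best$params
  model$states <- best$states
  attr(model, "history") <- hist
  attr(model, "selected_epoch") <- best$epoch
  model
}

central_patch <- function(case, unet_cfg) {
  vd <- dim(case$cbv)
  ps <- pmin(unet_cfg$patch_size, vd)
  start <- as.integer((vd - ps) %/% 2L)
  extract_patch(case, start, ps, unet_cfg$context_pad)
}

# per-case eta values under a horizon
case_eta <- function(case, horizon) {
  compute_eta(case$t_onset_to_imaging, case$t_imaging_to_treatment, horizon)
}

#' Train the shape space (E1 and decoder D)
#'
#' For every case the core, core+penumbra and follow-up lesion masks are
#' encoded independently, the interpolated code `y_i` is formed at the
#' case's normalized time, all three shapes are decoded, and the composite
#' shape loss is minimized with Adam. The latent-alignment term is switched
#' on after `alpha_switch_epoch` epochs. Shapes are elastically deformed
#' (jointly per case) every epoch when augmentation is enabled.
#'
#' @param train_cases,val_cases lists of [perfusion_case()] with all masks
#'   and times
#' @param cae_cfg a [cae_config()]
#' @param config a [train_config()]
#' @param loss_cfg a [loss_config()]
#' @param horizon growth horizon in hours
#' @param verbose print per-epoch losses
#' @return a `cae_model` (encoder = E1); attribute `history` as in
#'   [train_unet()]
#' @export
train_shape_space <- function(train_cases, val_cases, cae_cfg = cae_config(),
                              config = train_config(),
                              loss_cfg = loss_config(), horizon = 10,
                              verbose = FALSE) {
  for (case in train_cases)
    if (is.null(case$lesion_mask))
      stop("case ", case$case_id, " lacks the follow-up lesion mask ",
           "required for shape-space training")
  model <- build_cae(cae_cfg, seed = config$seed)
  params <- list(E = model$encoder$params, D = model$decoder$params)
  optE <- adam_init(params$E, lr = config$lr)
  optD <- adam_init(params$D, lr = config$lr)
  hist <- new_history()
  best <- list(val = Inf, model = NULL, epoch = 0L)
  etas_tr <- vapply(train_cases, case_eta, numeric(1), horizon = horizon)
  etas_va <- vapply(val_cases, case_eta, numeric(1), horizon = horizon)

  # With all terms active this equals shape_loss(); the lesion-trajectory
  # reconstruction R_i is the decode of the interpolated code at the
  # case's normalized time (the "intermediate lesion interpolation"), so
  # its overlap term calibrates the decoded trajectory against the true
  # follow-up lesion. During the reconstruction stage the monotonicity
  # hinges are withheld (their voxel-sum gradients otherwise flatten the
  # decoder into code-insensitive outputs before reconstruction is learned).
  case_loss <- function(ppe, ppd, shapes, eta, alpha, use_mono, training) {
    x3 <- rbind(shapes$c, shapes$l, shapes$cp)
    attr(x3, "d") <- cae_cfg$input_dim
    all_codes <- cae_encode_fw(cae_cfg, ppe, model$encoder$states, x3, 3L,
                               training)
    nc_ <- nrow(ag_value(all_codes)) / 3L
    codes <- list(c = ag_rows(all_codes, seq_len(nc_)),
                  l = ag_rows(all_codes, nc_ + seq_len(nc_)),
                  cp = ag_rows(all_codes, 2L * nc_ + seq_len(nc_)))
    y_i <- interpolate_latent(codes$c, codes$cp, eta)
    dec_in <- rbind2_t(codes$c, rbind2_t(codes$cp, y_i))
    all_recs <- cae_decode_fw(cae_cfg, ppd, model$decoder$states, dec_in,
                              3L, training)
    nv_ <- nrow(ag_value(all_recs)) / 3L
    recs <- list(c = ag_rows(all_recs, seq_len(nv_)),
                 cp = ag_rows(all_recs, nv_ + seq_len(nv_)),
                 i = ag_rows(all_recs, 2L * nv_ + seq_len(nv_)))
    eps <- loss_cfg$epsilon
    loss <- soft_dice_loss(recs$c, shapes$c, eps) +
      soft_dice_loss(recs$cp, shapes$cp, eps)
    if (loss_cfg$include_lesion_recon)
      loss <- loss + soft_dice_loss(recs$i, shapes$l, eps)
    if (use_mono)
      loss <- loss + mono_penalty(recs$c, recs$cp) +
        mono_penalty(recs$i, recs$cp)
    if (alpha != 0)
      loss <- loss + alpha * latent_l1(codes$l, y_i)
    loss
  }
  case_shapes <- function(case, augment) {
    s <- list(c = case$core_mask, l = case$lesion_mask,
              cp = case$core_penumbra_mask)
    if (augment && config$elastic_sd > 0) {
      s <- elastic_deform(s, sd = config$elastic_sd,
                          spacing = config$elastic_spacing)
    }
    lapply(s, vol_as_mat)
  }

  set.seed(config$seed + 2L)
  for (epoch in seq_len(config$epochs_shape)) {
    alpha <- if (epoch > config$alpha_switch_epoch) 1 else 0
    use_mono <- epoch >= config$mono_switch_epoch
    if (!is.null(config$lr_decay_epoch) && !is.null(config$finetune_lr) &&
        epoch == config$lr_decay_epoch) {
      optE$lr <- config$finetune_lr
      optD$lr <- config$finetune_lr
    }
    tr_loss <- 0; nb <- 0
    for (batch in make_batches(length(train_cases), config$batch_size)) {
      tape <- ag_tape()
      ppe <- wrap_params(tape, params$E)
      ppd <- wrap_params(tape, params$D)
      loss <- NULL
      for (ci in batch) {
        shapes <- case_shapes(train_cases[[ci]], augment = TRUE)
        l <- case_loss(ppe, ppd, shapes, etas_tr[ci], alpha, use_mono, TRUE)
        loss <- if (is.null(loss)) l else loss + l
      }
      loss <- loss / length(batch)
      ag_backward(loss)
      stE <- adam_step(optE, params$E, collect_grads(ppe))
      optE <- stE$opt; params$E <- stE$params
      stD <- adam_step(optD, params$D, collect_grads(ppd))
      optD <- stD$opt; params$D <- stD$params
      tr_loss <- tr_loss + ag_value(loss); nb <- nb + 1
    }
    model$encoder$params <- params$E
    model$decoder$params <- params$D
    # validation scores the schedule's full objective (hinges included only
    # if the schedule ever activates them) so checkpoints are comparable
    if (epoch %% config$val_every != 0 && epoch != config$epochs_shape)
      next
    mono_val <- config$epochs_shape >= config$mono_switch_epoch
    val_loss <- mean(vapply(seq_along(val_cases), function(i) {
      shapes <- case_shapes(val_cases[[i]], augment = FALSE)
      ag_value(case_loss(params$E, params$D, shapes, etas_va[i], 1,
                         mono_val, FALSE))
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, train = tr_loss / nb,
                                   val = val_loss))
    if (val_loss < best$val)
      best <- list(val = val_loss,
                   model = list(E = copy_params(params$E),
                                D = copy_params(params$D),
                                stE = copy_states(model$encoder$states),
                                stD = copy_states(model$decoder$states)),
                   epoch = epoch)
    if (verbose)
      message(sprintf("shape epoch %d (alpha=%d) train %.4f val %.4f",
                      epoch, alpha, tr_loss / nb, val_loss))
  }
  model$encoder$params <- best$model$E
  model$decoder$params <- best$model$D
  model$encoder$states <- best$model$stE
  model$decoder$states <- best$model$stD
  attr(model, "history") <- hist
  attr(model, "selected_epoch") <- best$epoch
  model
}

#' Train the estimate encoder E2 against the frozen shape space
#'
#' The U-Net's soft segmentations and the ground-truth latent codes (from
#' the frozen E1) are precomputed per case; E2 (initialized from E1) is then
#' optimized under the prediction loss while E1 and the decoder remain
#' untouched. An error is raised if the decoder parameters change.
#'
#' @param train_cases,val_cases lists of [perfusion_case()]
#' @param unet a trained `unet_model`
#' @param cae a trained `cae_model` (E1 + D)
#' @param config a [train_config()]
#' @param loss_cfg a [loss_config()]
#' @param horizon growth horizon in hours
#' @param verbose print per-epoch losses
#' @return the `cae_model` with an added `encoder2` (E2); attribute
#'   `history` as in [train_unet()]
#' @export
train_prediction_encoder <- function(train_cases, val_cases, unet, cae,
                                     config = train_config(),
                                     loss_cfg = loss_config(), horizon = 10,
                                     verbose = FALSE) {
  cae_cfg <- cae$config
  d_before <- unlist(cae$decoder$params, use.names = FALSE)
  e2 <- list(params = copy_params(cae$encoder$params),
             states = copy_states(cae$encoder$states))
  opt <- adam_init(e2$params, lr = config$lr)
  hist <- new_history()
  best <- list(val = Inf, model = NULL, epoch = 0L)

  prep <- function(case) {
    seg <- segment(unet, case)
    y_c <- encode(cae, case$core_mask, "y_c")
    y_cp <- encode(cae, case$core_penumbra_mask, "y_cp")
    y_l <- encode(cae, case$lesion_mask, "y_l")
    eta <- case_eta(case, horizon)
    list(shat_c = vol_as_mat(seg$core), shat_cp = vol_as_mat(seg$core_penumbra),
         s_l = vol_as_mat(case$lesion_mask),
         y_c = unclass_code(y_c), y_l = unclass_code(y_l),
         y_i = unclass_code(interpolate_latent(y_c, y_cp, eta)), eta = eta)
  }
  tr <- lapply(train_cases, prep)
  va <- lapply(val_cases, prep)

# With the hinges active this equals prediction_loss(); the schedule can
  # withhold them (see train_config).
  case_loss <- function(pp, p, use_mono, training) {
    x <- rbind(p$shat_c, p$shat_cp)
    attr(x, "d") <- cae_cfg$input_dim
    codes <- cae_encode_fw(cae_cfg, pp, e2$states, x, 2L, training)
    nb_ <- nrow(ag_value(codes)) / 2L
    yh_c <- ag_rows(codes, seq_len(nb_))
    yh_cp <- ag_rows(codes, nb_ + seq_len(nb_))
    yh_i <- interpolate_latent(yh_c, yh_cp, p$eta)
    allc <- rbind2_t(yh_c, rbind2_t(yh_cp, yh_i))
    dec <- cae_decode_fw(cae_cfg, cae$decoder$params, cae$decoder$states,
                         allc, 3L, FALSE)
    nv <- nrow(ag_value(dec)) / 3L
    d_c <- ag_rows(dec, seq_len(nv))
    d_cp <- ag_rows(dec, nv + seq_len(nv))
    pred <- ag_rows(dec, 2L * nv + seq_len(nv))
    loss <- soft_dice_loss(pred, p$s_l, loss_cfg$epsilon) +
      latent_l1(yh_c, p$y_c) + latent_l1(yh_i, p$y_l) +
      latent_l1(yh_i, p$y_i)
    if (use_mono)
      loss <- loss + mono_penalty(d_c, d_cp) + mono_penalty(pred, d_cp)
    loss
  }

  set.seed(config$seed + 3L)
  for (epoch in seq_len(config$epochs_prediction)) {
    use_mono <- epoch >= config$mono_switch_epoch
    tr_loss <- 0; nb <- 0
    for (batch in make_batches(length(tr), config$batch_size)) {
      tape <- ag_tape()
      pp <- wrap_params(tape, e2$params)
      loss <- NULL
      for (ci in batch) {
        l <- case_loss(pp, tr[[ci]], use_mono, TRUE)
        loss <- if (is.null(loss)) l else loss + l
      }
      loss <- loss / length(batch)
      ag_backward(loss)
      st <- adam_step(opt, e2$params, collect_grads(pp))
      opt <- st$opt; e2$params <- st$params
      tr_loss <- tr_loss + ag_value(loss); nb <- nb + 1
    }
    val_loss <- mean(vapply(va, function(p)
      ag_value(case_loss(e2$params, p,
                         config$epochs_prediction >= config$mono_switch_epoch,
                         FALSE)), numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, train = tr_loss / nb,
                                   val = val_loss))
    if (val_loss < best$val)
      best <- list(val = val_loss, model = list(params = copy_params(e2$params),
                                                states = copy_states(e2$states)),
                   epoch = epoch)
    if (verbose)
      message(sprintf("prediction epoch %d train %.4f val %.4f", epoch,
                      tr_loss / nb, val_loss))
  }
  d_after <- unlist(cae$decoder$params, use.names = FALSE)
  if (!identical(d_before, d_after))
    stop("internal consistency error: decoder parameters drifted during ",
         "phase 2 although they must stay frozen")
  cae$encoder2 <- best$model
  attr(cae, "history2") <- hist
  attr(cae, "selected_epoch2") <- best$epoch
  cae
}

# stack two code tensors/matrices along rows (batch)
rbind2_t <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  v <- rbind(va, vb)
  if (!is_tensor(a) && !is_tensor(b)) return(v)
  tape <- tape_of(a, b)
  na <- nrow(va)
  ta <- is_tensor(a); tb <- is_tensor(b)
  parents <- c(if (ta) list(a), if (tb) list(b))
  ag_node(tape, v, parents, function(g) {
    out <- list()
    if (ta) out <- c(out, list(g[seq_len(na), , drop = FALSE]))
    if (tb) out <- c(out, list(g[-seq_len(na), , drop = FALSE]))
    out
  })
}

#' Run a k-fold cross-validation experiment
#'
#' Builds folds with [make_folds()], trains all three phases on each
#' training split (holding out about a quarter of it for validation-based
#' model selection), evaluates the held-out fold, and aggregates the
#' per-case metrics. A failing fold is recorded and the remaining folds
#' continue.
#'
#' @param cases named list of [perfusion_case()]
#' @param k number of folds
#' @param unet_cfg,cae_cfg,config,loss_cfg configurations
#' @param horizon growth horizon in hours
#' @param verbose print progress
#' @return list with `folds` (the assignment), `bundles` (per-fold trained
#'   models), `metrics` (per-case data frame) and `summary` (mean Dice per
#'   method)
#' @export
run_kfold <- function(cases, k = 5L, unet_cfg = unet_config(),
                      cae_cfg = cae_config(), config = train_config(),
                      loss_cfg = loss_config(), horizon = 10,
                      verbose = FALSE) {
  folds <- make_folds(names(cases), k, seed = config$seed)
  metrics <- list(); bundles <- list()
  for (f in 0:(k - 1L)) {
    test_ids <- folds$case_id[folds$fold == f]
    pool_ids <- folds$case_id[folds$fold != f]
    n_val <- max(1L, round(length(pool_ids) / 4))
    set.seed(config$seed + f)
    val_ids <- sample(pool_ids, n_val)
    train_ids <- setdiff(pool_ids, val_ids)
    res <- try({
      unet <- train_unet(cases[train_ids], cases[val_ids], unet_cfg, config,
                         loss_cfg, verbose)
      cae <- train_shape_space(cases[train_ids], cases[val_ids], cae_cfg,
                               config, loss_cfg, horizon, verbose)
      cae <- train_prediction_encoder(cases[train_ids], cases[val_ids],
                                      unet, cae, config, loss_cfg, horizon,
                                      verbose)
      m <- evaluate_cases(cases[test_ids], unet, cae, horizon = horizon)
      m$fold <- f
      bundles[[as.character(f)]] <- list(unet = unet, cae = cae)
      metrics[[as.character(f)]] <- m
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("fold ", f, " failed: ", attr(res, "condition")$message)
      bundles[[as.character(f)]] <- NULL
    }
  }
  metrics <- do.call(rbind, metrics)
  list(folds = folds, bundles = bundles, metrics = metrics,
       summary = summarize_metrics(metrics))
}
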