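# Training pipeline: augmentation, model selection, determinism, freezing.

small_cfgs <- function(seed = 11L) {
  list(unet = unet_config(channels = c(2L, 4L, 8L),
                          patch_size = c(16L, 16L, 8L), context_pad = 2L),
       cae = cae_config(input_dim = c(32L, 32L, 8L),
                        widths = c(2L, 4L, 4L, 4L), bottleneck_channels = 4L,
                        bottleneck_extent = c(3L, 3L, 1L)),
       train = train_config(scale = 0.02, batch_size = 2L, seed = seed,
                            patience = Inf),
       loss = loss_config(alpha_switch_epoch = 1L))
}

smoke_cases <- function(n = 5L, seed = 19L) {
  cfg <- smoke_synth_config(n_cases = n, seed = seed)
  cases <- generate_cases(cfg)
  names(cases) <- vapply(cases, function(x) x$case_id, "")
  cases
}

test_that("elastic deformation: identity at zero sd, deterministic, nesting-safe", {
  case <- smoke_cases(1)[[1]]
  vols <- list(c = case$core_mask, l = case$lesion_mask,
               cp = case$core_penumbra_mask)
  same <- elastic_deform(vols, sd = 0, seed = 1)
  expect_identical(same$c, vols$c)
  d1 <- elastic_deform(vols, sd = 1.5, seed = 42)
  d2 <- elastic_deform(vols, sd = 1.5, seed = 42)
  expect_identical(d1, d2)
  expect_false(identical(d1$c, vols$c))
  # jointly deformed nested masks stay nested almost everywhere
  viol <- 0; tot <- 0
  for (s in 1:50) {
    d <- elastic_deform(vols, sd = 1.5, seed = s)
    viol <- viol + sum(d$c > d$l) + sum(d$l > d$cp)
    tot <- tot + 2 * length(d$c)
  }
  expect_lt(viol / tot, 0.001)
  expect_warning(elastic_deform(vols, sd = 1e3, seed = 1), "clipping")
})

test_that("U-Net smoke training improves and selects the argmin-validation epoch", {
  cases <- smoke_cases(5)
  cfgs <- small_cfgs()
  cfgs$train <- train_config(scale = 1, epochs_unet = 5L, batch_size = 2L,
                             seed = 11L, patience = Inf)
  m <- train_unet(cases[1:3], cases[4:5], cfgs$unet, cfgs$train, cfgs$loss)
  hist <- attr(m, "history")
  expect_equal(nrow(hist), 5)
  expect_identical(attr(m, "selected_epoch"), which.min(hist$val))
  expect_lte(hist$val[attr(m, "selected_epoch")], hist$val[1])
  # identical seeds give identical loss curves
  m2 <- train_unet(cases[1:3], cases[4:5], cfgs$unet, cfgs$train, cfgs$loss)
  expect_identical(attr(m2, "history"), hist)
  expect_error(train_unet(list(), cases[4:5], cfgs$unet, cfgs$train),
               "empty")
})

test_that("shape-space training requires lesions and tracks validation loss", {
  cases <- smoke_cases(5)
  cfgs <- small_cfgs()
  cfgs$train <- train_config(scale = 1, epochs_shape = 3L,
                             alpha_switch_epoch = 1L, batch_size = 2L,
                             seed = 11L)
  cae <- train_shape_space(cases[1:3], cases[4:5], cfgs$cae, cfgs$train,
                           cfgs$loss)
  hist <- attr(cae, "history")
  expect_equal(nrow(hist), 3)
  expect_identical(attr(cae, "selected_epoch"), which.min(hist$val))
  broken <- cases[1:3]
  broken[[1]]$lesion_mask <- NULL
  expect_error(train_shape_space(broken, cases[4:5], cfgs$cae, cfgs$train,
                                 cfgs$loss), "lesion")
})

test_that("phase 2 leaves the decoder and E1 bitwise frozen", {
  cases <- smoke_cases(5)
  cfgs <- small_cfgs()
  cfgs$train <- train_config(scale = 1, epochs_unet = 2L, epochs_shape = 2L,
                             epochs_prediction = 2L,
                             alpha_switch_epoch = 1L, batch_size = 2L,
                             seed = 11L, patience = Inf)
  unet <- train_unet(cases[1:3], cases[4:5], cfgs$unet, cfgs$train, cfgs$loss)
  cae <- train_shape_space(cases[1:3], cases[4:5], cfgs$cae, cfgs$train,
                           cfgs$loss)
  d_before <- unlist(cae$decoder$params)
  e1_before <- unlist(cae$encoder$params)
  cae2 <- train_prediction_encoder(cases[1:3], cases[4:5], unet, cae,
                                   cfgs$train, cfgs$loss)
  expect_identical(unlist(cae2$decoder$params), d_before)
  expect_identical(unlist(cae2$encoder$params), e1_before)
  expect_false(is.null(cae2$encoder2))
  # E2 actually moved away from its E1 warm start
  expect_false(identical(unlist(cae2$encoder2$params), e1_before))
  hist <- attr(cae2, "history2")
  expect_equal(nrow(hist), 2)
})

test_that("k-fold bookkeeping evaluates every case exactly once", {
  cases <- smoke_cases(6)
  cfgs <- small_cfgs()
  cfgs$train <- train_config(scale = 1, epochs_unet = 1L, epochs_shape = 1L,
                             epochs_prediction = 1L, alpha_switch_epoch = 1L,
                             batch_size = 2L, seed = 11L, patience = Inf)
  res <- run_kfold(cases, k = 2L, cfgs$unet, cfgs$cae, cfgs$train, cfgs$loss)
  expect_setequal(res$metrics$case_id, names(cases))
  expect_equal(nrow(res$metrics), 6)
  # aggregated means equal the independent mean of the per-case values
  expect_equal(res$summary[["dice_cp"]], mean(res$metrics$dice_cp))
  expect_length(res$bundles, 2)
})
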