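# U-Net architecture, patch sampling, tiling and segmentation contracts.

test_that("default configuration lands on about 355k trainable parameters", {
  m <- build_unet(unet_config(), seed = 1)
  n <- n_parameters(m)
  expect_gt(n, 355000 * 0.95)
  expect_lt(n, 355000 * 1.05)
})

test_that("parameter count matches the closed-form oracle for any widths", {
  for (ch in list(c(16L, 32L, 64L), c(4L, 8L, 16L), c(8L, 24L, 40L))) {
    cfg <- unet_config(channels = ch, patch_size = c(16L, 16L, 8L),
                       context_pad = 2L)
    m <- build_unet(cfg, seed = 1)
    expect_identical(n_parameters(m), as.integer(unet_param_oracle(2, 2, ch)))
  }
})

test_that("weight initialization is deterministic in the seed", {
  cfg <- unet_config(channels = c(4L, 8L, 16L), patch_size = c(16L, 16L, 8L),
                     context_pad = 2L)
  expect_identical(build_unet(cfg, seed = 5)$params,
                   build_unet(cfg, seed = 5)$params)
  expect_false(identical(build_unet(cfg, seed = 5)$params,
                         build_unet(cfg, seed = 6)$params))
})

test_that("training patches have the documented padded geometry", {
  cfg <- unet_config()  # 64x64x28 patch, 20 voxels of context
  grid <- c(128L, 128L, 28L)
  case <- perfusion_case("g", array(1, grid), array(1, grid),
                         array(0, grid), array(0, grid), NULL, 1, 1)
  patch <- sample_training_patch(case, cfg, seed = 3)
  expect_identical(patch$input_dims, c(104L, 104L, 68L))
  expect_identical(dim(patch$input),
                   as.integer(c(prod(c(104, 104, 68)), 2)))
  expect_identical(attr(patch$target, "d"), c(64L, 64L, 28L))
  # determinism in the seed
  p2 <- sample_training_patch(case, cfg, seed = 3)
  expect_identical(patch$start, p2$start)
  # positions vary across seeds
  starts <- vapply(1:20, function(s)
    sample_training_patch(case, cfg, seed = s)$start[1], numeric(1))
  expect_gt(length(unique(starts)), 1)
})

test_that("an all-background patch is valid with all-zero targets", {
  grid <- c(32L, 32L, 16L)
  case <- perfusion_case("bg", array(0, grid), array(0, grid),
                         array(0, grid), array(0, grid), NULL, 1, 1)
  cfg <- unet_config(channels = c(2L, 4L, 8L), patch_size = c(16L, 16L, 8L),
                     context_pad = 2L)
  patch <- sample_training_patch(case, cfg, seed = 1)
  expect_true(all(patch$target == 0))
})

test_that("volumes smaller than the patch raise a configuration error", {
  grid <- c(32L, 32L, 8L)
  case <- perfusion_case("sm", array(0, grid), array(0, grid),
                         array(0, grid), array(0, grid), NULL, 1, 1)
  cfg <- unet_config(channels = c(2L, 4L, 8L), patch_size = c(64L, 64L, 28L),
                     context_pad = 2L)
  expect_error(sample_training_patch(case, cfg), "smaller")
})

test_that("the default geometry tiles into exactly 4 patches", {
  placements <- tile_for_inference(c(128L, 128L, 28L), unet_config())
  expect_length(placements, 4)
  # non-overlapping cores partition the grid
  covered <- array(0L, c(128, 128, 28))
  for (pl in placements) {
    sl <- lapply(1:3, function(a) (pl$start[a] + 1):(pl$start[a] + pl$size[a]))
    covered[sl[[1]], sl[[2]], sl[[3]]] <-
      covered[sl[[1]], sl[[2]], sl[[3]]] + 1L
  }
  expect_true(all(covered == 1L))
})

test_that("tiling covers odd geometries with end-anchored overlaps", {
  expect_length(tile_for_inference(c(64L, 64L, 28L), unet_config()), 1)
  pls <- tile_for_inference(c(96L, 128L, 28L), unet_config())
  expect_length(pls, 4)
  covered <- array(0L, c(96, 128, 28))
  for (pl in pls) {
    sl <- lapply(1:3, function(a) (pl$start[a] + 1):(pl$start[a] + pl$size[a]))
    covered[sl[[1]], sl[[2]], sl[[3]]] <-
      covered[sl[[1]], sl[[2]], sl[[3]]] + 1L
  }
  expect_true(all(covered >= 1L))
  expect_true(any(covered > 1L))  # one overlapping column pair
})

test_that("segment returns probability volumes on the case grid", {
  grid <- c(32L, 32L, 8L)
  cfg <- unet_config(channels = c(2L, 4L, 8L), patch_size = c(16L, 16L, 8L),
                     context_pad = 2L)
  model <- build_unet(cfg, seed = 2)
  case <- generate_case(smoke_synth_config(n_cases = 1, grid = grid), 1)
  seg <- segment(model, case)
  expect_identical(dim(seg$core), grid)
  expect_true(all(seg$core >= 0 & seg$core <= 1))
  expect_true(all(seg$core_penumbra >= 0 & seg$core_penumbra <= 1))
  # deterministic in evaluation mode
  seg2 <- segment(model, case)
  expect_identical(seg$core, seg2$core)
})
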