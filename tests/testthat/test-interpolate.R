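# Time normalization, latent/image-space interpolation and the oracle-eta
# search.

test_that("compute_eta implements the normalization with clamping", {
  expect_equal(compute_eta(2, 4, 10), 0.5)
  expect_equal(compute_eta(3, 0, 10), 0.0)
  expect_equal(compute_eta(2, 8, 10), 1.0)
  expect_equal(compute_eta(2, 12, 10), 1.0)  # clamped beyond the horizon
  expect_equal(compute_eta(14, 5, 24), 0.5)  # 24 h normalization
  expect_error(compute_eta(10, 1, 10), "horizon")
  expect_error(compute_eta(-1, 1, 10), "non-negative")
})

test_that("latent interpolation is exact at endpoints and affine", {
  set.seed(31)
  y_c <- matrix(rnorm(20), 10, 2)
  y_cp <- matrix(rnorm(20), 10, 2)
  expect_equal(unclass(interpolate_latent(y_c, y_cp, 0))[, ],
               y_c[, ], ignore_attr = TRUE)
  expect_equal(unclass(interpolate_latent(y_c, y_cp, 1))[, ],
               y_cp[, ], ignore_attr = TRUE)
  expect_equal(as.numeric(interpolate_latent(matrix(c(0, 0)), matrix(c(2, 4)),
                                             0.25)), c(0.5, 1.0))
  for (eta in c(0.2, 0.7)) {
    # reflection identity: walking from the other endpoint mirrors the path
    expect_equal(unclass(interpolate_latent(y_cp, y_c, 1 - eta))[, ],
                 unclass(interpolate_latent(y_c, y_cp, eta))[, ],
                 tolerance = 1e-12, ignore_attr = TRUE)
    # affine: same-eta blends from both ends sum to the endpoint sum
    lhs <- unclass(interpolate_latent(y_c, y_cp, eta)) +
      unclass(interpolate_latent(y_cp, y_c, eta))
    expect_equal(lhs[, ], (y_c + y_cp)[, ], ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  expect_error(interpolate_latent(matrix(0, 2, 2), matrix(0, 3, 2), 0.5),
               "congruent")
})

test_that("image-space interpolation matches the per-voxel oracle", {
  res <- image_space_interpolate(c(1, 0), c(1, 1), 0.5)
  expect_equal(as.numeric(res$prob), c(1, 0.5))
  set.seed(32)
  s_c <- array(runif(60), c(5, 4, 3))
  s_cp <- pmax(s_c, array(runif(60), c(5, 4, 3)))
  for (eta in c(0, 0.3, 1)) {
    res <- image_space_interpolate(s_c, s_cp, eta)
    oracle <- array(0, dim(s_c))
    for (i in seq_along(s_c))
      oracle[i] <- s_c[i] + eta * (s_cp[i] - s_c[i])
    expect_lt(max(abs(res$prob - oracle)), 1e-7)
  }
  expect_equal(image_space_interpolate(s_c, s_cp, 0)$prob, s_c)
})

test_that("the image-space blend fades the penumbral shell in uniformly", {
  core <- c(1, 1, 0, 0, 0)
  cp <- c(1, 1, 1, 1, 0)
  eta <- 0.4
  res <- image_space_interpolate(core, cp, eta)
  shell <- cp == 1 & core == 0
  expect_true(all(res$prob[shell] == eta))
  # below-threshold eta keeps the support at the core: no spatial growth
  expect_identical(as.numeric(res$mask), core)
})

test_that("oracle eta dominates any fixed-time prediction on the grid", {
  cfg <- cae_config(input_dim = c(16L, 16L, 8L),
                    widths = c(2L, 4L, 4L, 4L), bottleneck_channels = 4L,
                    bottleneck_extent = c(2L, 2L, 1L))
  cae <- build_cae(cfg, seed = 8)
  x_c <- array(0, c(16, 16, 8)); x_c[6:9, 6:9, 3:5] <- 1
  x_cp <- array(0, c(16, 16, 8)); x_cp[4:12, 4:12, 2:7] <- 1
  s_l <- array(0, c(16, 16, 8)); s_l[5:10, 5:10, 3:6] <- 1
  y_c <- encode(cae, x_c); y_cp <- encode(cae, x_cp)
  grid <- seq(0, 1, by = 0.25)
  orc <- oracle_eta(y_c, y_cp, cae, s_l, grid)
  for (eta in grid) {
    pr <- decode(cae, strokeshape:::new_latent_code(
      interpolate_latent(y_c, y_cp, eta), cfg, "i"))
    expect_gte(orc$dice_star, hard_dice((pr >= 0.5) * 1, s_l))
  }
  # singleton grid equals the fixed-time prediction
  orc1 <- oracle_eta(y_c, y_cp, cae, s_l, grid = 0.5)
  pr <- decode(cae, strokeshape:::new_latent_code(
    interpolate_latent(y_c, y_cp, 0.5), cfg, "i"))
  expect_equal(orc1$dice_star, hard_dice((pr >= 0.5) * 1, s_l))
  expect_equal(orc1$eta_star, 0.5)
  expect_error(oracle_eta(y_c, y_cp, cae, s_l, grid = numeric(0)), "empty")
})

test_that("predict_followup validates modes and reproduces eta endpoints", {
  cfg <- cae_config(input_dim = tiny_grid, widths = c(2L, 4L, 4L, 4L),
                    bottleneck_channels = 4L, bottleneck_extent = c(2L, 2L, 1L))
  cae <- build_cae(cfg, seed = 4)
  case <- tiny_case(t_on = 2, t_tr = 0)  # eta = 0
  res <- predict_followup(case, list(cae = cae), horizon = 10,
                          mode = "from_expert_masks")
  expect_equal(res$eta, 0)
  rec_c <- decode(cae, encode(cae, case$core_mask))
  expect_equal(res$prob, rec_c, tolerance = 1e-12)
  expect_error(predict_followup(case, list(cae = cae), 10,
                                mode = "from_estimates"), "unet")
  expect_identical(res$volume_voxels, sum(res$mask))
})
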