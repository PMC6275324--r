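# Convolutional auto-encoder: bottleneck geometry, encode/decode contracts
# and the parameter-count oracle.

test_that("the default 128x128x28 input reaches a 10x10x1 bottleneck", {
  cfg <- cae_config()
  expect_identical(cfg$bottleneck_extent, c(10L, 10L, 1L))
  expect_identical(cfg$stage_dims$e3, c(16L, 16L, 4L))
  expect_identical(cfg$bottleneck_kernel, c(7L, 7L, 4L))
})

test_that("infeasible bottleneck extents raise an informative error", {
  expect_error(cae_config(input_dim = c(16L, 16L, 8L),
                          bottleneck_extent = c(10L, 10L, 1L)),
               "achievable")
})

test_that("decode(encode(x)) restores the input extent and range", {
  cfg <- cae_config(input_dim = c(16L, 16L, 8L),
                    widths = c(2L, 4L, 4L, 4L), bottleneck_channels = 4L,
                    bottleneck_extent = c(2L, 2L, 1L))
  cae <- build_cae(cfg, seed = 3)
  x <- array(0, c(16, 16, 8)); x[5:9, 5:9, 3:5] <- 1
  code <- encode(cae, x)
  expect_identical(nrow(code), as.integer(prod(cfg$bottleneck_extent)))
  expect_identical(ncol(code), 4L)
  rec <- decode(cae, code)
  expect_identical(dim(rec), c(16L, 16L, 8L))
  expect_true(all(rec >= 0 & rec <= 1))
})

test_that("encoding is deterministic, separate per shape, and total for empty input", {
  cfg <- cae_config(input_dim = c(16L, 16L, 8L),
                    widths = c(2L, 4L, 4L, 4L), bottleneck_channels = 4L,
                    bottleneck_extent = c(2L, 2L, 1L))
  cae <- build_cae(cfg, seed = 3)
  x1 <- array(0, c(16, 16, 8)); x1[3:6, 3:6, 2:4] <- 1
  x2 <- array(0, c(16, 16, 8)); x2[3:10, 3:10, 2:6] <- 1
  expect_identical(unclass(encode(cae, x1)), unclass(encode(cae, x1)))
  c1 <- encode(cae, x1); c2 <- encode(cae, x2)
  expect_identical(dim(c1), dim(c2))
  expect_false(identical(unclass(c1), unclass(c2)))
  c0 <- encode(cae, array(0, c(16, 16, 8)))
  expect_true(all(is.finite(c0)))
  expect_error(encode(cae, array(0, c(8, 8, 8))), "extent")
  expect_error(decode(cae, matrix(0, 3, 4)), "dimensionality")
})

test_that("the latent code is far smaller than the input volume", {
  cfg <- cae_config()
  code_len <- prod(cfg$bottleneck_extent) * cfg$bottleneck_channels
  expect_lt(code_len, prod(cfg$input_dim) / 100)
})

test_that("parameter count matches the closed-form oracle for any widths", {
  for (w in list(c(2L, 4L, 4L, 4L), c(4L, 8L, 16L, 16L))) {
    cfg <- cae_config(input_dim = c(16L, 16L, 8L), widths = w,
                      bottleneck_channels = 4L,
                      bottleneck_extent = c(2L, 2L, 1L))
    cae <- build_cae(cfg, seed = 1)
    expect_identical(n_parameters(cae),
                     as.integer(cae_param_oracle(w, 4L, cfg$bottleneck_kernel)))
  }
})
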