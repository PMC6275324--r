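# Properties of the nested-shape growth simulator.

test_that("generated masks are exactly nested and confined to one hemisphere", {
  cfg <- smoke_synth_config(n_cases = 6)
  for (i in 1:6) {
    case <- generate_case(cfg, i)
    expect_true(all(case$core_mask <= case$lesion_mask))
    expect_true(all(case$lesion_mask <= case$core_penumbra_mask))
    expect_true(case$nesting_ok)
    # one hemisphere only (along the first axis)
    mid <- cfg$grid[1] / 2
    occupied <- apply(case$core_penumbra_mask, 1, sum) > 0
    left <- any(occupied[seq_len(floor(mid))])
    right <- any(occupied[(floor(mid) + 1):cfg$grid[1]])
    expect_false(left && right)
  }
})

test_that("zero treatment delay reproduces the core exactly", {
  cfg <- synth_config(grid = c(32L, 32L, 8L), n_cases = 3, seed = 4,
                      eta_range = c(0, 0))
  case <- generate_case(cfg, 2)
  expect_equal(case$t_imaging_to_treatment, 0)
  expect_identical(case$lesion_mask, case$core_mask)
})

test_that("lesion volume fraction tracks eta over many cases", {
  cfg <- smoke_synth_config(n_cases = 100, seed = 42)
  etas <- numeric(100); fracs <- numeric(100)
  for (i in 1:100) {
    case <- generate_case(cfg, i)
    etas[i] <- attr(case, "eta_true")
    nc <- sum(case$core_mask); np <- sum(case$core_penumbra_mask)
    fracs[i] <- (sum(case$lesion_mask) - nc) / (np - nc)
  }
  expect_gt(cor(etas, fracs, method = "spearman"), 0.9)
  # with gamma = 1 the volume fraction equals eta up to discretization
  expect_lt(max(abs(etas - fracs)), 0.05)
})

test_that("CBV drops inside the core and TTD rises inside core+penumbra", {
  cfg <- smoke_synth_config(n_cases = 5, seed = 9)
  for (i in 1:5) {
    case <- generate_case(cfg, i)
    brain <- case$ttd != 0 | case$cbv != 0
    core <- case$core_mask > 0
    cp <- case$core_penumbra_mask > 0
    expect_lt(mean(case$cbv[core]), mean(case$cbv[brain & !core]))
    expect_gt(mean(case$ttd[cp]), mean(case$ttd[brain & !cp]))
    expect_gt(mean(case$ttd[core]), mean(case$ttd[cp & !core]))
  }
})

test_that("mask interpolation is monotone in the growth fraction", {
  cfg <- smoke_synth_config(n_cases = 1, seed = 13)
  case <- generate_case(cfg, 1)
  fs <- c(0, 0.2, 0.5, 0.8, 1)
  masks <- lapply(fs, function(f)
    interpolate_masks(case$core_mask, case$core_penumbra_mask, f))
  expect_identical(masks[[1]] * 1, case$core_mask)
  expect_identical(masks[[5]] * 1, case$core_penumbra_mask)
  for (i in 1:4) expect_true(all(masks[[i]] <= masks[[i + 1]]))
})

test_that("generation is a pure function of configuration and index", {
  cfg <- smoke_synth_config(n_cases = 3, seed = 77)
  a <- generate_case(cfg, 2)
  b <- generate_case(cfg, 2)
  expect_identical(a$cbv, b$cbv)
  expect_identical(a$lesion_mask, b$lesion_mask)
  expect_identical(attr(a, "eta_true"), attr(b, "eta_true"))
  # different indices differ
  c3 <- generate_case(cfg, 3)
  expect_false(identical(a$core_mask, c3$core_mask))
})

test_that("time sampling respects the horizon cap and clinical scale", {
  cfg <- synth_config(grid = c(32L, 32L, 8L), n_cases = 30, seed = 5)
  t_on <- numeric(30); t_tr <- numeric(30)
  for (i in 1:30) {
    case <- generate_case(cfg, i)
    t_on[i] <- case$t_onset_to_imaging
    t_tr[i] <- case$t_imaging_to_treatment
    expect_lte(t_on[i] + t_tr[i], cfg$horizon + 1e-9)
  }
  # medians sit near the clinically reported ~1.7 h values
  expect_gt(median(t_on), 0.8); expect_lt(median(t_on), 3.5)
  expect_gt(median(t_tr), 0.8); expect_lt(median(t_tr), 3.0)
})

test_that("written datasets are bit-identical across runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- smoke_synth_config(n_cases = 2, seed = 21)
  m1 <- generate_dataset(cfg, d1)
  m2 <- generate_dataset(cfg, d2)
  expect_identical(m1$t_onset_to_imaging, m2$t_onset_to_imaging)
  for (f in list.files(d1, pattern = "nii.gz$")) {
    a <- RNifti::readNifti(file.path(d1, f))
    b <- RNifti::readNifti(file.path(d2, f))
    expect_identical(as.numeric(a), as.numeric(b))
  }
})
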