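# Scalar objectives against hand-evaluated and brute-force oracles.

test_that("soft_dice matches hand-evaluated values and is symmetric", {
  expect_equal(soft_dice(c(1, 1, 0), c(1, 1, 0), 1), 1.0)
  expect_equal(soft_dice(c(0, 0), c(0, 0), 1), 1.0)       # eps/eps
  expect_equal(soft_dice(c(1, 0), c(0, 1), 1), 1 / 3)
  expect_equal(soft_dice(0.5, 1.0, 0), 0.8)               # 2*0.5/(0.25+1)
  set.seed(1)
  a <- runif(20); b <- runif(20)
  expect_equal(soft_dice(a, b, 1), soft_dice(b, a, 1))
})

test_that("soft_dice_loss is the complement and stays in [0,1)", {
  expect_equal(soft_dice_loss(c(1, 0, 1), c(1, 0, 1), 1), 0.0)
  expect_equal(soft_dice_loss(c(1, 0), c(0, 1), 1), 2 / 3)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(8); b <- runif(8)
    l <- soft_dice_loss(a, b, 1)
    expect_gte(l, 0); expect_lt(l, 1)
    expect_equal(l, 1 - soft_dice(a, b, 1))
  }
})

test_that("soft_dice converges to hard_dice on binary masks as eps -> 0", {
  set.seed(3)
  for (i in 1:25) {
    a <- (runif(40) > 0.5) * 1
    b <- (runif(40) > 0.5) * 1
    if (sum(a) + sum(b) == 0) next
    expect_lt(abs(soft_dice(a, b, 1e-8) - hard_dice(a, b)), 1e-4)
  }
})

test_that("mono_penalty is a one-sided hinge", {
  expect_equal(mono_penalty(c(1, 0), c(1, 1)), 0.0)
  expect_equal(mono_penalty(c(1, 1), c(0, 1)), 1.0)
  expect_equal(mono_penalty(0.7, 0.4), 0.3)
  # zero in both directions iff equal
  set.seed(4)
  for (i in 1:20) {
    a <- runif(10); b <- runif(10)
    both_zero <- mono_penalty(a, b) == 0 && mono_penalty(b, a) == 0
    expect_equal(both_zero, all(a == b))
  }
  expect_equal(mono_penalty(c(0.3, 0.3), c(0.3, 0.3)), 0)
})

test_that("latent_l1 is the mean absolute difference and a metric", {
  expect_equal(latent_l1(c(1, 2), c(1, 2)), 0.0)
  expect_equal(latent_l1(c(0, 0), c(1, 3)), 2.0)
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6); z <- rnorm(6)
    expect_lte(latent_l1(x, z), latent_l1(x, y) + latent_l1(y, z) + 1e-12)
  }
})

test_that("hard_dice handles identity, disjoint and empty cases", {
  expect_equal(hard_dice(c(1, 1, 0), c(1, 1, 0)), 1.0)
  expect_equal(hard_dice(c(1, 1, 0), c(1, 0, 0)), 2 / 3)
  expect_equal(hard_dice(c(1, 0), c(0, 1)), 0.0)
  expect_equal(hard_dice(c(0, 0), c(0, 0)), 1.0)
  expect_error(hard_dice(c(0.4, 1), c(1, 0)), "binary")
})

test_that("shape_loss equals the sum of independently computed terms", {
  set.seed(6)
  cfg <- loss_config(epsilon = 1)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    recons <- list(c = runif(n), cp = runif(n), l = runif(n))
    truths <- list(c = (runif(n) > 0.5) * 1, cp = (runif(n) > 0.5) * 1,
                   l = (runif(n) > 0.5) * 1)
    codes <- list(l = rnorm(4), i = rnorm(4))
    for (alpha in c(0, 1)) {
      got <- shape_loss(recons, truths, codes, alpha, cfg)
      want <- (1 - soft_dice(recons$c, truths$c, 1)) +
        (1 - soft_dice(recons$cp, truths$cp, 1)) +
        (1 - soft_dice(recons$l, truths$l, 1)) +
        sum(pmax(recons$c - recons$cp, 0)) +
        sum(pmax(recons$l - recons$cp, 0)) +
        alpha * mean(abs(codes$l - codes$i))
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("shape_loss is zero at its optimum and alpha gates the latent term", {
  cfg <- loss_config()
  s <- list(c = c(1, 0, 0), cp = c(1, 1, 0), l = c(1, 1, 0))
  codes_eq <- list(l = c(1, 2), i = c(1, 2))
  expect_equal(shape_loss(s, s, codes_eq, alpha = 1, cfg), 0.0)
  codes_diff <- list(l = c(1, 2), i = c(3, 5))
  expect_equal(shape_loss(s, s, codes_diff, alpha = 0, cfg), 0.0)
  expect_gt(shape_loss(s, s, codes_diff, alpha = 1, cfg), 0.0)
})

test_that("prediction_loss equals its term-by-term oracle", {
  set.seed(7)
  cfg <- loss_config(epsilon = 1)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    pred <- runif(n); truth <- (runif(n) > 0.5) * 1
    decoded <- list(c = runif(n), cp = runif(n))
    codes <- list(c = rnorm(5), i = rnorm(5))
    targets <- list(c = rnorm(5), l = rnorm(5), i = rnorm(5))
    got <- prediction_loss(pred, truth, decoded, codes, targets, cfg)
    want <- (1 - soft_dice(pred, truth, 1)) +
      sum(pmax(decoded$c - decoded$cp, 0)) +
      sum(pmax(pred - decoded$cp, 0)) +
      mean(abs(codes$c - targets$c)) +
      mean(abs(codes$i - targets$l)) +
      mean(abs(codes$i - targets$i))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("prediction_loss vanishes when estimates equal targets", {
  pred <- c(1, 0, 1); decoded <- list(c = c(1, 0, 0), cp = c(1, 0, 1))
  codes <- list(c = c(0.5, 1), i = c(1, 2))
  targets <- list(c = c(0.5, 1), l = c(1, 2), i = c(1, 2))
  expect_equal(prediction_loss(pred, pred, decoded, codes, targets,
                               loss_config()), 0.0)
})

test_that("a monotonicity violation inflates the loss by exactly its hinge", {
  pred <- c(0.2, 0.1); truth <- c(0, 0)
  decoded_ok <- list(c = c(0.1, 0.2), cp = c(0.8, 0.9))
  decoded_bad <- list(c = c(0.95, 0.2), cp = c(0.8, 0.9))
  codes <- list(c = c(0), i = c(0)); targets <- list(c = c(0), l = c(0), i = c(0))
  d <- prediction_loss(pred, truth, decoded_bad, codes, targets, loss_config()) -
    prediction_loss(pred, truth, decoded_ok, codes, targets, loss_config())
  expect_equal(d, 0.95 - 0.8 - max(0.1 - 0.8, 0), tolerance = 1e-12)
})

test_that("losses reject incongruent volumes", {
  expect_error(soft_dice(c(1, 0), c(1, 0, 1)), "congruent")
  expect_error(mono_penalty(matrix(0, 2, 2), matrix(0, 3, 2)), "congruent")
  expect_error(latent_l1(c(1, 2), c(1, 2, 3)), "congruent")
})
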