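# Continuous BART engine: structure prior, sampler correctness on known
# functions, prediction contracts.

test_that("split probability follows base * (1 + depth)^(-power)", {
  expect_equal(split_probability(0, 0.95, 2), 0.95)
  expect_equal(split_probability(1, 0.95, 2), 0.2375)
  expect_equal(split_probability(1, 0.25, 3), 0.03125)
  expect_true(all(diff(split_probability(0:5, 0.95, 2)) < 0))
  expect_error(split_probability(0, 1.2, 2), "base")
  expect_error(split_probability(-1, 0.5, 2), "depth")
})

test_that("deeper trees are rarer under stronger structure priors", {
  sim_depth <- function(base, power, reps = 400, seed = 1) {
    set.seed(seed)
    grow <- function(d) {
      if (d < 12 && runif(1) < split_probability(d, base, power)) {
        max(grow(d + 1), grow(d + 1))
      } else {
        d
      }
    }
    mean(replicate(reps, grow(0)))
  }
  expect_gt(sim_depth(0.95, 1), sim_depth(0.95, 3))
  expect_gt(sim_depth(0.95, 2), sim_depth(0.25, 2))
})

test_that("a constant outcome is recovered by a degenerate fit", {
  set.seed(1)
  X <- matrix(runif(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_bart(X, rep(5, 30), test_config(1))
  mu <- colMeans(predict(fit, X))
  expect_true(all(abs(mu - 5) < 0.01 * 5 + 0.01))
})

test_that("a linear signal is recovered with small held-out error", {
  set.seed(2)
  n <- 500
  X <- cbind(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  y <- 2 * X[, "x1"] + rnorm(n, 0, 0.1)
  fit <- fit_bart(X, y, bart_config(ntree = 50, seed = 11))
  grid <- cbind(x1 = seq(-0.9, 0.9, length.out = 40),
                x2 = runif(40, -1, 1))
  mu <- colMeans(predict(fit, grid))
  expect_lt(sqrt(mean((mu - 2 * grid[, "x1"])^2)), 0.3)
  rates <- with(fit$accept, accepts / pmax(attempts, 1))
  expect_true(all(rates > 0 & rates < 1))
})

test_that("a single known tree's leaf means are recovered", {
  set.seed(3)
  n <- 400
  X <- cbind(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  y <- ifelse(X[, "x1"] > 0, 2, -1) + rnorm(n, 0, 0.3)
  fit <- fit_bart(X, y, test_config(4, ntotal = 500))
  mu <- colMeans(predict(fit, cbind(x1 = c(-0.5, 0.5), x2 = 0)))
  expect_lt(abs(mu[1] - (-1)), 0.3)
  expect_lt(abs(mu[2] - 2), 0.3)
})

test_that("sigma draws concentrate near the true noise scale", {
  set.seed(4)
  n <- 500
  X <- cbind(x1 = runif(n), x2 = runif(n))
  y <- rnorm(n, 0, 2)
  fit <- fit_bart(X, y, test_config(5, ntotal = 500))
  expect_lt(abs(median(fit$sigma) / 2 - 1), 0.15)
})

test_that("the forest prediction is the sum of its trees, draw by draw", {
  set.seed(5)
  n <- 60
  X <- cbind(x1 = runif(n), x2 = runif(n))
  y <- sin(4 * X[, "x1"]) + rnorm(n, 0, 0.2)
  fit <- fit_bart(X, y, test_config(6, ntree = 10, ntotal = 150))
  Xnew <- cbind(x1 = runif(8), x2 = runif(8))
  pred <- predict(fit, Xnew)
  for (d in c(1, 17, 50)) {
    contrib <- bartcate:::forest_tree_contributions(fit, d, Xnew)
    expect_equal(nrow(contrib), 10)
    expect_equal(fit$center + fit$scale * colSums(contrib),
                 unname(pred[d, ]), tolerance = 1e-12)
  }
})

test_that("prediction is a pure function of the stored draws", {
  set.seed(6)
  n <- 80
  X <- cbind(x1 = runif(n), x2 = runif(n))
  y <- X[, "x1"] + rnorm(n, 0, 0.2)
  fit <- fit_bart(X, y, test_config(7, ntree = 20, ntotal = 200))
  expect_identical(predict(fit, X), fit$fit)   # exact in-sample match
  Xdup <- X[c(3, 3, 10), ]
  pd <- predict(fit, Xdup)
  expect_identical(pd[, 1], pd[, 2])
  Xbad <- X
  colnames(Xbad) <- c("x1", "zz")
  expect_error(predict(fit, Xbad), "fingerprint")
  expect_error(fit_bart(X, c(y[-1], NA), test_config(1)), "missing")
})

test_that("single-stump forests predict one value per draw", {
  set.seed(8)
  n <- 50
  X <- cbind(x1 = runif(n))
  y <- rnorm(n)
  # power so large that splitting is effectively impossible
  fit <- fit_bart(X, y, test_config(9, ntree = 5, ntotal = 150,
                                    base = 0.01, power = 8))
  pred <- predict(fit, cbind(x1 = c(0.1, 0.5, 0.9)))
  expect_true(all(apply(pred, 1, function(r) diff(range(r))) < 1e-12))
})

test_that("row order does not change what the model learns", {
  set.seed(9)
  n <- 300
  X <- cbind(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  y <- 2 * X[, "x1"] + rnorm(n, 0, 0.2)
  grid <- cbind(x1 = seq(-0.8, 0.8, length.out = 20), x2 = 0)
  fit1 <- fit_bart(X, y, test_config(10, ntotal = 400))
  perm <- sample(n)
  fit2 <- fit_bart(X[perm, ], y[perm], test_config(10, ntotal = 400))
  mu1 <- colMeans(predict(fit1, grid))
  mu2 <- colMeans(predict(fit2, grid))
  # exact invariance is not promised (the chains diverge in floating
  # point); the learned function must agree within Monte-Carlo error
  expect_gt(cor(mu1, mu2), 0.95)
  expect_lt(mean(abs(mu1 - mu2)), 0.25)
})
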