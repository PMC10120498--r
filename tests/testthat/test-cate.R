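# Stage 1: counterfactual CATE estimation, partial dependence, quartile
# summaries.

fit_cate_fixture <- function(outcome = "dawols", n = 400, seed = 31,
                             effects = effect_spec(missing_rate = 0.01),
                             cfg = test_config(seed + 500)) {
  ds <- standardize_covariates(generate_trial(n, effects = effects,
                                              seed = seed))
  estimate_cate(ds, outcome, cfg)
}

test_that("CATE results carry coherent per-patient summaries", {
  cate <- fit_cate_fixture()
  expect_true(all(cate$conf.low <= cate$estimate + 1e-12))
  expect_true(all(cate$estimate <= cate$conf.high + 1e-12))
  expect_true(all(abs(cate$estimate) < 90))
  draws <- bartcate:::cate_draws(cate)
  expect_equal(dim(draws), c(200, nrow(cate)))
  # complete-case stage 1: patients with a missing outcome are excluded
  expect_true(all(!is.na(bartcate:::cate_data(cate)$dawols90)))
  g <- glance(cate)
  expect_equal(g$n, nrow(cate))
  expect_s3_class(tidy(cate), "tbl_df")
})

test_that("mortality CATE draws are differences of valid probabilities", {
  cate <- fit_cate_fixture("mortality", seed = 32)
  draws <- bartcate:::cate_draws(cate)
  expect_true(all(draws > -1 & draws < 1))
  p1 <- attr(cate, "pred1")
  p0 <- attr(cate, "pred0")
  expect_true(all(p1 > 0 & p1 < 1 & p0 > 0 & p0 < 1))
  expect_equal(draws, p1 - p0)
})

test_that("equal counterfactual inputs give exactly zero effect draws", {
  cate <- fit_cate_fixture(n = 200, seed = 33)
  fit <- bartcate:::cate_fit(cate)
  df <- bartcate:::cate_design(bartcate:::cate_data(cate))
  df$trt <- 0.5  # the arm column ablated to a common value
  expect_true(all(predict(fit, df) - predict(fit, df) == 0))
})

test_that("estimate_cate rejects unusable inputs", {
  ds <- generate_trial(100, seed = 34)
  expect_error(estimate_cate(ds, "dawols", test_config(1)), "standardized")
  std <- standardize_covariates(ds)
  std$mort90[] <- NA_integer_
  expect_error(estimate_cate(std, "mortality", test_config(1)),
               "entirely missing")
})

test_that("partial dependence is flat when the covariate plays no role", {
  # outcomes built with no weight term and modest noise, so any weight
  # structure in the curve is invented; averaged over replicates to damp
  # Monte-Carlo wiggle
  ranges <- vapply(1:3, function(s) {
    ds <- generate_trial(600, seed = 130 + s,
                         effects = effect_spec(missing_rate = 0))
    set.seed(200 + s)
    ds$dawols90 <- as.integer(round(pmin(pmax(
      50 + 4 * ds$arm + rnorm(nrow(ds), 0, 8), 0), 90)))
    std <- standardize_covariates(ds)
    cate <- estimate_cate(std, "dawols", test_config(300 + s))
    pd <- partial_dependence(cate, "weight", grid_size = 15)
    stopifnot(all(diff(pd$value) > 0),
              all(pd$conf.low <= pd$estimate),
              all(pd$estimate <= pd$conf.high))
    max(pd$estimate) - min(pd$estimate)
  }, numeric(1))
  expect_lt(mean(ranges), 0.5)
})

test_that("a planted age interaction bends the age curve upward", {
  eff <- effect_spec(treatment_main_effect_dawols = 4,
                     treatment_main_effect_mortality = 0,
                     dawols_interactions = effect_term("age", 4),
                     missing_rate = 0)
  cate <- fit_cate_fixture(n = 700, seed = 36, effects = eff,
                           cfg = test_config(41, ntotal = 500))
  pd <- partial_dependence(cate, "age", grid_size = 21)
  central <- pd[3:19, ]  # central 80% of the grid
  expect_gt(cor(central$value, central$estimate, method = "spearman"), 0.7)
  expect_gt(central$estimate[nrow(central)], central$estimate[1])
})

test_that("a one-point grid collapses to the sample-average CATE there", {
  cate <- fit_cate_fixture(n = 200, seed = 37)
  pd <- partial_dependence(cate, "age", grid_size = 1)
  expect_equal(nrow(pd), 1)
  fit <- bartcate:::cate_fit(cate)
  df <- bartcate:::cate_design(bartcate:::cate_data(cate))
  df$age <- stats::median(df$age)
  d1 <- df; d1$trt <- 1
  d0 <- df; d0$trt <- 0
  avg <- rowMeans(predict(fit, d1) - predict(fit, d0))
  expect_equal(pd$estimate, mean(avg), tolerance = 1e-12)
  expect_error(partial_dependence(cate, "diabetes"), "continuous")
})

test_that("quartile groups partition the sample and order the effect", {
  cate <- fit_cate_fixture(n = 982, seed = 38)
  q <- quartile_summary(cate)
  expect_equal(sum(q$n), nrow(cate))
  expect_lte(diff(range(q$n)), 1)
  expect_true(all(diff(q$estimate) >= -1e-12))
  expect_true(all(q$conf.low <= q$estimate & q$estimate <= q$conf.high))
})

test_that("a homogeneous effect gives four near-identical quartiles", {
  cate <- fit_cate_fixture(n = 500, seed = 39,
                           effects = effect_spec(
                             treatment_main_effect_mortality = 0,
                             missing_rate = 0))
  q <- quartile_summary(cate)
  # no planted heterogeneity: the quartile means differ only by the
  # model's smoothing noise
  expect_lt(max(q$estimate) - min(q$estimate), 3)
})
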