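# Synthetic trial generator: marginals, outcome construction, planted
# effects, missingness, determinism.

test_that("default marginals emulate the baseline table", {
  m <- default_marginals()
  expect_equal(sum(m$probs[[which(m$name == "resp_support")]]), 1)
  ds <- generate_trial(n = 10000, seed = 21)
  expect_lt(abs(median(ds$age) - 64), 2)
  expect_lt(abs(mean(ds$diabetes) - 0.30), 0.02)
  expect_lt(abs(median(ds$weight) - 80), 3)
  tab <- table(ds$resp_support) / nrow(ds)
  expect_lt(max(abs(tab - c(0.54, 0.25, 0.21))), 0.02)
})

test_that("outcomes respect their ranges and the DAWOLS definition", {
  ds <- generate_trial(n = 5000, seed = 22)
  daw <- ds$dawols90[!is.na(ds$dawols90)]
  expect_true(all(daw >= 0 & daw <= 90))
  expect_true(all(ds$mort90[!is.na(ds$mort90)] %in% 0:1))
  # dead patients keep their drawn DAWOLS; they are not forced to zero
  dead_daw <- ds$dawols90[!is.na(ds$mort90) & ds$mort90 == 1 &
                            !is.na(ds$dawols90)]
  expect_gt(sum(dead_daw > 0), 0)
})

test_that("generation is deterministic given the seed", {
  a <- generate_trial(n = 300, seed = 7)
  b <- generate_trial(n = 300, seed = 7)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- generate_trial(n = 300, seed = 8)
  expect_false(identical(a$dawols90, c$dawols90))
})

test_that("randomization balances covariates across arms", {
  ds <- generate_trial(n = 20000, seed = 23)
  std <- standardize_covariates(ds)
  for (nm in c("age", "weight")) {
    d <- abs(mean(std[[nm]][std$arm == 1]) - mean(std[[nm]][std$arm == 0]))
    expect_lt(d, 0.05)
  }
  expect_lt(abs(mean(ds$diabetes[ds$arm == 1]) -
                  mean(ds$diabetes[ds$arm == 0])), 0.05)
})

test_that("null treatment terms give a null arm contrast", {
  sc <- trial_scenario("null")
  ds <- generate_trial(n = 4000, effects = sc$effects, seed = 24)
  rd <- mean(ds$mort90[ds$arm == 1], na.rm = TRUE) -
    mean(ds$mort90[ds$arm == 0], na.rm = TRUE)
  expect_lt(abs(rd), 0.03)
})

test_that("a calibrated logit main effect plants the target risk difference", {
  target <- -0.055
  delta <- calibrate_mortality_shift(target, n_mc = 1e5, seed = 1)
  eff <- effect_spec(treatment_main_effect_mortality = delta,
                     missing_rate = 0)
  # verification sample large enough that the +-0.01 band is ~3 MC SEs
  ds <- generate_trial(n = 80000, effects = eff, seed = 25)
  rd <- mean(ds$mort90[ds$arm == 1]) - mean(ds$mort90[ds$arm == 0])
  expect_lt(abs(rd - target), 0.01)
})

test_that("missingness masking is Bernoulli, seeded and outcome-only", {
  ds <- tiny_trial(10000, seed = 26)
  expect_identical(apply_missingness(ds, 0), ds)
  m1 <- apply_missingness(ds, 0.5, seed = 3)
  m2 <- apply_missingness(ds, 0.5, seed = 3)
  expect_identical(tibble::as_tibble(m1), tibble::as_tibble(m2))
  expect_lt(abs(mean(is.na(m1$dawols90)) - 0.5), 0.02)
  expect_lt(abs(mean(is.na(m1$mort90)) - 0.5), 0.02)
  expect_identical(m1$age, ds$age)
  expect_identical(m1$arm, ds$arm)
  expect_error(apply_missingness(ds, 1.2), "rate")
})

test_that("scenario configurations round-trip through YAML and JSON", {
  sc <- trial_scenario("diabetes-interaction")
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scenario(sc, path)
    back <- read_scenario(path)
    expect_equal(back$name, sc$name)
    expect_equal(back$marginals, sc$marginals)
    expect_equal(back$effects$dawols_interactions,
                 sc$effects$dawols_interactions)
    a <- generate_trial(150, sc$marginals, sc$effects, seed = 5)
    b <- generate_trial(150, back$marginals, back$effects, seed = 5)
    # serialized reals can differ in the last ulp, which carries into the
    # continuous draws; everything else regenerates exactly
    expect_equal(tibble::as_tibble(a), tibble::as_tibble(b),
                 tolerance = 1e-12)
  }
})

test_that("degenerate outcome models are rejected, not clamped", {
  eff <- effect_spec(baseline_mortality_logit = 900)
  expect_error(generate_trial(n = 50, effects = eff, seed = 1),
               "degenerate|non-finite")
})
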