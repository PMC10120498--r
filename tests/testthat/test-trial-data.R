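# Data model, I/O, standardization and arm summaries.

make_rows <- function(n, seed = 1) {
  tibble::as_tibble(generate_trial(n = n, seed = seed,
                                   effects = effect_spec(missing_rate = 0)))
}

test_that("loading validates and never imputes", {
  df <- make_rows(4)
  df$mort90[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path, na = "NA")
  ds <- read_trial_data(path)
  expect_s3_class(ds, "trial_data")
  expect_equal(nrow(ds), 4)
  expect_equal(sum(is.na(ds$mort90)), 1)

  bad <- df
  bad$dawols90[3] <- 91
  readr::write_csv(bad, path, na = "NA")
  expect_error(read_trial_data(path), "row 3")

  bad2 <- df
  bad2$age[4] <- NA
  readr::write_csv(bad2, path, na = "NA")
  expect_error(read_trial_data(path), "covariates may not be missing")

  bad3 <- df
  bad3$resp_support <- as.character(bad3$resp_support)
  bad3$resp_support[1] <- "ecmo"
  readr::write_csv(bad3, path, na = "NA")
  expect_error(read_trial_data(path), "unknown level 'ecmo'")

  bad4 <- dplyr::bind_rows(df, df[1, ])
  readr::write_csv(bad4, path, na = "NA")
  expect_error(read_trial_data(path), "duplicate id")
})

test_that("generator output round-trips through write/read unchanged", {
  ds <- generate_trial(n = 200, seed = 33)
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_trial_data(ds, path)
    back <- read_trial_data(path)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(ds))
  }
})

test_that("column mapping renames file columns to the canonical schema", {
  df <- make_rows(6)
  names(df)[names(df) == "dawols90"] <- "days_alive"
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path, na = "NA")
  expect_error(read_trial_data(path), "missing column")
  ds <- read_trial_data(path, col_map = c(dawols90 = "days_alive"))
  expect_equal(ds$dawols90, df$days_alive)
})

test_that("standardization centers and scales with the n-1 denominator", {
  ds <- tiny_trial(50, seed = 2)
  ds$age[1:2] <- c(60, 70)  # hand-checkable pair lives among others
  two <- trial_data(tibble::as_tibble(ds)[1:2, ])
  std2 <- standardize_covariates(two)
  # sd({60,70}) = 10/sqrt(2) with denominator n-1, so values are +-0.7071
  expect_equal(std2$age, c(-1, 1) / sqrt(2), tolerance = 1e-10)

  std <- standardize_covariates(ds)
  for (nm in c("age", "weight")) {
    expect_lt(abs(mean(std[[nm]])), 1e-10)
    expect_equal(sd(std[[nm]]), 1, tolerance = 1e-10)
  }
  expect_identical(std$diabetes, ds$diabetes)
  expect_identical(std$resp_support, ds$resp_support)

  # idempotence on an already-standard covariate
  pre <- ds
  pre$age <- (pre$age - mean(pre$age)) / sd(pre$age)
  std_pre <- standardize_covariates(trial_data(tibble::as_tibble(pre)))
  expect_equal(std_pre$age, pre$age, tolerance = 1e-10)

  expect_error(standardize_covariates(std), "already standardized")
  const <- ds
  const$weight <- 80
  expect_error(standardize_covariates(trial_data(tibble::as_tibble(const))),
               "zero-variance.*weight")
})

test_that("standardize/destandardize round-trips on random datasets", {
  for (seed in 1:3) {
    ds <- tiny_trial(120, seed = seed)
    std <- standardize_covariates(ds)
    back <- destandardize_covariates(std)
    expect_equal(back$age, ds$age, tolerance = 1e-9)
    expect_equal(back$weight, ds$weight, tolerance = 1e-9)
    params <- attr(std, "std_params")
    expect_equal(destandardize_value("age", std$age, params), ds$age,
                 tolerance = 1e-9)
  }
})

test_that("destandardize_value maps the standard scale to original units", {
  params <- tibble::tibble(name = c("age", "weight"), center = c(64, 80),
                           scale = c(12, 20))
  expect_equal(destandardize_value("age", 0, params), 64)
  expect_equal(destandardize_value("weight", 1, params), 100)
  expect_error(destandardize_value("height", 0, params), "unknown")
})

test_that("tree cutpoints destandardize to the original-units cutpoints", {
  ds <- tiny_trial(300, seed = 9)
  # a response split cleanly by age so the first cutpoint lands on age
  t_resp <- as.numeric(ds$age > median(ds$age)) * 4
  std <- standardize_covariates(ds)
  tr_std <- fit_cart(data.frame(age = std$age, weight = std$weight), t_resp,
                     max_depth = 1, min_leaf = 5, cp = 0)
  tr_orig <- fit_cart(data.frame(age = ds$age, weight = ds$weight), t_resp,
                      max_depth = 1, min_leaf = 5, cp = 0)
  expect_equal(tr_std$var[1], "age")
  expect_equal(
    destandardize_value("age", tr_std$cut[1], attr(std, "std_params")),
    tr_orig$cut[1], tolerance = 1e-9)
})

test_that("arm summaries reproduce the printed count/percentage arithmetic", {
  # one arm with 490 non-missing mortality outcomes of which 157 deaths,
  # the other with 180/478; diabetes 135/497 vs 163/485
  n1 <- 497; n0 <- 485
  df <- make_rows(n1 + n0, seed = 4)
  df$arm <- rep(c(1L, 0L), c(n1, n0))
  df$mort90 <- c(rep(c(1L, 0L, NA), c(157, 333, 7)),
                 rep(c(1L, 0L, NA), c(180, 298, 7)))
  df$diabetes <- c(rep(1:0, c(135, n1 - 135)), rep(1:0, c(163, n0 - 163)))
  tab <- summarize_by_arm(trial_data(df))

  mort <- dplyr::filter(tab, variable == "mort90")
  expect_equal(mort$pct[mort$arm == "12mg"], 32.0)
  expect_equal(mort$denom[mort$arm == "12mg"], 490)
  expect_equal(mort$pct[mort$arm == "6mg"], 37.7)

  diab <- dplyr::filter(tab, variable == "diabetes")
  expect_equal(diab$pct[diab$arm == "12mg"], 27)
  expect_equal(diab$pct[diab$arm == "6mg"], 34)
})

test_that("degenerate distributions summarize sanely", {
  df <- make_rows(40, seed = 5)
  df$weight <- 80
  tab <- summarize_by_arm(trial_data(df))
  w <- dplyr::filter(tab, variable == "weight")
  expect_equal(w$median, c(80, 80))
  expect_equal(w$q1, c(80, 80))
  expect_equal(w$q3, c(80, 80))
})

test_that("summary percentages equal a direct recount on random data", {
  for (seed in 6:8) {
    ds <- generate_trial(150, seed = seed)
    tab <- summarize_by_arm(ds)
    df <- tibble::as_tibble(ds)
    for (armlab in c("12mg", "6mg")) {
      a <- if (armlab == "12mg") 1 else 0
      sub <- df[df$arm == a, ]
      r <- dplyr::filter(tab, variable == "diabetes", arm == armlab)
      expect_equal(r$count, sum(sub$diabetes))
      expect_equal(r$pct, round(100 * sum(sub$diabetes) / nrow(sub)))
      m <- dplyr::filter(tab, variable == "mort90", arm == armlab)
      expect_equal(m$count, sum(sub$mort90, na.rm = TRUE))
      expect_equal(m$denom, sum(!is.na(sub$mort90)))
      expect_equal(m$pct, round(100 * m$count / m$denom, 1))
    }
  }
})
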