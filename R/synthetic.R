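#' Default covariate marginal distributions
#'
#' Marginals emulating the pooled baseline table of the dexamethasone dosing
#' trial: age is truncated Normal(64, 13) on \[18, 100\] years; weight is
#' log-normal calibrated to median 80 kg with IQR roughly (68, 96); the
#' binary prevalences are limitations in care 0.056, IL-6 receptor
#' inhibitors 0.10, prior dexamethasone 3-4 days 0.25, diabetes 0.30,
#' ischemic heart disease / heart failure 0.14, COPD 0.115, recent
#' immunosuppression 0.085; respiratory support levels (open, NIV/cCPAP,
#' IMV) have probabilities (0.54, 0.25, 0.21).
#'
#' The `center` / `spread` columns carry a nominal location and scale per
#' continuous covariate, used to express planted interaction coefficients
#' per standardized unit.
#'
#' @return A tibble with one row per covariate: `name`, `kind`, `dist`,
#'   distribution parameters, bounds and level probabilities (list column).
#' @export
default_marginals <- function() {
  tibble::tibble(
    name = c("age", "limitations", "resp_support", "il6_inhibitor",
             "dex_prior_3_4d", "weight", "diabetes", "ihd_hf", "copd",
             "immunosuppression"),
    kind = c("continuous", "binary", "categorical", "binary", "binary",
             "continuous", "binary", "binary", "binary", "binary"),
    dist = c("truncnorm", "bernoulli", "categorical", "bernoulli",
             "bernoulli", "lognormal", "bernoulli", "bernoulli", "bernoulli",
             "bernoulli"),
    center = c(64, NA, NA, NA, NA, 82.7, NA, NA, NA, NA),
    spread = c(13, NA, NA, NA, NA, 21.5, NA, NA, NA, NA),
    meanlog = c(NA, NA, NA, NA, NA, log(80), NA, NA, NA, NA),
    sdlog = c(NA, NA, NA, NA, NA, 0.2557, NA, NA, NA, NA),
    lower = c(18, NA, NA, NA, NA, 35, NA, NA, NA, NA),
    upper = c(100, NA, NA, NA, NA, 250, NA, NA, NA, NA),
    prevalence = c(NA, 0.056, NA, 0.10, 0.25, NA, 0.30, 0.14, 0.115, 0.085),
    probs = list(NULL, NULL, c(open = 0.54, niv_cpap = 0.25, imv = 0.21),
                 NULL, NULL, NULL, NULL, NULL, NULL, NULL)
  )
}

#' A planted treatment-effect term
#'
#' One row of the interaction (or prognostic) term table of an
#' [effect_spec()]. The term's covariate value entering the linear
#' predictor is: the level indicator for categorical covariates (`level`),
#' a threshold indicator for continuous covariates when `threshold` is
#' given (`below = TRUE` means `x < threshold`, in original units),
#' otherwise the covariate standardized by its nominal marginal center and
#' spread (continuous) or the 0/1 value itself (binary).
#'
#' @param var Covariate name.
#' @param coef Coefficient (logit units for mortality terms, days for
#'   DAWOLS terms).
#' @param level Categorical level whose indicator the term multiplies.
#' @param threshold Original-units threshold for a continuous indicator.
#' @param below Direction of the threshold indicator.
#' @return A one-row tibble.
#' @export
effect_term <- function(var, coef, level = NA_character_,
                        threshold = NA_real_, below = TRUE) {
  tibble::tibble(var = var, coef = coef, level = level,
                 threshold = threshold, below = below)
}

no_terms <- function() effect_term(character(0), numeric(0))[0, ]

default_prognostic_mortality <- function() {
  dplyr::bind_rows(
    effect_term("age", 0.35),
    effect_term("resp_support", 0.40, level = "niv_cpap"),
    effect_term("resp_support", 0.80, level = "imv")
  )
}

default_prognostic_dawols <- function() {
  dplyr::bind_rows(
    effect_term("age", -3),
    effect_term("resp_support", -6, level = "niv_cpap"),
    effect_term("resp_support", -12, level = "imv")
  )
}

#' Outcome-generating effect specification
#'
#' Defines how the synthetic generator turns covariates and the randomized
#' arm into outcomes. Mortality follows a logistic model
#' `logit P(death) = baseline + prognostic terms + z * (main + interactions)`
#' with `z = 1` for 12 mg/d. DAWOLS is drawn as
#' `round(clamp(mu + z * (main + interactions) + Normal(0, noise_sd), 0, 90))`
#' where `mu` centers survivors high (default 75 days) and the dead low
#' (default 15 days) plus prognostic terms, giving the bimodal marginal seen
#' in such trials; dead patients keep their drawn value rather than being
#' forced to the worst one. Outcomes are then masked missing independently
#' at `missing_rate`.
#'
#' @param baseline_mortality_logit Control-arm mortality intercept (logit).
#' @param treatment_main_effect_mortality Arm main effect (logit). The
#'   default, -0.24, is calibrated (see [calibrate_mortality_shift()]) to a
#'   marginal risk difference of about -0.055 under the default marginals.
#' @param mortality_interactions,dawols_interactions Tibbles of
#'   [effect_term()] rows multiplying the arm indicator.
#' @param dawols_mean_survivor,dawols_mean_dead Latent DAWOLS centers (days).
#' @param treatment_main_effect_dawols Arm main effect on DAWOLS (days).
#' @param noise_sd_dawols Latent DAWOLS noise sd (days); must be > 0.
#' @param missing_rate Independent masking probability per outcome, in
#'   \[0, 1); the trial's own missingness was about 1.4%.
#' @param prognostic_mortality,prognostic_dawols Arm-independent covariate
#'   effects (see Details of the package vignette for the defaults).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(baseline_mortality_logit = -0.78,
                        treatment_main_effect_mortality = -0.24,
                        mortality_interactions = no_terms(),
                        dawols_mean_survivor = 75,
                        dawols_mean_dead = 15,
                        treatment_main_effect_dawols = 4,
                        dawols_interactions = no_terms(),
                        noise_sd_dawols = 12,
                        missing_rate = 0.014,
                        prognostic_mortality = default_prognostic_mortality(),
                        prognostic_dawols = default_prognostic_dawols()) {
  if (noise_sd_dawols <= 0) abort("noise_sd_dawols must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  structure(list(
    baseline_mortality_logit = baseline_mortality_logit,
    treatment_main_effect_mortality = treatment_main_effect_mortality,
    mortality_interactions = mortality_interactions,
    dawols_mean_survivor = dawols_mean_survivor,
    dawols_mean_dead = dawols_mean_dead,
    treatment_main_effect_dawols = treatment_main_effect_dawols,
    dawols_interactions = dawols_interactions,
    noise_sd_dawols = noise_sd_dawols,
    missing_rate = missing_rate,
    prognostic_mortality = prognostic_mortality,
    prognostic_dawols = prognostic_dawols
  ), class = "effect_spec")
}

term_values <- function(df, terms, marginals) {
  if (nrow(terms) == 0) return(rep(0, nrow(df)))
  out <- rep(0, nrow(df))
  for (k in seq_len(nrow(terms))) {
    x <- df[[terms$var[k]]]
    if (is.null(x)) abort(paste0("unknown term covariate '", terms$var[k], "'"))
    v <- if (!is.na(terms$level[k])) {
      as.numeric(as.character(x) == terms$level[k])
    } else if (!is.na(terms$threshold[k])) {
      if (isTRUE(terms$below[k])) as.numeric(x < terms$threshold[k])
      else as.numeric(x > terms$threshold[k])
    } else if (is.factor(x)) {
      abort(paste0("term on categorical '", terms$var[k],
                   "' needs a level"))
    } else {
      m <- marginals[marginals$name == terms$var[k], ]
      if (nrow(m) == 1 && m$kind == "continuous") {
        (x - m$center) / m$spread
      } else {
        as.numeric(x)
      }
    }
    out <- out + terms$coef[k] * v
  }
  out
}

draw_covariates <- function(n, marginals, schema, age_resp_rho = 0) {
  df <- list()
  age_z <- NULL
  for (k in seq_len(nrow(marginals))) {
    m <- marginals[k, ]
    df[[m$name]] <- switch(
      m$dist,
      truncnorm = {
        plo <- pnorm(m$lower, m$center, m$spread)
        phi <- pnorm(m$upper, m$center, m$spread)
        u <- runif(n, plo, phi)
        x <- qnorm(u, m$center, m$spread)
        if (m$name == "age") age_z <- (x - m$center) / m$spread
        x
      },
      lognormal = pmin(pmax(rlnorm(n, m$meanlog, m$sdlog), m$lower), m$upper),
      bernoulli = rbinom(n, 1L, m$prevalence),
      categorical = {
        p <- m$probs[[1]]
        z <- if (age_resp_rho != 0 && !is.null(age_z)) {
          pnorm(age_resp_rho * age_z +
                  sqrt(1 - age_resp_rho^2) * rnorm(n))
        } else {
          runif(n)
        }
        lev <- names(p)
        lev[findInterval(z, cumsum(p) / sum(p)) + 1L]
      }
    )
  }
  tibble::as_tibble(df)
}

#' Generate a synthetic randomized trial
#'
#' Draws `n` patients with independent covariate marginals (optionally an
#' age / respiratory-support Gaussian-copula correlation), assigns the arm
#' by a fair coin, and generates both outcomes from `effects` (see
#' [effect_spec()]). Reproducible: the same `seed` and arguments give a
#' byte-identical dataset.
#'
#' @param n Number of patients (default 982, the analyzed trial size).
#' @param marginals Covariate marginals, see [default_marginals()].
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @param schema Covariate schema.
#' @param age_resp_rho Latent correlation between age and respiratory
#'   support (default 0, independent marginals).
#' @return A `trial_data` tibble in original units.
#' @export
generate_trial <- function(n = 982, marginals = default_marginals(),
                           effects = effect_spec(), seed = 1,
                           schema = hte_schema(), age_resp_rho = 0) {
  stopifnot(n >= 2)
  set.seed(seed)
  df <- draw_covariates(n, marginals, schema, age_resp_rho)
  z <- rbinom(n, 1L, 0.5)

  lp <- effects$baseline_mortality_logit +
    term_values(df, effects$prognostic_mortality, marginals) +
    z * (effects$treatment_main_effect_mortality +
           term_values(df, effects$mortality_interactions, marginals))
  if (any(!is.finite(lp))) abort("non-finite mortality linear predictor")
  p <- plogis(lp)
  if (any(p <= 0) || any(p >= 1)) {
    abort("extreme coefficients give degenerate mortality probabilities")
  }
  mort <- rbinom(n, 1L, p)

  mu <- ifelse(mort == 1L, effects$dawols_mean_dead,
               effects$dawols_mean_survivor) +
    term_values(df, effects$prognostic_dawols, marginals) +
    z * (effects$treatment_main_effect_dawols +
           term_values(df, effects$dawols_interactions, marginals))
  daw <- as.integer(round(pmin(pmax(mu + rnorm(n, 0, effects$noise_sd_dawols),
                                    0), 90)))

  if (effects$missing_rate > 0) {
    daw[rbinom(n, 1L, effects$missing_rate) == 1L] <- NA_integer_
    mort[rbinom(n, 1L, effects$missing_rate) == 1L] <- NA_integer_
  }

  df <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("P%05d", seq_len(n)), arm = z,
                   dawols90 = daw, mort90 = mort),
    df
  )
  trial_data(df, schema = schema)
}

#' Independently mask outcomes as missing
#'
#' Each outcome of each patient is set to `NA` independently with
#' probability `rate`; covariates and arm are never masked.
#'
#' @param ds A `trial_data` tibble.
#' @param rate Masking probability in \[0, 1).
#' @param seed Integer seed.
#' @return The masked dataset.
#' @export
apply_missingness <- function(ds, rate, seed = 1) {
  if (rate < 0 || rate >= 1) abort("rate must be in [0, 1)")
  if (rate == 0) return(ds)
  set.seed(seed)
  n <- nrow(ds)
  out <- ds
  out$dawols90[rbinom(n, 1L, rate) == 1L] <- NA_integer_
  out$mort90[rbinom(n, 1L, rate) == 1L] <- NA_integer_
  new_trial_data(out, ds_schema(ds), ds_standardized(ds), ds_std_params(ds))
}

#' Calibrate the mortality arm effect to a target risk difference
#'
#' Finds the logit-scale main effect delta such that the marginal risk
#' difference `E[plogis(lp + delta)] - E[plogis(lp)]`, integrated over the
#' covariate distribution by Monte Carlo, equals `target_rd`.
#'
#' @param target_rd Target risk difference (12 mg/d minus 6 mg/d).
#' @param marginals,effects Generator settings the calibration is for.
#' @param n_mc Monte-Carlo integration sample size.
#' @param seed Seed for the integration sample.
#' @return The calibrated logit shift (a scalar).
#' @export
calibrate_mortality_shift <- function(target_rd,
                                      marginals = default_marginals(),
                                      effects = effect_spec(),
                                      n_mc = 2e5, seed = 1) {
  set.seed(seed)
  df <- draw_covariates(n_mc, marginals, hte_schema(), 0)
  lp0 <- effects$baseline_mortality_logit +
    term_values(df, effects$prognostic_mortality, marginals)
  f <- function(delta) mean(plogis(lp0 + delta) - plogis(lp0)) - target_rd
  uniroot(f, c(-5, 5), tol = 1e-8)$root
}

#' Save or load a synthetic scenario configuration
#'
#' Serializes a scenario (marginals plus effect specification) to YAML or
#' JSON so that simulation conditions travel with an analysis and can be
#' regenerated exactly.
#'
#' @param scenario A list with `name`, `marginals` and `effects` (as
#'   returned by [trial_scenario()], or hand-built).
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @return `path` (write) / the scenario list (read).
#' @export
write_scenario <- function(scenario, path) {
  ser <- list(
    name = scenario$name %||% "custom",
    marginals = lapply(seq_len(nrow(scenario$marginals)), function(k) {
      row <- as.list(scenario$marginals[k, ])
      row$probs <- if (is.null(row$probs[[1]])) NULL else
        as.list(row$probs[[1]])
      row[!vapply(row, function(v) is.null(v) ||
                    (length(v) == 1 && is.na(v)), logical(1))]
    }),
    effects = {
      e <- unclass(scenario$effects)
      for (nm in c("mortality_interactions", "dawols_interactions",
                   "prognostic_mortality", "prognostic_dawols")) {
        e[[nm]] <- lapply(seq_len(nrow(e[[nm]])), function(k) {
          r <- as.list(e[[nm]][k, ])
          r[!vapply(r, function(v) length(v) == 1 && is.na(v), logical(1))]
        })
      }
      e
    }
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(ser, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  marg <- purrr::map_dfr(raw$marginals, function(row) {
    tibble::tibble(
      name = row$name, kind = row$kind, dist = row$dist,
      center = row$center %||% NA_real_,
      spread = row$spread %||% NA_real_,
      meanlog = row$meanlog %||% NA_real_,
      sdlog = row$sdlog %||% NA_real_,
      lower = row$lower %||% NA_real_,
      upper = row$upper %||% NA_real_,
      prevalence = row$prevalence %||% NA_real_,
      probs = list(if (is.null(row$probs)) NULL else unlist(row$probs))
    )
  })
  terms <- function(lst) {
    if (length(lst) == 0) return(no_terms())
    purrr::map_dfr(lst, function(r) {
      effect_term(var = r$var, coef = as.numeric(r$coef),
                  level = r$level %||% NA_character_,
                  threshold = as.numeric(r$threshold %||% NA_real_),
                  below = r$below %||% TRUE)
    })
  }
  e <- raw$effects
  effects <- effect_spec(
    baseline_mortality_logit = as.numeric(e$baseline_mortality_logit),
    treatment_main_effect_mortality =
      as.numeric(e$treatment_main_effect_mortality),
    mortality_interactions = terms(e$mortality_interactions),
    dawols_mean_survivor = as.numeric(e$dawols_mean_survivor),
    dawols_mean_dead = as.numeric(e$dawols_mean_dead),
    treatment_main_effect_dawols =
      as.numeric(e$treatment_main_effect_dawols),
    dawols_interactions = terms(e$dawols_interactions),
    noise_sd_dawols = as.numeric(e$noise_sd_dawols),
    missing_rate = as.numeric(e$missing_rate),
    prognostic_mortality = terms(e$prognostic_mortality),
    prognostic_dawols = terms(e$prognostic_dawols)
  )
  list(name = raw$name, marginals = marg, effects = effects)
}

#' Named synthetic scenarios
#'
#' The scenario library used throughout the package's tests and pipeline:
#' * `"null"` - all treatment terms zero (no effect, no heterogeneity).
#' * `"constant"` - a homogeneous effect: +4 days DAWOLS and a mortality
#'   risk difference of about -0.055.
#' * `"diabetes-interaction"` - DAWOLS benefit of 6 days without diabetes
#'   vs 2 days with diabetes (noise sd 20 days); the mortality arm effect
#'   is zero so the planted DAWOLS leaf effects are not shifted by
#'   survival composition (dying patients accrue few days alive without
#'   life support, so a mortality benefit would leak into the DAWOLS
#'   contrast).
#' * `"weight-nonlinear"` - DAWOLS benefit larger (+4 days extra) below
#'   70 kg, a step the first-stage model must discover.
#'
#' @param name Scenario name.
#' @return A list with elements `name`, `marginals` and `effects`, ready to
#'   pass to [generate_trial()].
#' @export
trial_scenario <- function(name = c("null", "constant",
                                    "diabetes-interaction",
                                    "weight-nonlinear")) {
  name <- match.arg(name)
  effects <- switch(
    name,
    "null" = effect_spec(treatment_main_effect_mortality = 0,
                         treatment_main_effect_dawols = 0),
    "constant" = effect_spec(),
    "diabetes-interaction" = effect_spec(
      treatment_main_effect_dawols = 6,
      dawols_interactions = effect_term("diabetes", -4),
      noise_sd_dawols = 20,
      treatment_main_effect_mortality = 0
    ),
    "weight-nonlinear" = effect_spec(
      treatment_main_effect_dawols = 2,
      dawols_interactions = effect_term("weight", 4, threshold = 70,
                                        below = TRUE)
    )
  )
  list(name = name, marginals = default_marginals(), effects = effects)
}
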