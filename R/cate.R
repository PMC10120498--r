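# Stage 1: counterfactual CATE estimation. One joint BART is fitted with
# the randomized arm as a covariate; each patient is then predicted under
# both arms with their covariates fixed, and every retained draw yields a
# CATE draw as the difference (days for DAWOLS, risk difference for
# mortality).

cate_design <- function(ds, resp_coding = "indicator") {
  schema <- ds_schema(ds)
  df <- tibble::as_tibble(ds)[schema$name]
  if (resp_coding == "ordinal") {
    for (nm in schema_categorical(schema)) {
      df[[nm]] <- as.numeric(df[[nm]]) - 1
    }
  }
  dplyr::bind_cols(tibble::tibble(trt = as.numeric(ds$arm)), df)
}

#' Estimate conditional average treatment effects
#'
#' Fits one BART model on (arm, covariates) jointly - standard BART for
#' DAWOLS, latent-augmentation BART for mortality - then forms, for every
#' analyzed patient, the two counterfactual predictions (arm set to 12 mg/d
#' and to 6 mg/d with covariates fixed). Each retained posterior draw gives
#' a per-patient CATE draw as their difference; effects are coded
#' 12 mg/d minus 6 mg/d. Patients with a missing outcome are excluded from
#' both fitting and summarization (complete-case stage 1).
#'
#' @param ds A standardized `trial_data` (see [standardize_covariates()]).
#' @param outcome `"dawols"` (days alive without life support, continuous)
#'   or `"mortality"` (90-day death, binary; CATEs are risk differences).
#' @param config A [bart_config()].
#' @param link Binary link for mortality, see [fit_bart_binary()].
#' @param resp_coding Respiratory-support encoding: `"indicator"` (two
#'   contrasts against the open-system level; default) or `"ordinal"`
#'   (0 < 1 < 2).
#' @return A `cate_result`: a tibble with one row per analyzed patient
#'   (`id`, posterior mean `estimate`, equal-tailed 95% credible bounds
#'   `conf.low` / `conf.high`) carrying the full draw matrices and fitted
#'   model as attributes for the downstream stages.
#' @export
estimate_cate <- function(ds, outcome = c("dawols", "mortality"),
                          config = bart_config(), link = "probit",
                          resp_coding = c("indicator", "ordinal")) {
  outcome <- match.arg(outcome)
  resp_coding <- match.arg(resp_coding)
  if (!ds_standardized(ds)) {
    abort("estimate_cate() expects standardized covariates; call standardize_covariates() first")
  }
  ycol <- if (outcome == "dawols") "dawols90" else "mort90"
  keep <- !is.na(ds[[ycol]])
  if (!any(keep)) abort(paste0("outcome '", outcome, "' is entirely missing"))
  sub <- new_trial_data(tibble::as_tibble(ds)[keep, ], ds_schema(ds),
                        TRUE, ds_std_params(ds))
  y <- sub[[ycol]]

  df <- cate_design(sub, resp_coding)
  fit <- if (outcome == "dawols") {
    fit_bart(df, y, config)
  } else {
    fit_bart_binary(df, y, config, link = link)
  }

  df1 <- df; df1$trt <- 1
  df0 <- df; df0$trt <- 0
  pred1 <- predict(fit, df1)
  pred0 <- predict(fit, df0)
  draws <- pred1 - pred0
  colnames(draws) <- colnames(pred1) <- colnames(pred0) <- sub$id

  new_cate_result(sub, draws, pred1, pred0, fit, outcome)
}

new_cate_result <- function(sub, draws, pred1, pred0, fit, outcome) {
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  tab <- tibble::tibble(
    id = sub$id,
    estimate = colMeans(draws),
    conf.low = qs[1, ],
    conf.high = qs[2, ]
  )
  structure(tab, draws = draws, pred1 = pred1, pred0 = pred0, fit = fit,
            data = sub, outcome = outcome,
            scale = if (outcome == "dawols") "days" else "risk difference",
            class = c("cate_result", class(tibble::tibble())))
}

cate_draws <- function(x) attr(x, "draws")
cate_data <- function(x) attr(x, "data")
cate_fit <- function(x) attr(x, "fit")
cate_outcome <- function(x) attr(x, "outcome")
cate_scale <- function(x) attr(x, "scale")

#' @export
print.cate_result <- function(x, ...) {
  cat("# cate_result (", cate_outcome(x), ", ", cate_scale(x), "): ",
      nrow(x), " patients, ", nrow(cate_draws(x)), " draws\n", sep = "")
  NextMethod()
}

#' @rdname estimate_cate
#' @param x A `cate_result`.
#' @param ... Unused.
#' @export
tidy.cate_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname estimate_cate
#' @export
glance.cate_result <- function(x, ...) {
  avg <- rowMeans(cate_draws(x))  # sample-average effect per draw
  tibble::tibble(
    outcome = cate_outcome(x), scale = cate_scale(x),
    n = nrow(x), n_draws = length(avg),
    estimate = mean(avg),
    conf.low = unname(quantile(avg, 0.025)),
    conf.high = unname(quantile(avg, 0.975))
  )
}

#' Partial-dependence curve of the CATE over a continuous covariate
#'
#' Sweeps one continuous covariate over a quantile-spaced grid: at each
#' grid value the covariate is set to that value for every analyzed
#' patient (other covariates kept at their observed values), the
#' counterfactual predictions are re-evaluated, and the per-draw average
#' CATE over patients is summarized (posterior mean and equal-tailed 95%
#' interval). The grid is reported in original covariate units.
#'
#' @param cate A `cate_result`.
#' @param covariate A continuous covariate name (e.g. `"age"`).
#' @param grid_size Number of grid points (default 25).
#' @return A `pd_curve` tibble: `covariate`, `value` (original units),
#'   `estimate`, `conf.low`, `conf.high`.
#' @export
partial_dependence <- function(cate, covariate, grid_size = 25) {
  ds <- cate_data(cate)
  schema <- ds_schema(ds)
  if (!covariate %in% schema_continuous(schema)) {
    abort(paste0("'", covariate, "' is not a continuous covariate"))
  }
  fit <- cate_fit(cate)
  df <- cate_design(ds)
  probs <- if (grid_size == 1) 0.5 else seq(0, 1, length.out = grid_size)
  grid <- sort(unique(unname(quantile(df[[covariate]], probs = probs))))

  rows <- purrr::map_dfr(grid, function(g) {
    d1 <- df; d1[[covariate]] <- g; d0 <- d1
    d1$trt <- 1; d0$trt <- 0
    avg <- rowMeans(predict(fit, d1) - predict(fit, d0))
    tibble::tibble(value_std = g, estimate = mean(avg),
                   conf.low = unname(quantile(avg, 0.025)),
                   conf.high = unname(quantile(avg, 0.975)))
  })
  rows$value <- destandardize_value(covariate, rows$value_std,
                                    ds_std_params(ds))
  out <- tibble::tibble(covariate = covariate, value = rows$value,
                        estimate = rows$estimate, conf.low = rows$conf.low,
                        conf.high = rows$conf.high)
  structure(out, outcome = cate_outcome(cate), scale = cate_scale(cate),
            class = c("pd_curve", class(tibble::tibble())))
}

#' Treatment-effect summaries by quartile of estimated CATE
#'
#' Ranks patients by posterior-mean CATE (ties broken by stable id order),
#' cuts the sample into four groups of as-equal-as-possible size, and
#' reports per group: the posterior mean outcome under each arm, and the
#' group-mean CATE with an equal-tailed 95% credible interval computed
#' from group-averaged draws (an interval for the subgroup mean, not for
#' individual effects).
#'
#' @param cate A `cate_result`.
#' @return A tibble with one row per quartile (Q1 = least favorable CATE
#'   for 12 mg/d ... in the effect's own direction of ranking).
#' @export
quartile_summary <- function(cate) {
  n <- nrow(cate)
  if (n < 4) abort("need at least 4 patients for quartile groups")
  draws <- cate_draws(cate)
  pred1 <- attr(cate, "pred1")
  pred0 <- attr(cate, "pred0")
  ord <- order(cate$estimate)  # stable: ties keep id (input) order
  cuts <- floor(n * (0:4) / 4)
  purrr::map_dfr(1:4, function(qk) {
    members <- ord[(cuts[qk] + 1):cuts[qk + 1]]
    gdraws <- rowMeans(draws[, members, drop = FALSE])
    tibble::tibble(
      quartile = paste0("Q", qk),
      n = length(members),
      mean_outcome_12mg = mean(pred1[, members]),
      mean_outcome_6mg = mean(pred0[, members]),
      estimate = mean(gdraws),
      conf.low = unname(quantile(gdraws, 0.025)),
      conf.high = unname(quantile(gdraws, 0.975))
    )
  })
}
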