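# Tenfold cross-validation over the pre-specified 27-point hyperparameter
# grid. CV fits run on a reduced MCMC schedule by default; the selected
# configuration is then refitted at the full schedule for final inference.

#' The 27-configuration hyperparameter grid
#'
#' Every combination of power 1, 2 or 3; base 0.25, 0.5 or 0.95; and 50,
#' 200 or 400 trees, in deterministic order (power major, then base, then
#' trees).
#'
#' @return A 27-row tibble with columns `power`, `base`, `ntree`.
#' @export
build_grid <- function() {
  tidyr::expand_grid(power = c(1, 2, 3), base = c(0.25, 0.5, 0.95),
                     ntree = c(50, 200, 400))
}

make_folds <- function(y, k, stratify) {
  n <- length(y)
  fold <- integer(n)
  if (stratify) {
    for (cls in unique(y)) {
      pos <- which(y == cls)
      fold[pos[sample.int(length(pos))]] <-
        rep_len(seq_len(k), length(pos))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Cross-validate BART hyperparameters
#'
#' Seeded k-fold cross-validation (fold sizes differ by at most one;
#' stratified by outcome for mortality so every fold holds both classes)
#' of each grid configuration. The error is the RMSE of posterior-mean
#' predictions for the continuous outcome and, by default, the mean
#' negative log-likelihood of posterior-mean probabilities for mortality
#' (a proper scoring rule; misclassification rate available via `loss`).
#' The selected configuration attains the minimal mean error, ties going
#' to the earlier grid row.
#'
#' @param ds A standardized `trial_data`.
#' @param outcome `"dawols"` or `"mortality"`.
#' @param grid Configuration grid, see [build_grid()].
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment and the inner fits.
#' @param schedule MCMC schedule for the inner fits; the default reduced
#'   profile (1 chain, 200 total / 50 burn-in) keeps the 27 x k fits
#'   affordable, the full schedule being reserved for the final model.
#' @param loss `"default"` or `"misclass"` (binary only).
#' @param link Binary link, see [fit_bart_binary()].
#' @return A `cv_result` tibble (one row per configuration with its mean
#'   and per-fold errors) whose `"selected"` attribute holds the winning
#'   configuration.
#' @export
cross_validate <- function(ds, outcome = c("dawols", "mortality"),
                           grid = build_grid(), k = 10, seed = 1,
                           schedule = list(nchain = 1, ntotal = 200,
                                           nburn = 50),
                           loss = c("default", "misclass"),
                           link = "probit") {
  outcome <- match.arg(outcome)
  loss <- match.arg(loss)
  if (k < 2) abort("k must be >= 2")
  if (!ds_standardized(ds)) abort("cross_validate() expects standardized covariates")
  ycol <- if (outcome == "dawols") "dawols90" else "mort90"
  keep <- !is.na(ds[[ycol]])
  sub <- new_trial_data(tibble::as_tibble(ds)[keep, ], ds_schema(ds),
                        TRUE, ds_std_params(ds))
  y <- as.numeric(sub[[ycol]])
  if (length(y) < k) abort("fewer observations than folds")
  df <- cate_design(sub)
  binary <- outcome == "mortality"

  set.seed(seed)
  fold <- make_folds(y, k, stratify = binary)

  eval_config <- function(power, base, ntree) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      # fit seed is a deterministic function of the configuration values
      # and fold (identical configurations give identical errors)
      fit_seed <- (seed + 131L * f +
                     as.integer(ntree + 1000 * power + round(1e4 * base))) %%
        .Machine$integer.max
      cfg <- bart_config(ntree = ntree, base = base, power = power,
                         nchain = schedule$nchain, ntotal = schedule$ntotal,
                         nburn = schedule$nburn, seed = fit_seed)
      if (binary) {
        fit <- fit_bart_binary(df[tr, ], y[tr], cfg, link = link)
        p <- colMeans(predict(fit, df[!tr, ]))
        if (loss == "misclass") {
          mean((p >= 0.5) != (y[!tr] == 1))
        } else {
          p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
          -mean(y[!tr] * log(p) + (1 - y[!tr]) * log(1 - p))
        }
      } else {
        fit <- fit_bart(df[tr, ], y[tr], cfg)
        mu <- colMeans(predict(fit, df[!tr, ]))
        sqrt(mean((mu - y[!tr])^2))
      }
    }, numeric(1))
    errs
  }

  res <- grid %>%
    dplyr::mutate(fold_errors = purrr::pmap(list(.data$power, .data$base,
                                                 .data$ntree), eval_config),
                  error = purrr::map_dbl(.data$fold_errors, mean))
  sel <- which.min(res$error)  # ties -> first in grid order
  structure(res,
            selected = as.list(res[sel, c("power", "base", "ntree")]),
            outcome = outcome, k = k, loss = loss, folds = fold,
            class = c("cv_result", class(tibble::tibble())))
}

#' @export
print.cv_result <- function(x, ...) {
  sel <- attr(x, "selected")
  cat("# cv_result (", attr(x, "outcome"), ", k = ", attr(x, "k"),
      "): selected power ", sel$power, ", base ", sel$base, ", ",
      sel$ntree, " trees\n", sep = "")
  NextMethod()
}

#' @export
tidy.cv_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$fold_errors <- NULL
  out
}

#' @export
glance.cv_result <- function(x, ...) {
  sel <- attr(x, "selected")
  tibble::tibble(outcome = attr(x, "outcome"), k = attr(x, "k"),
                 power = sel$power, base = sel$base, ntree = sel$ntree,
                 error = min(x$error))
}

#' Selected hyperparameters as a fitting configuration
#'
#' @param cv A `cv_result`.
#' @param ... Further arguments (schedule, seed, ...) for [bart_config()].
#' @return A `bart_config` with the selected power/base/ntree.
#' @export
selected_config <- function(cv, ...) {
  sel <- attr(cv, "selected")
  bart_config(ntree = sel$ntree, base = sel$base, power = sel$power, ...)
}
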