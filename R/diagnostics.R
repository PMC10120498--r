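# Convergence assessment. The Geweke diagnostic compares the mean of an
# early window of a chain against a late window, standardized by
# spectral-density-at-zero variance estimates, giving a z-score that is
# approximately standard normal for a converged chain.

# spectral density at frequency zero via a Bartlett lag-window estimate,
# bandwidth floor(sqrt(n))
spectral_var0 <- function(x) {
  n <- length(x)
  K <- floor(sqrt(n))
  ac <- acf(x, lag.max = K, type = "covariance", plot = FALSE,
            demean = TRUE)$acf[, 1, 1]
  w <- 1 - seq_len(K) / (K + 1)
  s <- ac[1] + 2 * sum(w * ac[-1])
  if (!is.finite(s) || s <= 0) s <- ac[1]
  s
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` fraction of a chain with the
#' mean of the last `frac2` fraction:
#' `z = (mean_A - mean_B) / sqrt(s_A/n_A + s_B/n_B)` with `s` the
#' spectral-density-at-zero variance estimates of the two windows. For a
#' stationary, converged chain z is approximately standard normal.
#'
#' @param x Scalar draw sequence (length >= 50).
#' @param frac1 Early-window fraction (default 0.1).
#' @param frac2 Late-window fraction (default 0.5); windows must not
#'   overlap.
#' @return The z-score.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 50) abort("chain too short for the Geweke diagnostic (need >= 50)")
  if (frac1 + frac2 > 1) abort("windows overlap: frac1 + frac2 must be <= 1")
  if (var(x) == 0) {
    abort("degenerate chain: zero variance (not a convergence failure)")
  }
  a <- x[seq_len(floor(frac1 * n))]
  b <- x[(n - floor(frac2 * n) + 1):n]
  (mean(a) - mean(b)) /
    sqrt(spectral_var0(a) / length(a) + spectral_var0(b) / length(b))
}

#' Convergence diagnostics for a BART fit
#'
#' Computes per-chain Geweke z-scores for the monitored quantities: the
#' residual sd sigma (continuous fits) and the prediction traces of 20
#' patients chosen by seeded sampling (so the report is reproducible from
#' the stored draws). The fit passes when at least 95% of the finite
#' z-scores satisfy |z| < 3. Degenerate (zero-variance) traces are flagged
#' separately and excluded from the fractions. Acceptance rates per
#' proposal move are reported alongside.
#'
#' @param draws A `bart_draws` or `bart_binary_draws` object.
#' @param n_monitor Number of prediction traces to monitor (default 20).
#' @return A `bart_diagnostics` list: `$z` (tibble of z-scores), `$frac_gt_196`,
#'   `$frac_gt_3`, `$accept` and `$pass`.
#' @export
diagnose <- function(draws, n_monitor = 20) {
  n <- ncol(draws$fit)
  kept <- draws$kept_per_chain
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(draws$seed)
  monitored <- sort(sample.int(n, min(n_monitor, n)))

  one <- function(x, quantity, chain) {
    z <- tryCatch(geweke_z(x), error = function(e) NA_real_)
    tibble::tibble(quantity = quantity, chain = chain, z = z,
                   degenerate = is.na(z))
  }
  rows <- list()
  for (ch in seq_len(draws$nchain)) {
    rng <- ((ch - 1) * kept + 1):(ch * kept)
    if (!is.null(draws$sigma)) {
      rows[[length(rows) + 1]] <- one(draws$sigma[rng], "sigma", ch)
    }
    for (i in monitored) {
      rows[[length(rows) + 1]] <-
        one(draws$fit[rng, i], paste0("pred_", i), ch)
    }
  }
  z <- dplyr::bind_rows(rows)
  zok <- z$z[!z$degenerate]
  frac196 <- mean(abs(zok) > 1.96)
  frac3 <- mean(abs(zok) > 3)
  structure(list(
    z = z,
    frac_gt_196 = frac196,
    frac_gt_3 = frac3,
    accept = draws$accept,
    monitored = monitored,
    pass = is.finite(frac3) && (1 - frac3) >= 0.95
  ), class = "bart_diagnostics")
}

#' @export
print.bart_diagnostics <- function(x, ...) {
  cat("# bart_diagnostics: ", nrow(x$z), " monitored traces\n",
      "fraction |z| > 1.96: ", formatC(x$frac_gt_196, digits = 3,
                                       format = "f"),
      "; fraction |z| > 3: ", formatC(x$frac_gt_3, digits = 3,
                                      format = "f"),
      "\nresult: ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bart_diagnostics <- function(x, ...) x$z

#' @export
glance.bart_diagnostics <- function(x, ...) {
  tibble::tibble(n_traces = nrow(x$z), frac_gt_196 = x$frac_gt_196,
                 frac_gt_3 = x$frac_gt_3, pass = x$pass)
}

diagnostics_to_list <- function(x) {
  list(frac_gt_196 = x$frac_gt_196, frac_gt_3 = x$frac_gt_3,
       pass = x$pass, z = x$z, accept = x$accept)
}
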