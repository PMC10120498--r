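# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive best single split by SSE reduction: enumerates every variable,
# every midpoint cutpoint (numeric) or level subset (factor), with the same
# deterministic tie-breaks the tree contract promises (smaller cutpoint,
# then lower variable index, via first-strictly-better scanning order).
brute_force_first_split <- function(x_df, y, min_leaf = 1) {
  sse <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  parent <- sse(y)
  best <- NULL
  for (j in seq_along(x_df)) {
    xj <- x_df[[j]]
    if (is.factor(xj) || is.character(xj)) {
      lev <- if (is.factor(xj)) levels(xj) else sort(unique(xj))
      lev <- lev[lev %in% as.character(xj)]
      if (length(lev) < 2) next
      rest <- lev[-1]
      for (mask in 0:(2^length(rest) - 1)) {
        S <- c(lev[1], rest[bitwAnd(mask, 2^(seq_along(rest) - 1)) > 0])
        if (length(S) == length(lev)) next
        left <- as.character(xj) %in% S
        if (sum(left) < min_leaf || sum(!left) < min_leaf) next
        red <- parent - sse(y[left]) - sse(y[!left])
        if (is.null(best) || red > best$reduction + 1e-12) {
          best <- list(var = names(x_df)[j], cut = NA_real_,
                       levels_left = S, reduction = red)
        }
      }
    } else {
      u <- sort(unique(xj))
      if (length(u) < 2) next
      for (cut in (u[-1] + u[-length(u)]) / 2) {
        left <- xj <= cut
        if (sum(left) < min_leaf || sum(!left) < min_leaf) next
        red <- parent - sse(y[left]) - sse(y[!left])
        if (is.null(best) || red > best$reduction + 1e-12) {
          best <- list(var = names(x_df)[j], cut = cut,
                       levels_left = NULL, reduction = red)
        }
      }
    }
  }
  best
}

# From-scratch Geweke z: plain-sum autocovariances and a Bartlett window,
# written independently of the package implementation.
geweke_oracle <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[1:floor(frac1 * n)]
  b <- x[(n - floor(frac2 * n) + 1):n]
  s0 <- function(v) {
    m <- length(v)
    K <- floor(sqrt(m))
    vc <- v - mean(v)
    g <- vapply(0:K, function(k) {
      sum(vc[1:(m - k)] * vc[(1 + k):m]) / m
    }, numeric(1))
    s <- g[1] + 2 * sum((1 - (1:K) / (K + 1)) * g[-1])
    if (s <= 0) g[1] else s
  }
  (mean(a) - mean(b)) / sqrt(s0(a) / length(a) + s0(b) / length(b))
}

# random small regression-tree instances (numeric and factor covariates)
random_cart_case <- function(seed) {
  set.seed(seed)
  n <- sample(10:50, 1)
  p <- sample(2:4, 1)
  x <- as.data.frame(lapply(seq_len(p), function(j) {
    if (j == p && runif(1) < 0.4) {
      factor(sample(c("a", "b", "c"), n, TRUE), levels = c("a", "b", "c"))
    } else {
      round(runif(n), 2)
    }
  }))
  names(x) <- paste0("v", seq_len(p))
  list(x = x, y = rnorm(n))
}

# small fully-observed dataset for quick pipeline-level checks
tiny_trial <- function(n = 200, seed = 1, effects = effect_spec(missing_rate = 0)) {
  generate_trial(n = n, effects = effects, seed = seed)
}

# fast sampler settings for unit tests
test_config <- function(seed, ...) {
  bart_config_fast(seed = seed, ...)
}
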