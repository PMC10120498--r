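# Continuous-outcome BART: R-side orchestration around the C++ backfitting
# sampler (src/bart_mcmc.cpp). The outcome is internally mapped to
# [-0.5, 0.5]; all stored predictions and sigma draws are returned on the
# original outcome scale.

design_info <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    return(list(source = "matrix", cols = colnames(x)))
  }
  x <- as.data.frame(x)
  lv <- lapply(x, function(col) {
    if (is.factor(col)) levels(col)
    else if (is.character(col)) sort(unique(col))
    else NULL
  })
  list(source = "df", cols = names(x), levels = lv)
}

design_matrix <- function(x, info) {
  if (info$source == "matrix") {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    if (!identical(colnames(x), info$cols)) {
      abort("design matrix columns do not match the training fingerprint")
    }
    storage.mode(x) <- "double"
    return(x)
  }
  x <- as.data.frame(x)
  if (!identical(names(x), info$cols)) {
    abort("design matrix columns do not match the training fingerprint")
  }
  out <- list()
  for (nm in info$cols) {
    col <- x[[nm]]
    lev <- info$levels[[nm]]
    if (is.null(lev)) {
      out[[nm]] <- as.numeric(col)
    } else {
      colc <- as.character(col)
      if (!all(colc %in% lev)) {
        abort(paste0("unknown level in column '", nm, "'"))
      }
      for (l in lev[-1]) out[[paste0(nm, "_", l)]] <- as.numeric(colc == l)
    }
  }
  mat <- do.call(cbind, out)
  storage.mode(mat) <- "double"
  mat
}

# cutpoint grid per design-matrix column: midpoints of adjacent sorted
# unique values, capped at 100 quantile-based cutpoints
cutpoint_grids <- function(X, max_cut = 100) {
  lapply(seq_len(ncol(X)), function(v) {
    u <- sort(unique(X[, v]))
    if (length(u) < 2) return(numeric(0))
    mids <- (u[-1] + u[-length(u)]) / 2
    if (length(mids) > max_cut) {
      mids <- unique(unname(quantile(mids, probs = seq_len(max_cut) /
                                       (max_cut + 1))))
    }
    mids
  })
}

resolve_seed <- function(seed) {
  if (!is.null(seed)) return(as.integer(seed))
  sample.int(.Machine$integer.max - 64L, 1L)
}

run_chains <- function(X, y, cfg, cutgrids, sigma_mu, nu, lambda,
                       sigma_init, ytype, offset, tdf, tscale2) {
  fits <- list(); sigmas <- list(); tv <- list(); td <- list()
  offs <- list(); acc <- list()
  nodes_so_far <- 0L
  seed <- resolve_seed(cfg$seed)
  for (ch in seq_len(cfg$nchain)) {
    set.seed(seed + ch - 1L)
    res <- bart_mcmc_chain(X, y, cutgrids, cfg$ntree, cfg$base, cfg$power,
                           sigma_mu, nu, lambda, sigma_init,
                           cfg$nburn, cfg$ntotal, unname(cfg$prop_probs),
                           ytype, offset, tdf, tscale2)
    fits[[ch]] <- res$fit
    sigmas[[ch]] <- res$sigma
    tv[[ch]] <- res$tree_var
    td[[ch]] <- res$tree_val
    o <- res$tree_offsets
    offs[[ch]] <- if (ch == 1) o else o[-1] + nodes_so_far
    nodes_so_far <- nodes_so_far + length(res$tree_var)
    acc[[ch]] <- tibble::tibble(
      chain = ch, move = c("grow", "prune", "change"),
      attempts = as.integer(res$attempts), accepts = as.integer(res$accepts))
  }
  list(fit = do.call(rbind, fits), sigma = unlist(sigmas),
       tree_var = unlist(tv), tree_val = unlist(td),
       tree_offsets = unlist(offs), accept = dplyr::bind_rows(acc),
       seed = seed)
}

#' Fit a continuous-outcome BART model
#'
#' Runs `nchain` independent backfitting MCMC chains of the sum-of-trees
#' model with a regularizing structure prior, conjugate normal leaves and a
#' scaled inverse chi-squared residual-variance prior. Each iteration
#' proposes a grow, prune or change move per tree, accepted by
#' Metropolis-Hastings with the leaf values integrated out, then draws leaf
#' values and sigma^2 from their full conditionals.
#'
#' @param x Covariate data: a numeric matrix or a data frame (factor and
#'   character columns are expanded to level indicators).
#' @param y Continuous outcome vector, no missing values.
#' @param config A [bart_config()].
#' @return A `bart_draws` object: retained in-sample prediction draws
#'   (`$fit`, draws by observations, original outcome scale), sigma draws,
#'   the sampled forests (for [predict()]), acceptance counts per move and
#'   chain, and bookkeeping (seed, schedule, design fingerprint).
#' @export
fit_bart <- function(x, y, config = bart_config()) {
  info <- design_info(x)
  X <- design_matrix(x, info)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort("x and y sizes differ")
  if (length(y) < 10) abort("need at least 10 observations")
  if (anyNA(X) || any(!is.finite(X))) abort("x contains missing/non-finite values")
  if (anyNA(y) || any(!is.finite(y))) abort("y contains missing/non-finite values")

  ymin <- min(y); ymax <- max(y)
  yscale <- if (ymax > ymin) ymax - ymin else 1
  ycenter <- (ymin + ymax) / 2
  y_int <- (y - ycenter) / yscale

  # anchor the variance prior and the initial sigma at the linear-model
  # residual sd (falls back to the marginal sd for degenerate designs), so
  # chains start near the stationary noise level
  sigma_hat <- max(sd(y_int), 1e-6)
  if (nrow(X) > ncol(X) + 2) {
    res <- tryCatch(stats::lm.fit(cbind(1, X), y_int)$residuals,
                    error = function(e) NULL)
    if (!is.null(res)) {
      s <- sqrt(sum(res^2) / (nrow(X) - ncol(X) - 1))
      if (is.finite(s) && s > 1e-6) sigma_hat <- s
    }
  }
  lambda <- sigma_hat^2 * stats::qchisq(1 - config$q, config$nu) / config$nu
  sigma_mu <- 0.5 / (config$k * sqrt(config$ntree))
  cutgrids <- cutpoint_grids(X)

  res <- run_chains(X, y_int, config, cutgrids, sigma_mu, config$nu, lambda,
                    sigma_hat, ytype = 0L, offset = 0, tdf = 0, tscale2 = 1)

  new_bart_draws(res, config, info, ncol(X),
                 center = ycenter, scale = yscale, link = NULL, offset = 0,
                 n_train = nrow(X))
}

new_bart_draws <- function(res, config, info, p, center, scale, link,
                           offset, n_train, subclass = character(0)) {
  fit <- res$fit
  if (!is.null(link)) {
    fit <- link_cdf(link)(fit + offset)
  } else {
    fit <- center + scale * fit
  }
  structure(list(
    fit = fit,
    sigma = if (is.null(link)) scale * res$sigma else NULL,
    forest = list(var = res$tree_var, val = res$tree_val,
                  offsets = res$tree_offsets, ntree = config$ntree, p = p),
    center = center, scale = scale, link = link, offset = offset,
    info = info, config = config, seed = res$seed,
    nchain = config$nchain,
    kept_per_chain = config$ntotal - config$nburn,
    n_train = n_train,
    accept = res$accept
  ), class = c(subclass, "bart_draws"))
}

link_cdf <- function(link) if (link == "probit") pnorm else plogis

#' @export
print.bart_draws <- function(x, ...) {
  kind <- if (is.null(x$link)) "continuous" else paste0("binary (", x$link, ")")
  cat("<bart_draws> ", kind, ": ", x$config$ntree, " trees, ",
      x$nchain, " chain(s) x ", x$kept_per_chain, " retained draws, ",
      x$n_train, " training rows\n", sep = "")
  ar <- x$accept %>%
    dplyr::group_by(.data$move) %>%
    dplyr::summarise(rate = sum(.data$accepts) / max(1, sum(.data$attempts)))
  cat("acceptance: ",
      paste(ar$move, sprintf("%.2f", ar$rate), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Posterior predictions at new covariate values
#'
#' Evaluates every retained forest draw at each row of `newdata`. The
#' result is deterministic given the draws; continuous models return
#' predictions on the original outcome scale, binary models return event
#' probabilities (strictly inside (0, 1)).
#'
#' @param object A `bart_draws` object.
#' @param newdata Covariate data with the same columns as the training
#'   data (a column mismatch is an error).
#' @param ... Unused.
#' @return A draws-by-rows numeric matrix.
#' @export
predict.bart_draws <- function(object, newdata, ...) {
  X <- design_matrix(newdata, object$info)
  if (ncol(X) != object$forest$p) {
    abort("design matrix columns do not match the training fingerprint")
  }
  raw <- bart_predict_raw(object$forest$var, object$forest$val,
                          object$forest$offsets, object$forest$ntree, X)
  if (is.null(object$link)) {
    object$center + object$scale * raw
  } else {
    link_cdf(object$link)(raw + object$offset)
  }
}

# Independent R-language walker over the serialized forests: returns the
# per-tree contribution matrix (ntree x rows) for one retained draw.  Used
# in tests as an oracle for sum-of-trees additivity and C++ predict
# consistency; deliberately written without reference to the C++ code path.
forest_tree_contributions <- function(object, draw, newdata) {
  X <- design_matrix(newdata, object$info)
  iv <- object$forest$var
  dv <- object$forest$val
  pos <- object$forest$offsets[draw] + 1L
  ntree <- object$forest$ntree
  parse_tree <- function() {
    v <- iv[pos]; val <- dv[pos]; pos <<- pos + 1L
    if (v < 0) return(list(leaf = TRUE, mu = val))
    l <- parse_tree(); r <- parse_tree()
    list(leaf = FALSE, var = v + 1L, cut = val, l = l, r = r)
  }
  walk <- function(node, xrow) {
    while (!node$leaf) {
      node <- if (xrow[node$var] <= node$cut) node$l else node$r
    }
    node$mu
  }
  out <- matrix(0, ntree, nrow(X))
  for (t in seq_len(ntree)) {
    tr <- parse_tree()
    for (i in seq_len(nrow(X))) out[t, i] <- walk(tr, X[i, ])
  }
  out
}
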