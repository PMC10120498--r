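#' BART sampler configuration
#'
#' Collects the sum-of-trees model settings: the number of trees `ntree`,
#' the tree-structure prior (`base` and `power`, giving split probability
#' `base * (1 + depth)^(-power)` at each depth), the leaf-prior scale `k`,
#' the residual-variance prior (`nu` degrees of freedom and quantile `q`
#' anchoring the scale at the sample sd of the outcome), and the MCMC
#' schedule (`nchain` chains of `ntotal` iterations with `nburn` discarded;
#' the defaults, 4 chains of 1100 with 100 burn-in and 200 trees with
#' base 0.95 / power 2, follow common practice for these models).
#'
#' @param ntree Number of trees in the sum (default 200).
#' @param base Structure-prior base, in (0, 1) (default 0.95).
#' @param power Structure-prior power, >= 0 (default 2).
#' @param k Leaf-prior scale (default 2): leaf values have prior sd
#'   `(ymax - ymin) / (2 k sqrt(ntree))` for continuous outcomes.
#' @param nu,q Residual-variance prior: sigma^2 ~ scaled inverse
#'   chi-squared with `nu` df, scaled so the prior puts probability `q`
#'   below the sample sd of the (internally rescaled) outcome.
#' @param nchain Number of independent chains (default 4).
#' @param nburn Burn-in iterations per chain (default 100).
#' @param ntotal Total iterations per chain (default 1100); the retained
#'   draws number `nchain * (ntotal - nburn)`.
#' @param prop_probs Proposal probabilities for the grow / prune / change
#'   moves; must sum to 1.
#' @param seed Master seed; chain `c` is run under `seed + c - 1`. When
#'   `NULL` a seed is drawn from the session RNG (so an outer
#'   `set.seed()` still makes the fit reproducible).
#' @return A `bart_config` list.
#' @export
bart_config <- function(ntree = 200, base = 0.95, power = 2, k = 2,
                        nu = 3, q = 0.90, nchain = 4, nburn = 100,
                        ntotal = 1100,
                        prop_probs = c(grow = 0.25, prune = 0.25,
                                       change = 0.50),
                        seed = NULL) {
  if (base <= 0 || base >= 1) abort("base must be in (0, 1)")
  if (power < 0) abort("power must be >= 0")
  if (ntree < 1) abort("ntree must be >= 1")
  if (ntotal <= nburn) abort("ntotal must exceed nburn")
  if (length(prop_probs) != 3 || abs(sum(prop_probs) - 1) > 1e-8) {
    abort("prop_probs must be three probabilities summing to 1")
  }
  structure(list(ntree = as.integer(ntree), base = base, power = power,
                 k = k, nu = nu, q = q, nchain = as.integer(nchain),
                 nburn = as.integer(nburn), ntotal = as.integer(ntotal),
                 prop_probs = prop_probs, seed = seed),
            class = "bart_config")
}

#' Fast MCMC profile
#'
#' A reduced schedule (1 chain, 300 iterations with 100 burn-in, 50 trees)
#' for cross-validation inner fits, smoke tests and quick exploration; final
#' inference should use the full [bart_config()] schedule.
#'
#' @param ... Overrides passed to [bart_config()].
#' @return A `bart_config`.
#' @export
bart_config_fast <- function(...) {
  cfg <- list(ntree = 50, nchain = 1, nburn = 100, ntotal = 300)
  do.call(bart_config, modifyList(cfg, list(...)))
}

#' Prior probability that a node at a given depth splits
#'
#' The tree-structure prior: a node at depth `d` (root = 0) splits with
#' probability `base * (1 + d)^(-power)`, strictly decreasing in depth for
#' `power > 0`, which penalizes deep trees.
#'
#' @param depth Nonnegative node depth(s).
#' @param base Base parameter in (0, 1).
#' @param power Power parameter, >= 0.
#' @return The split probability (vectorized over `depth`).
#' @examples
#' split_probability(0:3, 0.95, 2)
#' @export
split_probability <- function(depth, base = 0.95, power = 2) {
  if (base <= 0 || base >= 1) abort("base must be in (0, 1)")
  if (power < 0) abort("power must be >= 0")
  if (any(depth < 0)) abort("depth must be nonnegative")
  base * (1 + depth)^(-power)
}
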