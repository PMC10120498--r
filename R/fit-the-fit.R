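# Stage 2: "fit-the-fit". A greedy depth-limited regression tree is fitted
# to the posterior-mean CATEs so the flexible stage-1 surface collapses to
# a handful of covariate-defined subgroups. Splitting minimizes the sum of
# squared errors; a split is kept only if it removes at least cp * root SSE.
# Continuous cutpoints are midpoints of adjacent sorted unique values; ties
# in the SSE reduction break toward the smaller cutpoint, then the lower
# variable index, so the tree is deterministic.

sse_of <- function(y) sum((y - mean(y))^2)

# all level subsets defining a binary partition of a factor, canonicalized
# to contain the first level (3 levels -> 3 partitions)
level_subsets <- function(lev) {
  rest <- lev[-1]
  out <- list()
  for (mask in 0:(2^length(rest) - 1)) {
    S <- c(lev[1], rest[bitwAnd(mask, 2^(seq_along(rest) - 1)) > 0])
    if (length(S) < length(lev)) out[[length(out) + 1]] <- S
  }
  out
}

best_split <- function(x_df, y, idx, min_leaf) {
  best <- NULL
  parent_sse <- sse_of(y[idx])
  for (j in seq_along(x_df)) {
    xj <- x_df[[j]]
    if (is.factor(xj) || is.character(xj)) {
      xs <- as.character(xj[idx])
      lev <- if (is.factor(xj)) levels(xj) else sort(unique(xj))
      lev <- lev[lev %in% xs]
      if (length(lev) < 2) next
      for (S in level_subsets(lev)) {
        left <- xs %in% S
        nl <- sum(left); nr <- sum(!left)
        if (nl < min_leaf || nr < min_leaf) next
        red <- parent_sse - sse_of(y[idx][left]) - sse_of(y[idx][!left])
        if (is.null(best) || red > best$reduction + 1e-12) {
          best <- list(var = names(x_df)[j], var_index = j, cut = NA_real_,
                       levels_left = S, reduction = red,
                       left = idx[left], right = idx[!left])
        }
      }
    } else {
      x <- xj[idx]
      o <- order(x)
      xo <- x[o]; yo <- y[idx][o]
      n <- length(xo)
      if (n < 2 * min_leaf) next
      cy <- cumsum(yo); cy2 <- cumsum(yo^2)
      tot <- cy[n]; tot2 <- cy2[n]
      ks <- which(xo[-n] != xo[-1])          # split after position k
      ks <- ks[ks >= min_leaf & (n - ks) >= min_leaf]
      if (!length(ks)) next
      sseL <- cy2[ks] - cy[ks]^2 / ks
      sseR <- (tot2 - cy2[ks]) - (tot - cy[ks])^2 / (n - ks)
      red <- parent_sse - sseL - sseR
      for (m in seq_along(ks)) {            # ascending cutpoints
        if (is.null(best) || red[m] > best$reduction + 1e-12) {
          k <- ks[m]
          cut <- (xo[k] + xo[k + 1]) / 2
          best <- list(var = names(x_df)[j], var_index = j, cut = cut,
                       levels_left = NULL, reduction = red[m],
                       left = idx[o[seq_len(k)]],
                       right = idx[o[(k + 1):n]])
        }
      }
    }
  }
  best
}

#' Greedy depth-limited regression tree on CATE estimates
#'
#' Recursive partitioning of a numeric response (here: posterior-mean
#' CATEs) by covariates, minimizing the sum of squared errors. A node is
#' split only while its depth is below `max_depth`, both children would
#' hold at least `min_leaf` observations, and the best split reduces the
#' total SSE by at least `cp` times the root SSE (and by a strictly
#' positive amount). Categorical covariates are split on level subsets.
#' Leaf values are response means.
#'
#' @param x Covariate data frame (numeric and factor columns), one row per
#'   observation; pass original-units covariates if cutpoints should read
#'   in original units (see [fit_subgroups()]).
#' @param y Numeric response.
#' @param max_depth Maximum tree depth (default 3; root = depth 0).
#' @param min_leaf Minimum observations per leaf (default 20). With
#'   `n < 2 * min_leaf` the result is a root-only tree, not an error.
#' @param cp Complexity parameter: minimum SSE reduction as a fraction of
#'   the root SSE (default 0.01).
#' @param ids Optional observation identifiers (stored per node so that
#'   subgroup credible intervals can be attached later).
#' @return A `subgroup_tree`: a tibble of nodes (preorder) with split
#'   variable/cutpoint or level subset, per-node size, sample proportion
#'   and mean response, plus member ids per node.
#' @export
fit_cart <- function(x, y, max_depth = 3, min_leaf = 20, cp = 0.01,
                     ids = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) abort("x and y sizes differ")
  if (max_depth < 0) abort("max_depth must be >= 0")
  if (is.null(ids)) ids <- as.character(seq_along(y))
  n_all <- length(y)
  root_sse <- sse_of(y)

  nodes <- list()
  recurse <- function(idx, depth, parent) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, depth = depth,
                         var = NA_character_, cut = NA_real_,
                         levels_left = NULL, n = length(idx),
                         prop = length(idx) / n_all,
                         estimate = mean(y[idx]), members = ids[idx],
                         child_left = NA_integer_, child_right = NA_integer_)
    if (depth < max_depth && length(idx) >= 2 * min_leaf &&
        sse_of(y[idx]) > 0) {
      sp <- best_split(x, y, idx, min_leaf)
      if (!is.null(sp) && sp$reduction > 0 &&
          sp$reduction >= cp * root_sse) {
        nodes[[id]]$var <<- sp$var
        nodes[[id]]$cut <<- sp$cut
        nodes[[id]]$levels_left <<- sp$levels_left
        nodes[[id]]$child_left <<- recurse(sp$left, depth + 1L, id)
        nodes[[id]]$child_right <<- recurse(sp$right, depth + 1L, id)
      }
    }
    id
  }
  recurse(seq_len(n_all), 0L, NA_integer_)

  tab <- purrr::map_dfr(nodes, function(nd) {
    tibble::tibble(
      node = nd$id, parent = nd$parent, depth = nd$depth,
      var = nd$var, cut = nd$cut,
      levels_left = list(nd$levels_left),
      child_left = nd$child_left, child_right = nd$child_right,
      is_leaf = is.na(nd$var),
      n = nd$n, prop = nd$prop, estimate = nd$estimate,
      conf.low = NA_real_, conf.high = NA_real_,
      members = list(nd$members)
    )
  })
  structure(tab, root_sse = root_sse, cp = cp, min_leaf = min_leaf,
            max_depth = max_depth, n = n_all,
            class = c("subgroup_tree", class(tibble::tibble())))
}

#' @export
print.subgroup_tree <- function(x, ...) {
  cat(render_tree(x, "text"))
  invisible(x)
}

#' Fit-the-fit subgroups from a CATE result
#'
#' Convenience wrapper for stage 2: takes the stage-1 [estimate_cate()]
#' result, back-translates the covariates to their original units (so
#' cutpoints read in years and kilograms), fits the depth-limited CART on
#' the posterior-mean CATEs, and attaches subgroup credible intervals via
#' [attach_subgroup_intervals()]. The root estimate is the model-based
#' sample-average CATE, which may differ slightly from the raw arm
#' difference.
#'
#' @param cate A `cate_result`.
#' @inheritParams fit_cart
#' @return A `subgroup_tree` with intervals attached.
#' @export
fit_subgroups <- function(cate, max_depth = 3, min_leaf = 20, cp = 0.01) {
  ds <- destandardize_covariates(cate_data(cate))
  x <- tibble::as_tibble(ds)[ds_schema(ds)$name]
  tree <- fit_cart(x, cate$estimate, max_depth = max_depth,
                   min_leaf = min_leaf, cp = cp, ids = ds$id)
  tree <- attach_subgroup_intervals(tree, cate)
  attr(tree, "outcome") <- cate_outcome(cate)
  attr(tree, "scale") <- cate_scale(cate)
  tree
}

#' Attach subgroup credible intervals to a tree
#'
#' For every node, the member patients' CATE draws are averaged within each
#' posterior draw and the 2.5 / 97.5 percentiles of those group averages
#' form an equal-tailed 95% credible interval for the subgroup mean effect.
#'
#' @param tree A `subgroup_tree` whose nodes carry member ids.
#' @param cate The `cate_result` the tree was fitted to.
#' @return The tree with `conf.low` / `conf.high` filled in.
#' @export
attach_subgroup_intervals <- function(tree, cate) {
  draws <- cate_draws(cate)
  for (k in seq_len(nrow(tree))) {
    ids <- tree$members[[k]]
    pos <- match(ids, colnames(draws))
    if (anyNA(pos)) {
      abort("tree member ids do not match the CATE result")
    }
    g <- rowMeans(draws[, pos, drop = FALSE])
    tree$conf.low[k] <- unname(quantile(g, 0.025))
    tree$conf.high[k] <- unname(quantile(g, 0.975))
  }
  tree
}

#' @export
tidy.subgroup_tree <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$members <- NULL
  out
}

#' @export
glance.subgroup_tree <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    n_nodes = nrow(x),
    n_leaves = sum(x$is_leaf),
    depth = max(x$depth),
    root_estimate = x$estimate[x$node == 1],
    root_sse = attr(x, "root_sse")
  )
}

split_label <- function(tree, k, side) {
  v <- tree$var[k]
  if (!is.null(tree$levels_left[[k]])) {
    S <- tree$levels_left[[k]]
    if (side == "left") paste0(v, " in {", paste(S, collapse = ", "), "}")
    else paste0(v, " not in {", paste(S, collapse = ", "), "}")
  } else {
    cut <- formatC(tree$cut[k], digits = 6, format = "g")
    if (side == "left") paste0(v, " <= ", cut) else paste0(v, " > ", cut)
  }
}

node_to_list <- function(tree, k) {
  out <- list(
    estimate = tree$estimate[k],
    prop = tree$prop[k],
    n = tree$n[k],
    conf.low = tree$conf.low[k],
    conf.high = tree$conf.high[k]
  )
  if (!tree$is_leaf[k]) {
    out$var <- tree$var[k]
    if (!is.null(tree$levels_left[[k]])) {
      out$levels_left <- as.list(tree$levels_left[[k]])
    } else {
      out$cut <- tree$cut[k]
    }
    out$left <- node_to_list(tree, tree$child_left[k])
    out$right <- node_to_list(tree, tree$child_right[k])
  }
  out
}

#' Render a subgroup tree
#'
#' Emits the fitted tree with, per node, the subgroup effect estimate (in
#' the outcome's units, on the original covariate scales), the credible
#' interval when attached, and the proportion of the sample in the
#' subgroup.
#'
#' @param tree A `subgroup_tree`.
#' @param format `"text"` (indented plain text), `"json"` (nested document
#'   that [parse_subgroup_tree()] round-trips), or `"dot"` (Graphviz).
#' @return A single string.
#' @export
render_tree <- function(tree, format = c("text", "json", "dot")) {
  format <- match.arg(format)
  fmt <- function(v) formatC(v, digits = 3, format = "f")
  if (format == "text") {
    lines <- character(0)
    walk <- function(k, indent, label) {
      ci <- if (!is.na(tree$conf.low[k])) {
        paste0(" [", fmt(tree$conf.low[k]), ", ", fmt(tree$conf.high[k]), "]")
      } else ""
      lines <<- c(lines, paste0(strrep("  ", indent), label, ": ",
                                fmt(tree$estimate[k]), ci, "  (prop ",
                                fmt(tree$prop[k]), ")"))
      if (!tree$is_leaf[k]) {
        walk(tree$child_left[k], indent + 1, split_label(tree, k, "left"))
        walk(tree$child_right[k], indent + 1, split_label(tree, k, "right"))
      }
    }
    walk(1L, 0, "all")
    paste0(paste(lines, collapse = "\n"), "\n")
  } else if (format == "json") {
    as.character(jsonlite::toJSON(node_to_list(tree, 1L),
                                  auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  } else {
    lines <- c("digraph subgroup_tree {", "  node [shape=box];")
    for (k in seq_len(nrow(tree))) {
      lines <- c(lines, paste0(
        "  n", tree$node[k], " [label=\"", fmt(tree$estimate[k]), "\\nprop ",
        fmt(tree$prop[k]), "\"];"))
      if (!tree$is_leaf[k]) {
        lines <- c(lines, paste0(
          "  n", tree$node[k], " -> n", tree$child_left[k], " [label=\"",
          split_label(tree, k, "left"), "\"];"),
          paste0("  n", tree$node[k], " -> n", tree$child_right[k],
                 " [label=\"", split_label(tree, k, "right"), "\"];"))
      }
    }
    paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
  }
}

#' Parse a JSON-rendered subgroup tree
#'
#' Inverse of `render_tree(tree, "json")` for the tree structure: split
#' variables, cutpoints, level subsets, per-node estimates, intervals,
#' sizes and proportions are restored (member ids are not serialized).
#'
#' @param json A JSON string produced by [render_tree()].
#' @return A `subgroup_tree` tibble (with empty member lists).
#' @export
parse_subgroup_tree <- function(json) {
  lst <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  rows <- list()
  walk <- function(nd, depth, parent) {
    id <- length(rows) + 1L
    rows[[id]] <<- list(node = id, parent = parent, depth = depth,
                        var = nd$var %||% NA_character_,
                        cut = nd$cut %||% NA_real_,
                        levels_left = if (is.null(nd$levels_left)) NULL else
                          unlist(nd$levels_left),
                        n = nd$n, prop = nd$prop, estimate = nd$estimate,
                        conf.low = nd$conf.low %||% NA_real_,
                        conf.high = nd$conf.high %||% NA_real_)
    if (!is.null(nd$left)) {
      cl <- walk(nd$left, depth + 1L, id)
      cr <- walk(nd$right, depth + 1L, id)
      rows[[id]]$child_left <<- cl
      rows[[id]]$child_right <<- cr
    } else {
      rows[[id]]$child_left <<- NA_integer_
      rows[[id]]$child_right <<- NA_integer_
    }
    id
  }
  walk(lst, 0L, NA_integer_)
  tab <- purrr::map_dfr(rows, function(r) {
    tibble::tibble(node = r$node, parent = r$parent, depth = r$depth,
                   var = r$var, cut = as.numeric(r$cut),
                   levels_left = list(r$levels_left),
                   child_left = r$child_left, child_right = r$child_right,
                   is_leaf = is.na(r$var),
                   n = r$n, prop = r$prop, estimate = r$estimate,
                   conf.low = as.numeric(r$conf.low),
                   conf.high = as.numeric(r$conf.high),
                   members = list(character(0)))
  })
  structure(tab, n = tab$n[1],
            class = c("subgroup_tree", class(tibble::tibble())))
}
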