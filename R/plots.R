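# ggplot2 views of the result objects. These mirror the figures such
# analyses report: per-individual CATE curves with credible bands, partial
# dependence over continuous covariates, the CV error surface, and the
# subgroup tree.

#' @export
autoplot.cate_result <- function(object, order_by = c("estimate", "id"),
                                 ...) {
  order_by <- match.arg(order_by)
  df <- tidy(object)
  df$x <- if (order_by == "estimate") rank(df$estimate,
                                           ties.method = "first")
  else seq_len(nrow(df))
  ggplot2::ggplot(df[order(df$x), ],
                  ggplot2::aes(x = .data$x, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = if (order_by == "estimate") "patient (ranked by CATE)" else
        "patient index",
      y = paste0("CATE (", cate_scale(object), ", 12 mg/d - 6 mg/d)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                       y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$covariate[1],
                  y = paste0("average CATE (", attr(object, "scale"), ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  df$base <- factor(df$base)
  df$ntree <- factor(df$ntree)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ntree, y = .data$error,
                                   colour = .data$base,
                                   group = .data$base)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~power, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "number of trees", y = "cross-validation error") +
    ggplot2::theme_minimal()
}

# simple tidy layout: leaves evenly spaced, internal nodes centered over
# their children
tree_layout <- function(tree) {
  xs <- numeric(nrow(tree))
  next_leaf <- 0
  assign_x <- function(k) {
    if (tree$is_leaf[k]) {
      next_leaf <<- next_leaf + 1
      xs[k] <<- next_leaf
    } else {
      assign_x(tree$child_left[k])
      assign_x(tree$child_right[k])
      xs[k] <<- (xs[tree$child_left[k]] + xs[tree$child_right[k]]) / 2
    }
  }
  assign_x(1L)
  tibble::tibble(node = tree$node, x = xs, y = -tree$depth)
}

#' @export
autoplot.subgroup_tree <- function(object, ...) {
  lay <- tree_layout(object)
  df <- dplyr::left_join(tidy(object), lay, by = "node")
  edges <- df[!df$is_leaf, ]
  seg <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(nrow(edges)), function(r) {
      k <- edges$node[r]
      ch <- c(edges$child_left[r], edges$child_right[r])
      tibble::tibble(x = rep(edges$x[r], 2), y = rep(edges$y[r], 2),
                     xend = df$x[match(ch, df$node)],
                     yend = df$y[match(ch, df$node)],
                     label = c(split_label(object, k, "left"),
                               split_label(object, k, "right")))
    }))
  lab <- paste0(formatC(df$estimate, digits = 2, format = "f"), "\n",
                formatC(100 * df$prop, digits = 0, format = "f"), "%")
  p <- ggplot2::ggplot()
  if (nrow(seg)) {
    p <- p +
      ggplot2::geom_segment(data = seg,
                            ggplot2::aes(x = .data$x, y = .data$y,
                                         xend = .data$xend,
                                         yend = .data$yend),
                            colour = "grey50") +
      ggplot2::geom_text(data = seg,
                         ggplot2::aes(x = (.data$x + .data$xend) / 2,
                                      y = (.data$y + .data$yend) / 2,
                                      label = .data$label),
                         size = 2.7, vjust = -0.4)
  }
  p +
    ggplot2::geom_label(data = df,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        label = lab, size = 3) +
    ggplot2::theme_void()
}
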