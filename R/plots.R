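# ggplot2 views of the main result types

#' @export
autoplot.dge_enrichment <- function(object, binwidth = 1, ...) {
  nulls <- tibble(count = object$null_counts)
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_count,
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(
      x = "genes with DGE evidence in random sets",
      y = "random sets",
      title = sprintf("%s: fold %.2f, p %s",
                      object$phenotype %||% "DGE enrichment",
                      object$fold, format(object$empirical_p, digits = 3))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cv_result <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(c("auc_roc", "auc_prc"),
                        names_to = "metric", values_to = "auc") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$metric, y = .data$auc)) +
    ggplot2::geom_point(size = 2, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.4, colour = "red") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = object$family, x = NULL,
                  y = "hold-out AUC per fold") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.risk_model <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$score, fill = .data$source)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "risk score", y = "genes",
                  title = sprintf("%s risk scores (threshold %.2f)",
                                  object$family, object$threshold)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decile_enrichment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$list_name, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$p0[1], linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "proportion in first decile") +
    ggplot2::theme_minimal()
}

#' Dendrogram of a GO-term clustering
#'
#' @param x a [cluster_go_terms()] result.
#' @param ... passed to [plot()].
#' @export
plot.go_term_clustering <- function(x, ...) {
  plot(x$hclust, hang = -1, cex = 0.7,
       main = sprintf("GO term clustering (%d clusters)", x$k),
       xlab = "", sub = "", ...)
  invisible(x)
}
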