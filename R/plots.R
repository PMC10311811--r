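# ggplot2 views of pairwise comparison results. Figures are presentation;
# the numbers in the underlying tibbles are the contract.

#' Bar plot of pairwise disagreement percentages
#'
#' One bar cluster per reference tool (HA1), one bar per compared tool
#' (HA2), showing block or SNV disagreement percentages.
#'
#' @param x A `pairwise_set` from [compare_all()].
#' @param what `"block"` or `"snv"`.
#' @return A ggplot object.
#' @export
plot_disagreement <- function(x, what = c("block", "snv")) {
  what <- match.arg(what)
  ycol <- if (what == "block") "block_disagree_pct" else "snv_disagree_pct"
  ggplot2::ggplot(
    as_tibble(x),
    ggplot2::aes(x = .data$ha1_name, y = .data[[ycol]], fill = .data$ha2_name)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(
      x = "reference (HA1)",
      y = paste0(what, " disagreement (%)"),
      fill = "compared (HA2)",
      title = paste("Pairwise", what, "disagreement")
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of one switch-distance metric across all pairs
#'
#' @param x A `pairwise_set` from [compare_all()].
#' @param metric One of the 12 metric column names (default `"total_sw"`).
#' @return A ggplot object.
#' @export
plot_switch_metric <- function(x, metric = "total_sw") {
  stopifnot_scalar_chr(metric, "metric")
  if (!metric %in% names(x)) {
    hc_abort(paste0("unknown metric column '", metric, "'"), "usage_error")
  }
  ggplot2::ggplot(
    as_tibble(x),
    ggplot2::aes(x = .data$ha1_name, y = .data[[metric]], fill = .data$ha2_name)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(
      x = "reference (HA1)", y = metric, fill = "compared (HA2)",
      title = paste("Switch metric:", metric)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pairwise_set <- function(object, ...) {
  plot_disagreement(object, "block")
}

#' @export
autoplot.phasing_comparison <- function(object, ...) {
  s <- object$summary
  cats <- tibble(
    category = factor(
      c("0 switches", "NA (sites differ)", "switches > 0"),
      levels = c("0 switches", "NA (sites differ)", "switches > 0")
    ),
    blocks = c(s$blk_w_0sw, s$blk_w_NAsw, s$blk_w_sw)
  )
  ggplot2::ggplot(cats, ggplot2::aes(x = .data$category, y = .data$blocks)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "blocks",
      title = paste(object$ha1_name, "(HA1) vs", object$ha2_name, "(HA2)")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
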