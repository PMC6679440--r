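#' Plot the distribution of estimated background error by substitution type
#'
#' Strand-resolved boxplots of the callable per-entry error rates, grouped
#' by substitution type (ref>alt). On semiconductor amplicon data the
#' transition types (A>G/T>C, C>T/G>A) typically sit visibly above the
#' transversions.
#'
#' @param object An `error_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot error_model
#' @export
autoplot.error_model <- function(object, ...) {
  plot_data <- object$entries %>%
    filter(.data$callable) %>%
    mutate(substitution = paste0(.data$ref, ">", .data$alt)) %>%
    tidyr::pivot_longer(
      c("s_fwd", "s_rev"),
      names_to = "strand", values_to = "s"
    ) %>%
    mutate(strand = if_else(.data$strand == "s_fwd", "forward", "reverse"))
  ggplot2::ggplot(
    plot_data,
    ggplot2::aes(x = .data$substitution, y = .data$s, fill = .data$strand)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(
      x = "substitution type", y = "background error rate s",
      title = "Position-specific background error by substitution type"
    ) +
    ggplot2::theme_minimal()
}

#' Plot median FDR against the pseudo-count
#'
#' Visualises a self-consistency benchmark: one line per training-set size
#' (and per model kind if baseline runs are included), pseudo-count on a log
#' scale, separate panels for the Q>=20 and PASS call definitions.
#'
#' @param summary A tibble from [summarise_self_consistency()]; results from
#'   trained and baseline runs can be row-bound before summarising.
#' @return A ggplot.
#' @export
plot_fdr_curves <- function(summary) {
  plot_data <- summary %>%
    tidyr::pivot_longer(
      c("median_fdr_q20", "median_fdr_pass"),
      names_to = "call_rule", values_to = "median_fdr"
    ) %>%
    mutate(
      call_rule = if_else(.data$call_rule == "median_fdr_q20",
        "Q >= 20 calls", "PASS calls"
      ),
      model = if_else(.data$baseline, "constant baseline",
        paste0("trained, M = ", .data$m)
      )
    )
  ggplot2::ggplot(
    plot_data,
    ggplot2::aes(
      x = .data$pseudo_count, y = 100 * .data$median_fdr,
      colour = .data$model, group = .data$model
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$call_rule)) +
    ggplot2::labs(
      x = "pseudo-count C", y = "median FDR (%)",
      title = "Self-consistency FDR vs pseudo-count"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the sensitivity grid from a synthetic-variant experiment
#'
#' TPR bars by allele fraction, one panel per total depth, as produced by
#' [run_synthetic_variant_experiment()].
#'
#' @param tpr_table A tibble with columns `cov`, `vaf`, `tpr`.
#' @return A ggplot.
#' @export
plot_sensitivity_grid <- function(tpr_table) {
  ggplot2::ggplot(
    tpr_table,
    ggplot2::aes(x = factor(100 * .data$vaf), y = .data$tpr)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$cov), labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "VAF (%)", y = "TPR (PASS calls)",
      title = "Sensitivity on synthetic spike-in variants"
    ) +
    ggplot2::theme_minimal()
}
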