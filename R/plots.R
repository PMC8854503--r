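#' Plot heavy V gene usage of one or more repertoire summaries
#'
#' Bar chart of per-sample heavy V usage fractions for the most-used
#' genes, grouped by sample.
#'
#' @param summaries A `b2r_repertoire_summary` or list of them.
#' @param top_n Number of genes to show (ranked by pooled usage).
#' @return A ggplot object.
#' @export
plot_vh_usage <- function(summaries, top_n = 15) {
  usage <- usage_table(summaries, "vh_usage")
  keep <- usage %>%
    group_by(.data$v_gene) %>%
    summarise(total = sum(.data$n), .groups = "drop") %>%
    arrange(dplyr::desc(.data$total)) %>%
    slice(seq_len(min(top_n, dplyr::n()))) %>%
    pull(.data$v_gene)
  usage %>%
    filter(.data$v_gene %in% keep) %>%
    mutate(v_gene = factor(.data$v_gene, levels = keep)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$v_gene, y = .data$fraction,
                                 fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of clonotypes", fill = NULL,
                  title = "Heavy V gene usage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot Jkappa usage (proximal to distal)
#'
#' @inheritParams plot_vh_usage
#' @return A ggplot object.
#' @export
plot_jk_usage <- function(summaries) {
  usage_table(summaries, "jk_usage") %>%
    mutate(j_gene = factor(.data$j_gene, levels = paste0("IGKJ", 1:5))) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$j_gene, y = .data$fraction,
                                 fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of kappa chains", fill = NULL,
                  title = "Jkappa usage") +
    ggplot2::theme_minimal()
}

usage_table <- function(summaries, what) {
  if (inherits(summaries, "b2r_repertoire_summary")) summaries <- list(summaries)
  purrr::map_dfr(summaries, function(s)
    s[[what]] %>% mutate(sample_id = s$sample_id, .before = 1))
}

#' Kappa/lambda pseudocolour plot of simulated flow events
#'
#' Scatter of log10 kappa versus lambda intensity with the gates drawn,
#' the view in which decorated cells appear as a double-positive
#' population.
#'
#' @param events Event tibble from [stain()].
#' @param gates The [gate_set()] used.
#' @param colour_by Event column mapped to colour (default `decorated`).
#' @return A ggplot object.
#' @export
plot_flow_events <- function(events, gates = gate_set(),
                             colour_by = "decorated") {
  ggplot2::ggplot(events,
                  ggplot2::aes(x = .data$kappa_intensity,
                               y = .data$lambda_intensity,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_vline(xintercept = gates$kappa_pos, linetype = 2) +
    ggplot2::geom_hline(yintercept = gates$lambda_pos, linetype = 2) +
    ggplot2::labs(x = "Ig kappa (log10 AU)", y = "Ig lambda (log10 AU)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.b2r_cohort <- function(object, ...) {
  pat <- object$subjects %>% filter(.data$group == "patient")
  ggplot2::ggplot(pat, ggplot2::aes(x = .data$g4_pct,
                                    y = .data$kl_apparent_pct)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$hl_call)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "9G4+ B cells (%)",
                  y = "apparent kappa+lambda+ B cells (%)",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.b2r_repertoire_summary <- function(object, ...) {
  plot_vh_usage(object)
}
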