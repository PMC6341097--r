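#' Plot a burden scan
#'
#' Odds ratio (log scale) against statistical evidence, one point per gene
#' or variant; the Bonferroni threshold at 0.05 is drawn as a dashed line.
#' Infinite or missing odds ratios are dropped from the panel with a
#' message.
#'
#' @param object A `burden_scan` from [run_burden_scan()] or
#'   [per_variant_burden()].
#' @param label_top Number of smallest-p rows to label (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_scan
#' @export
autoplot.burden_scan <- function(object, label_top = 3, ...) {
  df <- as_tibble(object) %>%
    mutate(label = if ("variant_id" %in% names(object)) .data$variant_id else .data$gene)
  drop <- !is.finite(df$or) | df$or <= 0
  if (any(drop)) {
    inform(paste0(sum(drop), " result(s) with non-finite odds ratio not drawn"))
    df <- df[!drop, , drop = FALSE]
  }
  thresh <- 0.05 / max(1, nrow(object))
  top <- df %>% arrange(.data$p) %>% head(label_top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_variants), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(thresh), linetype = "dashed") +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (conditional MLE)",
                  y = expression(-log[10](p)),
                  size = "qualifying variants") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Enrichment ratio per gene set, points sized by observed overlap and
#' coloured by FDR significance.
#'
#' @param object An `enrichment_result` from [run_enrichment()].
#' @param max_sets Show at most this many sets, smallest p first.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, max_sets = 20, ...) {
  df <- as_tibble(object) %>%
    arrange(.data$p) %>%
    head(max_sets) %>%
    mutate(name = factor(.data$name, levels = rev(.data$name)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$name)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$O, colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "enrichment ratio (observed / expected)", y = NULL,
                  size = "genes in overlap", colour = "FDR < threshold") +
    ggplot2::theme_minimal()
}

#' Plot per-family VOI counts
#'
#' @param object A `voi_result` from [identify_vois()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot voi_result
#' @export
autoplot.voi_result <- function(object, ...) {
  df <- object$family_summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family_id, y = .data$n_vois)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "variants of interest") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Tidiers for rarefam result objects
#'
#' [generics::tidy()] returns the per-unit result table (per gene, per set,
#' per VOI record) as a plain tibble; [generics::glance()] returns a
#' one-row summary of the whole analysis.
#'
#' @param x A `burden_scan`, `enrichment_result`, `tdt_result` or
#'   `voi_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_rarefam
NULL
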