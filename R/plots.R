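# ggplot2 views of the main result types.

#' Plot an inheritance-mode breakdown
#'
#' Stacked bars of the class percentages, one bar per group.
#'
#' @param breakdown tibble from [mode_breakdown()].
#' @return a ggplot object.
#' @export
plot_mode_breakdown <- function(breakdown) {
  keys <- setdiff(names(breakdown), c("mode", "n", "percent"))
  breakdown$group <- if (length(keys)) {
    do.call(paste, c(breakdown[keys], sep = " / "))
  } else {
    "all genes"
  }
  breakdown$mode <- factor(breakdown$mode, levels = inheritance_classes)
  ggplot(breakdown, aes(x = .data$group, y = .data$percent,
                        fill = .data$mode)) +
    geom_col() +
    labs(x = NULL, y = "% of genes", fill = "mode of inheritance") +
    theme_minimal()
}

#' @method autoplot inheritance_fit
#' @export
autoplot.inheritance_fit <- function(object, ...) {
  plot_mode_breakdown(mode_breakdown(object))
}

#' Plot a heterosis table
#'
#' Side-by-side mid-parent and high-parent heterosis per trait cell,
#' annotated with significance flags where available.
#'
#' @param het tibble from [heterosis_table()].
#' @return a ggplot object.
#' @export
plot_heterosis <- function(het) {
  keys <- intersect(c("trait", "environment", "timepoint"), names(het))
  het$cell <- do.call(paste, c(het[keys], sep = " / "))
  long <- tidyr::pivot_longer(
    het, dplyr::all_of(c("mph", "hph")),
    names_to = "measure", values_to = "percent")
  if ("mph_flag" %in% names(het)) {
    long$flag <- ifelse(long$measure == "mph", het$mph_flag[match(
      long$cell, het$cell)], het$hph_flag[match(long$cell, het$cell)])
  } else {
    long$flag <- ""
  }
  ggplot(long, aes(x = .data$cell, y = .data$percent,
                   fill = toupper(.data$measure))) +
    geom_col(position = "dodge") +
    geom_text(aes(label = .data$flag),
              position = position_dodge(width = 0.9), vjust = -0.2) +
    labs(x = NULL, y = "heterosis (%)", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot module-trait correlations
#'
#' Heatmap of Pearson correlations between module eigengenes and traits.
#'
#' @param x a `coexpression_fit` with trait correlations, or the
#'   correlation tibble from [module_trait_correlation()].
#' @return a ggplot object.
#' @export
plot_module_trait <- function(x) {
  tc <- if (inherits(x, "coexpression_fit")) x$trait_cor else x
  if (is.null(tc)) abort("no module-trait correlations available")
  ggplot(tc, aes(x = .data$trait, y = .data$module, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$r)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal()
}

#' @method autoplot coexpression_fit
#' @export
autoplot.coexpression_fit <- function(object, ...) {
  if (!is.null(object$trait_cor)) return(plot_module_trait(object))
  sizes <- dplyr::count(object$modules, .data$module, sort = TRUE)
  ggplot(sizes, aes(x = stats::reorder(.data$module, -.data$n),
                    y = .data$n)) +
    geom_col() +
    labs(x = NULL, y = "genes per module") +
    theme_minimal()
}

#' Plot enrichment results
#'
#' Dot plot of the top terms by FDR.
#'
#' @param results tibble from [hypergeom_enrich()].
#' @param top_n number of terms to show.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(results, top_n = 20) {
  d <- head(results, top_n)
  ggplot(d, aes(x = -log10(.data$fdr),
                y = stats::reorder(.data$term, -.data$p_value),
                size = .data$k)) +
    geom_point() +
    labs(x = expression(-log[10] ~ FDR), y = NULL, size = "overlap") +
    theme_minimal()
}

#' @method autoplot sdg_analysis
#' @export
autoplot.sdg_analysis <- function(object, ...) {
  d <- tidy(object) |> dplyr::count(.data$set)
  ggplot(d, aes(x = .data$set, y = .data$n)) +
    geom_col() +
    labs(x = NULL, y = "genes") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
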