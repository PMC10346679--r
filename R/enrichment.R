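#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the query gene set overlaps the
#' term more than expected under random draws from the universe:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' universe size, `K` the term size within the universe, `n` the query size
#' and `k` the observed overlap (upper tail, over-representation only).
#' P-values are BH-adjusted across the tested terms.
#'
#' @param query character vector of gene ids; genes outside the universe
#'   are dropped with a warning.
#' @param annotation annotation tibble (`term`, `description`, list-column
#'   `genes`), e.g. from [read_gmt()] or [simulate_annotation()].
#' @param universe background gene set; defaults to the union of all
#'   annotated genes. Annotated genes outside the universe are ignored
#'   (the background is the annotated-and-measured intersection).
#' @param min_term_size terms annotating fewer universe genes are excluded
#'   before testing (default 5).
#' @return tibble sorted by p-value: `term`, `description`, `k`, `K`, `n`,
#'   `N`, `p_value`, `fdr`.
#' @examples
#' ann <- tibble::tibble(term = "t1", description = "",
#'                       genes = list(letters[1:5]))
#' hypergeom_enrich(letters[1:4], ann, universe = letters[1:10],
#'                  min_term_size = 1)
#' @export
hypergeom_enrich <- function(query, annotation, universe = NULL,
                             min_term_size = 5) {
  universe <- unique(universe %||%
                       unlist(annotation$genes, use.names = FALSE))
  if (length(universe) == 0) abort("the gene universe is empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the universe were dropped",
                 length(outside)))
    query <- intersect(query, universe)
  }
  empty <- tibble(term = character(), description = character(),
                  k = integer(), K = integer(), n = integer(), N = integer(),
                  p_value = numeric(), fdr = numeric())
  if (length(query) == 0) return(empty)

  N <- length(universe)
  n <- length(query)
  term_genes <- map(annotation$genes, intersect, y = universe)
  K <- lengths(term_genes)
  keep <- K >= min_term_size
  if (!any(keep)) return(empty)
  k <- vapply(term_genes[keep], function(g) length(intersect(g, query)),
              integer(1))
  p <- phyper(k - 1, K[keep], N - K[keep], n, lower.tail = FALSE)
  tibble(term = annotation$term[keep],
         description = annotation$description[keep],
         k = as.integer(k), K = as.integer(K[keep]),
         n = n, N = N,
         p_value = p, fdr = bh_adjust(p)) |>
    dplyr::arrange(.data$p_value)
}

#' Filter enrichment results to the significant terms
#'
#' Keeps terms with `fdr <= fdr_max` (threshold inclusive; default 0.05,
#' the study's rule).
#'
#' @param results tibble from [hypergeom_enrich()].
#' @param fdr_max FDR threshold.
#' @return the filtered tibble.
#' @export
significant_terms <- function(results, fdr_max = 0.05) {
  dplyr::filter(results, .data$fdr <= fdr_max)
}
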