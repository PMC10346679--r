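#' FPKM normalization
#'
#' Converts raw counts to fragments per kilobase of exon model per million
#' mapped reads: `FPKM = count * 1e9 / (library_total * gene_length)`, with
#' the per-sample column sum standing in for the total of mapped reads.
#'
#' @param counts tibble of raw counts: `gene_id` plus one integer column per
#'   sample.
#' @param gene_lengths tibble with `gene_id` and `length` (bp).
#' @return tibble of the same shape with FPKM values.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10)
#' lens <- tibble::tibble(gene_id = "g1", length = 1000)
#' compute_fpkm(counts, lens)  # 10 reads over a 1e6-read library would be 10
#' @export
compute_fpkm <- function(counts, gene_lengths) {
  m <- as_expr_matrix(counts)
  as_expr_tibble(fpkm_matrix(m, gene_lengths))
}

fpkm_matrix <- function(m, gene_lengths) {
  if (any(m < 0)) abort("counts must be nonnegative")
  len <- aligned_lengths(gene_lengths, rownames(m))
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf("sample(s) with zero total counts: %s",
                  paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  sweep(m, 2, totals, "/") * 1e9 / len
}

#' Drop genes expressed in too few samples
#'
#' Keeps genes with nonzero expression in at least `min_expressed_fraction`
#' of the samples (default 80%, the study's low-expression rule); row order
#' is preserved.
#'
#' @param expr expression tibble (`gene_id` + sample columns).
#' @param min_expressed_fraction required fraction of samples with nonzero
#'   expression, in (0, 1].
#' @return the filtered expression tibble (possibly empty).
#' @export
filter_low_expression <- function(expr, min_expressed_fraction = 0.8) {
  if (min_expressed_fraction <= 0 || min_expressed_fraction > 1) {
    abort("min_expressed_fraction must lie in (0, 1]")
  }
  m <- as_expr_matrix(expr)
  frac <- rowMeans(m > 0)
  expr[frac >= min_expressed_fraction, , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (a validating wrapper around
#' [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return BH-adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  check_probabilities(p)
  p.adjust(p, method = "BH")
}

welch_rows <- function(la, lb) {
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, var); vb <- apply(lb, 1, var)
  se2 <- va / na + vb / nb
  degen <- se2 == 0
  se2[degen] <- 1  # placeholder; overwritten below
  t_stat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  df[degen] <- 1
  p <- 2 * pt(-abs(t_stat), df)
  # zero variance in both groups: identical means -> 1, separated -> 0
  p[degen] <- ifelse(abs(mb - ma)[degen] < 1e-12, 1, 0)
  p
}

#' Differential expression between two replicated groups
#'
#' Tests each gene for differential expression between two sample groups.
#' The reported effect size is always the fold change on FPKM,
#' `log2_ratio = log2((mean_b + c) / (mean_a + c))` with pseudocount `c`,
#' and p-values come from the chosen test:
#'
#' * `"exact_nb"` (default): the classic exact negative-binomial test on raw
#'   counts (edgeR's `exactTest` after TMM normalization and empirical-Bayes
#'   dispersion estimation). Information sharing across genes gives this
#'   test useful power at very stringent FDR cutoffs even with 3 replicates,
#'   which a per-gene t-test cannot achieve.
#' * `"welch"`: a two-sided Welch t-test on `log2(FPKM + 1)`, entirely
#'   self-contained and assumption-light, at a substantial cost in power at
#'   small replicate numbers.
#'
#' Genes with zero counts everywhere get `p_value = 1` and `log2_ratio = 0`.
#' The `direction` column applies the study's DEG rule
#' (`|log2_ratio| >= lfc_min` and `fdr <= fdr_max`, both inclusive).
#'
#' @param counts raw count tibble (`gene_id` + sample columns).
#' @param gene_lengths tibble with `gene_id`, `length`.
#' @param group_a,group_b character vectors of sample column names, at least
#'   2 each.
#' @param method `"exact_nb"` or `"welch"`.
#' @param pseudocount FPKM pseudocount for the fold change (default 1).
#' @param lfc_min,fdr_max DEG thresholds used for `direction` (defaults 1
#'   and 0.005, the study's rule).
#' @return tibble: `gene_id`, `mean_a`, `mean_b` (FPKM), `log2_ratio`,
#'   `p_value`, `fdr`, `direction` (`up` / `down` / `ns`, where `up` means
#'   higher in `group_b`).
#' @seealso [call_degs()]
#' @export
test_differential <- function(counts, gene_lengths, group_a, group_b,
                              method = c("exact_nb", "welch"),
                              pseudocount = 1,
                              lfc_min = 1, fdr_max = 0.005) {
  method <- match.arg(method)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("at least 2 replicates per group are required")
  }
  m <- as_expr_matrix(counts)
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) {
    abort(sprintf("samples not in the count table: %s",
                  paste(missing, collapse = ", ")))
  }
  sub <- m[, c(group_a, group_b), drop = FALSE]
  fpkm <- fpkm_matrix(sub, gene_lengths)
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  mean_a <- unname(rowMeans(fpkm[, ia, drop = FALSE]))
  mean_b <- unname(rowMeans(fpkm[, ib, drop = FALSE]))
  lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))

  all_zero <- rowSums(sub) == 0
  p <- if (method == "welch") {
    welch_rows(log2(fpkm[, ia, drop = FALSE] + 1),
               log2(fpkm[, ib, drop = FALSE] + 1))
  } else {
    grp <- factor(rep(c("A", "B"), c(length(ia), length(ib))),
                  levels = c("A", "B"))
    y <- edgeR::DGEList(counts = sub, group = grp)
    y <- edgeR::calcNormFactors(y)
    y <- edgeR::estimateDisp(y)
    et <- edgeR::exactTest(y, pair = c("A", "B"))
    et$table$PValue
  }
  p <- unname(p)
  p[all_zero] <- 1
  lfc[all_zero] <- 0
  fdr <- bh_adjust(p)
  tibble(gene_id = rownames(sub),
         mean_a = mean_a, mean_b = mean_b,
         log2_ratio = lfc, p_value = p, fdr = fdr,
         direction = dplyr::case_when(
           lfc >= lfc_min & fdr <= fdr_max ~ "up",
           lfc <= -lfc_min & fdr <= fdr_max ~ "down",
           .default = "ns"
         ))
}

#' Extract up- and down-regulated gene sets from a DEG table
#'
#' Applies the DEG rule (`log2_ratio >= lfc_min` for up, `<= -lfc_min` for
#' down, both with `fdr <= fdr_max`; thresholds inclusive) and returns the
#' two disjoint gene sets.
#'
#' @param results a tibble from [test_differential()] (needs `gene_id`,
#'   `log2_ratio`, `fdr`).
#' @param lfc_min,fdr_max thresholds (defaults 1 and 0.005).
#' @return `list(up = , down = )` of gene-id character vectors.
#' @export
call_degs <- function(results, lfc_min = 1, fdr_max = 0.005) {
  if (lfc_min <= 0 || fdr_max <= 0) abort("thresholds must be positive")
  up <- results$gene_id[results$log2_ratio >= lfc_min &
                          results$fdr <= fdr_max]
  down <- results$gene_id[results$log2_ratio <= -lfc_min &
                            results$fdr <= fdr_max]
  list(up = up, down = down)
}
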