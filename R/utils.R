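# Internal helpers shared across modules. Expression tables travel as tibbles
# with a `gene_id` column plus one numeric column per sample; linear algebra
# happens on matrices built here.

# df (gene_id + sample columns) -> numeric matrix with gene_id rownames
as_expr_matrix <- function(x, id_col = "gene_id") {
  if (is.matrix(x)) return(x)
  if (!is.data.frame(x) || !id_col %in% names(x)) {
    abort(sprintf("expected a data frame with a '%s' column", id_col))
  }
  ids <- as.character(x[[id_col]])
  if (anyDuplicated(ids)) abort("gene identifiers must be unique")
  m <- as.matrix(x[setdiff(names(x), id_col)])
  if (!is.numeric(m)) abort("all sample columns must be numeric")
  rownames(m) <- ids
  m
}

# matrix -> tibble with gene_id first
as_expr_tibble <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out[[id_col]] <- rownames(m) %||% as.character(seq_len(nrow(m)))
  out[, c(id_col, setdiff(names(out), id_col))]
}

# lengths aligned to the gene order of `ids`; errors on missing genes
aligned_lengths <- function(gene_lengths, ids) {
  if (!all(c("gene_id", "length") %in% names(gene_lengths))) {
    abort("gene_lengths must have columns 'gene_id' and 'length'")
  }
  len <- setNames(gene_lengths$length, gene_lengths$gene_id)[ids]
  if (anyNA(len)) abort("gene_lengths is missing some genes in the count table")
  if (any(len <= 0)) abort("gene lengths must be positive")
  unname(len)
}

check_probabilities <- function(p, what = "p-values") {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort(sprintf("%s must lie in [0, 1] with no missing values", what))
  }
  invisible(p)
}

# Welch two-sided p that survives zero-variance groups:
# equal constant groups -> 1, different constant groups -> 0
welch_p <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  t.test(x, y)$p.value
}

signif_flag <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}
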