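#' Potency ratio
#'
#' The dominance ratio `Hp = d / a` of the composite dominance and additive
#' effects. Degenerate cases are defined so classification stays total:
#' `a = 0, d != 0` gives signed infinity (over-dominance downstream); both
#' zero gives 0 (additive).
#'
#' @param d_hat,a_hat dominance and additive effects (vectorized).
#' @return numeric vector, possibly infinite.
#' @export
potency_ratio <- function(d_hat, a_hat) {
  ifelse(a_hat == 0,
         ifelse(d_hat == 0, 0, sign(d_hat) * Inf),
         d_hat / a_hat)
}

#' Classify the mode of inheritance from the potency ratio
#'
#' Applies the four half-open intervals used in the source study:
#' additive `(-0.2, 0.2]`, partial dominance `(0.2, 0.8]` or `(-0.8, -0.2]`,
#' dominance `(0.8, 1.2]` or `(-1.2, -0.8]`, over-dominance `Hp <= -1.2` or
#' `Hp > 1.2`. The intervals are applied exactly as printed, which makes the
#' boundary points asymmetric in sign: `Hp = -0.2` is partial dominance
#' while `Hp = +0.2` is additive, and `Hp = -1.2` is over-dominance while
#' `+1.2` is dominance. Signed infinities map to over-dominance.
#'
#' @param hp potency ratios (vectorized; may contain `Inf`).
#' @param boundaries the three positive class boundaries, strictly
#'   increasing (default `c(0.2, 0.8, 1.2)`).
#' @return character vector over `additive`, `partial_dominance`,
#'   `dominance`, `over_dominance`.
#' @examples
#' classify_mode(c(0, 0.5, 1.0, 2.0, -0.2, Inf))
#' @export
classify_mode <- function(hp, boundaries = c(0.2, 0.8, 1.2)) {
  if (length(boundaries) != 3 || any(diff(boundaries) <= 0) ||
      boundaries[1] <= 0) {
    abort("boundaries must be three strictly increasing positive values")
  }
  b <- boundaries
  dplyr::case_when(
    is.na(hp) ~ NA_character_,
    hp > -b[1] & hp <= b[1] ~ "additive",
    (hp > b[1] & hp <= b[2]) | (hp > -b[2] & hp <= -b[1]) ~ "partial_dominance",
    (hp > b[2] & hp <= b[3]) | (hp > -b[3] & hp <= -b[2]) ~ "dominance",
    .default = "over_dominance"
  )
}

inheritance_classes <- c("additive", "partial_dominance",
                         "dominance", "over_dominance")

effects_from_stats <- function(m1, m2, mf, sigma2, df, n1, n2, nf) {
  m1 <- unname(m1); m2 <- unname(m2); mf <- unname(mf)
  sigma2 <- unname(sigma2)
  a <- (m1 - m2) / 2
  d <- mf - (m1 + m2) / 2
  se_a <- sqrt(sigma2 * (1 / n1 + 1 / n2)) / 2
  se_d <- sqrt(sigma2 * (1 / nf + 1 / (4 * n1) + 1 / (4 * n2)))
  hp <- potency_ratio(d, a)
  tibble(mu_hat = (m1 + m2) / 2, a_hat = a, d_hat = d,
         se_a = se_a, se_d = se_d, sigma2 = sigma2, df = df,
         hp = hp, mode = classify_mode(hp))
}

#' Additive/dominance decomposition for one gene
#'
#' Estimates the trio ANOVA `y = u + GA + GD + SR + e` from replicated
#' expression of the two parents and the hybrid:
#' `a = (mean(P1) - mean(P2)) / 2` (composite additive effect),
#' `d = mean(F1) - midparent` (composite dominance effect), `u` the
#' mid-parent mean. When replicates are paired across genotypes (equal
#' counts and `paired = TRUE`) the replication effect `SR` is estimated
#' from replicate-block means and removed from the residual; otherwise the
#' model reduces to genotype means with a pooled within-genotype residual.
#'
#' @param p1,p2,f1 numeric replicate vectors (>= 2 each), on the analysis
#'   expression scale (conventionally `log2(FPKM + 1)`; see
#'   [fit_inheritance()] for whole-matrix fits).
#' @param paired estimate the replication effect from paired replicate
#'   blocks (requires equal replicate counts).
#' @return one-row tibble: `mu_hat`, `a_hat`, `d_hat`, `se_a`, `se_d`,
#'   `sigma2`, `df`, `hp`, `mode`, plus a list-column `rep_effects`
#'   (replicate-block effects, `NULL` when unpaired).
#' @examples
#' estimate_effects(c(10, 10), c(6, 6), c(9, 9))  # a = 2, d = 1, Hp = 0.5
#' @export
estimate_effects <- function(p1, p2, f1, paired = TRUE) {
  n1 <- length(p1); n2 <- length(p2); nf <- length(f1)
  if (min(n1, n2, nf) < 2) {
    abort("at least 2 replicates per genotype are required")
  }
  paired <- paired && n1 == n2 && n2 == nf
  m1 <- mean(p1); m2 <- mean(p2); mf <- mean(f1)
  if (paired) {
    y <- rbind(p1, p2, f1)
    rep_eff <- colMeans(y) - mean(y)
    resid <- y - rowMeans(y) - rep(rep_eff, each = 3)
    df <- 2 * (n1 - 1)
    sigma2 <- sum(resid^2) / df
  } else {
    rep_eff <- NULL
    df <- n1 + n2 + nf - 3
    sigma2 <- ((n1 - 1) * var(p1) + (n2 - 1) * var(p2) +
                 (nf - 1) * var(f1)) / df
  }
  out <- effects_from_stats(m1, m2, mf, sigma2, df, n1, n2, nf)
  out$rep_effects <- list(rep_eff)
  out
}

#' Fit the trio inheritance model across a whole expression matrix
#'
#' Vectorized per-gene additive/dominance decomposition over an expression
#' table, grouped by design cells. With the default grouping every
#' environment x timepoint cell is fit from its own replicates (the way the
#' source study reports per-timepoint breakdowns); `group_by = NULL` pools
#' all libraries of each genotype into one fit, appropriate when no
#' environment or timepoint effect is expected and maximal precision is
#' wanted.
#'
#' @param expr expression tibble (`gene_id` + sample columns), typically
#'   FPKM.
#' @param design design tibble with `sample_id`, `genotype` (`P1`, `P2`,
#'   `F1`) and any grouping columns.
#' @param group_by character vector of design columns defining fit cells,
#'   or `NULL` for a single pooled fit.
#' @param transform `"log2p1"` (analysis on `log2(expr + 1)`, the default
#'   scale) or `"identity"`.
#' @param paired passed to the per-gene fit; replication effects are
#'   estimable only for paired replicates.
#' @return an object of class `inheritance_fit` with an `effects` tibble
#'   (`gene_id`, grouping columns, `mu_hat`, `a_hat`, `d_hat`, `se_a`,
#'   `se_d`, `sigma2`, `df`, `hp`, `mode`). Use [tidy()] / [glance()] /
#'   [mode_breakdown()] on it.
#' @export
fit_inheritance <- function(expr, design,
                            group_by = c("environment", "timepoint"),
                            transform = c("log2p1", "identity"),
                            paired = TRUE) {
  transform <- match.arg(transform)
  m <- as_expr_matrix(expr)
  if (transform == "log2p1") m <- log2(m + 1)
  if (!all(c("sample_id", "genotype") %in% names(design))) {
    abort("design needs 'sample_id' and 'genotype' columns")
  }
  design <- design[design$sample_id %in% colnames(m), , drop = FALSE]
  if (!all(c("P1", "P2", "F1") %in% design$genotype)) {
    abort("design must contain genotypes P1, P2 and F1")
  }
  if (is.null(group_by)) {
    cells <- list(design)
    keys <- tibble(.rows = 1)[, 0]
  } else {
    missing_cols <- setdiff(group_by, names(design))
    if (length(missing_cols)) {
      abort(sprintf("grouping columns not in design: %s",
                    paste(missing_cols, collapse = ", ")))
    }
    grouped <- dplyr::group_by(design, dplyr::across(dplyr::all_of(group_by)))
    keys <- dplyr::group_keys(grouped)
    cells <- dplyr::group_split(grouped)
  }

  fit_cell <- function(cell) {
    cols <- function(g) cell$sample_id[cell$genotype == g]
    s1 <- cols("P1"); s2 <- cols("P2"); sf <- cols("F1")
    n1 <- length(s1); n2 <- length(s2); nf <- length(sf)
    if (min(n1, n2, nf) < 2) {
      abort("each genotype needs at least 2 replicates in every fit cell")
    }
    x1 <- m[, s1, drop = FALSE]
    x2 <- m[, s2, drop = FALSE]
    xf <- m[, sf, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2); mfm <- rowMeans(xf)
    use_pairs <- paired && n1 == n2 && n2 == nf
    if (use_pairs) {
      # two-way (genotype x replicate-block) residual per gene
      n <- n1
      block_mean <- (x1 + x2 + xf) / 3
      grand <- (m1 + m2 + mfm) / 3
      res <- cbind(x1 - m1, x2 - m2, xf - mfm) -
        cbind(block_mean, block_mean, block_mean) + grand
      df <- 2 * (n - 1)
      sigma2 <- rowSums(res^2) / df
    } else {
      df <- n1 + n2 + nf - 3
      sigma2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2) +
                   rowSums((xf - mfm)^2)) / df
    }
    dplyr::bind_cols(tibble(gene_id = rownames(m)),
                     effects_from_stats(m1, m2, mfm, sigma2, df, n1, n2, nf))
  }

  effects <- purrr::map2(cells, seq_along(cells), function(cell, i) {
    dplyr::bind_cols(keys[rep(i, nrow(m)), , drop = FALSE], fit_cell(cell))
  }) |> purrr::list_rbind()

  structure(list(effects = effects, group_by = group_by,
                 transform = transform,
                 n_genes = nrow(m), n_cells = length(cells)),
            class = "inheritance_fit")
}

#' @export
print.inheritance_fit <- function(x, ...) {
  cat(sprintf("trio inheritance fit: %d genes, %d fit cell(s), scale %s\n",
              x$n_genes, x$n_cells, x$transform))
  print(head(x$effects))
  invisible(x)
}

#' @rdname fit_inheritance
#' @param x an `inheritance_fit`.
#' @param ... unused.
#' @method tidy inheritance_fit
#' @export
tidy.inheritance_fit <- function(x, ...) x$effects

#' @rdname fit_inheritance
#' @method glance inheritance_fit
#' @export
glance.inheritance_fit <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_cells = x$n_cells,
         transform = x$transform,
         median_sigma2 = median(x$effects$sigma2))
}

#' Breakdown of inheritance modes
#'
#' Percentage of genes falling in each inheritance class, optionally per
#' group (e.g. per environment and timepoint). Percentages sum to 100
#' within each group; classes with no genes appear with 0.
#'
#' @param x an `inheritance_fit` or an effects tibble with a `mode` column.
#' @param by character vector of grouping columns (default: the fit's own
#'   grouping, or none for a plain tibble).
#' @return tibble with grouping columns, `mode`, `n` and `percent`.
#' @examples
#' mode_breakdown(tibble::tibble(mode = classify_mode(c(0, 0.5, 1, 2))))
#' @export
mode_breakdown <- function(x, by = NULL) {
  if (inherits(x, "inheritance_fit")) {
    by <- by %||% x$group_by
    x <- x$effects
  }
  if (!nrow(x)) abort("no gene effect estimates to summarize")
  if (!"mode" %in% names(x)) abort("x needs a 'mode' column")
  by <- intersect(by %||% character(), names(x))
  x |>
    dplyr::mutate(mode = factor(.data$mode, levels = inheritance_classes)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::count(.data$mode, .drop = FALSE) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(mode = as.character(.data$mode))
}

#' Confidence-interval gate on dominance contrasts
#'
#' Optional pre-filter mirroring the study's construction of 99.8%
#' confidence intervals for `d - a` (when `d > 0`) or `d + a` (when
#' `d < 0`): genes whose relevant contrast interval covers 0 are dropped
#' before summarizing the mode breakdown.
#'
#' @param effects effects tibble from [fit_inheritance()] / [tidy()].
#' @param level confidence level (default 0.998).
#' @return the filtered effects tibble.
#' @export
hp_ci_gate <- function(effects, level = 0.998) {
  need <- c("a_hat", "d_hat", "se_a", "se_d", "df")
  if (!all(need %in% names(effects))) {
    abort(paste("effects needs columns", paste(need, collapse = ", ")))
  }
  contrast <- ifelse(effects$d_hat > 0,
                     effects$d_hat - effects$a_hat,
                     effects$d_hat + effects$a_hat)
  se <- sqrt(effects$se_a^2 + effects$se_d^2)
  crit <- qt(1 - (1 - level) / 2, effects$df)
  keep <- effects$d_hat != 0 & abs(contrast) > crit * se
  effects[keep, , drop = FALSE]
}
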