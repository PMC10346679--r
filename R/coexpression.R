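# Weighted gene co-expression network analysis, written out in full:
# MAD gene selection, soft-threshold adjacency, topological overlap,
# average-linkage module detection, module eigengenes, module-trait
# correlation.

#' Select the most variable genes by median absolute deviation
#'
#' Keeps the `n` genes with the largest MAD across samples (the study used
#' the top 5000 after low-expression filtering). Ties are broken by input
#' order.
#'
#' @param expr expression tibble (`gene_id` + sample columns).
#' @param n number of genes to keep (at most the number of rows).
#' @return the filtered expression tibble, original row order preserved.
#' @export
select_top_mad <- function(expr, n = 5000) {
  m <- as_expr_matrix(expr)
  if (n > nrow(m)) abort("n exceeds the number of genes")
  mads <- apply(m, 1, mad)
  keep <- sort(head(order(mads, decreasing = TRUE), n))
  expr[keep, , drop = FALSE]
}

#' Soft-threshold adjacency matrix
#'
#' Unsigned weighted network: `a_ij = |cor(x_i, x_j)|^power` with Pearson
#' correlation across samples and unit diagonal. Genes with zero variance
#' get correlation 0 (with a warning).
#'
#' @param expr expression tibble (`gene_id` + sample columns, >= 3 samples).
#' @param power soft-thresholding exponent (>= 1; the study used 20).
#' @return symmetric gene x gene adjacency matrix in `[0, 1]` with the
#'   chosen power stored in attribute `"power"`.
#' @export
soft_adjacency <- function(expr, power = 20) {
  m <- as_expr_matrix(expr)
  if (ncol(m) < 3) abort("at least 3 samples are required")
  if (power < 1) abort("power must be >= 1")
  flat <- apply(m, 1, sd) == 0
  if (any(flat)) {
    warn(sprintf("%d zero-variance gene(s); their correlations are set to 0",
                 sum(flat)))
  }
  cc <- suppressWarnings(cor(t(m)))
  cc[is.na(cc)] <- 0
  adj <- abs(cc)^power
  diag(adj) <- 1
  attr(adj, "power") <- power
  adj
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu`, the sum excluding `u = i, j`;
#' `TOM_ii = 1`. The corresponding dissimilarity is `1 - TOM`.
#'
#' @param adjacency symmetric adjacency matrix in `[0, 1]` with unit
#'   diagonal (from [soft_adjacency()]).
#' @return symmetric TOM matrix in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  a <- unclass(adjacency)
  if (!isSymmetric(unname(a))) abort("adjacency must be symmetric")
  # shared-neighbour sums: subtract the u = i and u = j terms (diag is 1)
  l <- a %*% a - 2 * a
  k <- rowSums(a) - 1
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity with a
#' static cut: clusters at `cut_height` become modules, clusters smaller
#' than `min_module_size` are collected into the unassigned module
#' `"grey"`, and modules are labelled `M1`, `M2`, ... by decreasing size.
#'
#' @param dissimilarity square dissimilarity matrix (typically
#'   `1 - topological_overlap(...)`).
#' @param min_module_size smallest cluster kept as a module (default 30).
#' @param cut_height static cut height on the dissimilarity scale; default
#'   0.995, just below the ceiling of a TOM dissimilarity, so unconnected
#'   genes fall off as singletons while correlated blocks stay together. A
#'   degenerate tree whose merges all happen at one height yields a single
#'   module.
#' @return tibble with `gene_id` and `module`.
#' @export
detect_modules <- function(dissimilarity, min_module_size = 30,
                           cut_height = 0.995) {
  d <- unclass(dissimilarity)
  if (nrow(d) != ncol(d)) abort("dissimilarity must be square")
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  tree <- hclust(as.dist(d), method = "average")
  if (diff(range(tree$height)) < 1e-12) {
    return(tibble(gene_id = ids, module = "M1"))
  }
  cl <- cutree(tree, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  big <- big[order(sizes[big], decreasing = TRUE)]
  label <- setNames(rep("grey", length(sizes)), names(sizes))
  label[big] <- sprintf("M%d", seq_along(big))
  tibble(gene_id = ids, module = unname(label[as.character(cl)]))
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module expression — a
#' per-sample summary profile. The sign is oriented so the eigengene
#' correlates positively with the module's mean standardized expression.
#' A single-gene module returns that gene's standardized profile.
#'
#' @param expr expression tibble or matrix restricted to one module's genes
#'   (`gene_id` + sample columns).
#' @return named numeric vector over samples, scaled to unit variance.
#' @export
module_eigengene <- function(expr) {
  m <- as_expr_matrix(expr)
  if (!nrow(m)) abort("the module is empty")
  sds <- apply(m, 1, sd)
  scaled <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  if (nrow(m) == 1) {
    e <- scaled[1, ]
  } else {
    e <- prcomp(t(scaled), center = FALSE, scale. = FALSE)$x[, 1]
  }
  avg <- colMeans(scaled)
  ori <- cor(e, avg)
  if (!is.na(ori) && ori < 0) e <- -e
  if (sd(e) > 0) e <- e / sd(e)
  setNames(e, colnames(m))
}

#' Eigengenes of every detected module
#'
#' @param expr expression tibble covering the clustered genes.
#' @param modules tibble from [detect_modules()].
#' @param include_grey also compute an eigengene for the unassigned
#'   `"grey"` collection (default `FALSE`).
#' @return tibble: `sample_id` plus one eigengene column per module.
#' @export
module_eigengenes <- function(expr, modules, include_grey = FALSE) {
  m <- as_expr_matrix(expr)
  mods <- unique(modules$module)
  if (!include_grey) mods <- setdiff(mods, "grey")
  mods <- mods[order(suppressWarnings(as.integer(sub("^M", "", mods))))]
  out <- tibble(sample_id = colnames(m))
  for (mod in mods) {
    genes <- modules$gene_id[modules$module == mod]
    out[[mod]] <- unname(module_eigengene(m[genes, , drop = FALSE]))
  }
  out
}

#' Module-trait correlation
#'
#' Pearson correlation (with two-sided p-values) between each module
#' eigengene and each trait, matched by sample. A constant trait or
#' eigengene yields `r = 0`, `p = 1` with a warning.
#'
#' @param eigengenes tibble from [module_eigengenes()] (`sample_id` +
#'   module columns).
#' @param traits tibble with `sample_id` plus one numeric column per trait;
#'   must cover exactly the eigengene samples.
#' @return tibble: `module`, `trait`, `r`, `p`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  if (!"sample_id" %in% names(traits)) abort("traits needs a sample_id column")
  if (!setequal(eigengenes$sample_id, traits$sample_id)) {
    abort("traits and eigengenes cover different samples")
  }
  traits <- traits[match(eigengenes$sample_id, traits$sample_id), ]
  mods <- setdiff(names(eigengenes), "sample_id")
  trts <- setdiff(names(traits), "sample_id")
  n <- nrow(eigengenes)
  grid <- tidyr::expand_grid(module = mods, trait = trts)
  res <- purrr::pmap(grid, function(module, trait) {
    x <- eigengenes[[module]]; y <- traits[[trait]]
    if (sd(x) == 0 || sd(y) == 0) {
      warn(sprintf("constant profile for %s/%s; correlation reported as 0",
                   module, trait))
      return(tibble(r = 0, p = 1))
    }
    r <- cor(x, y)
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    tibble(r = r, p = 2 * pt(-abs(t_stat), n - 2))
  }) |> purrr::list_rbind()
  dplyr::bind_cols(grid, res)
}

#' Run the full co-expression workflow
#'
#' Chains low-expression filtering, top-MAD gene selection, soft-threshold
#' adjacency, topological overlap, module detection, eigengene computation
#' and (optionally) module-trait correlation.
#'
#' @param expr expression tibble (`gene_id` + sample columns), typically
#'   FPKM.
#' @param n_top number of high-MAD genes to network (capped at the gene
#'   count after filtering).
#' @param power soft-thresholding exponent.
#' @param min_module_size,cut_height passed to [detect_modules()].
#' @param traits optional tibble (`sample_id` + trait columns) for
#'   module-trait correlation.
#' @param transform `"log2p1"` to network `log2(expr + 1)` (default) or
#'   `"identity"`.
#' @param min_expressed_fraction low-expression filter threshold (see
#'   [filter_low_expression()]).
#' @return object of class `coexpression_fit`: `modules` tibble,
#'   `eigengenes`, `trait_cor` (or `NULL`), and the parameters. [tidy()]
#'   returns the gene-module table, [glance()] a one-row summary.
#' @export
run_wgcna <- function(expr, n_top = 5000, power = 20,
                      min_module_size = 30, cut_height = 0.995,
                      traits = NULL,
                      transform = c("log2p1", "identity"),
                      min_expressed_fraction = 0.8) {
  transform <- match.arg(transform)
  expr <- filter_low_expression(expr, min_expressed_fraction)
  # variability is judged on the analysis scale: a raw-scale MAD would just
  # rank genes by expression level
  work <- expr
  if (transform == "log2p1") {
    m <- as_expr_matrix(expr)
    work <- as_expr_tibble(log2(m + 1))
  }
  work <- select_top_mad(work, min(n_top, nrow(work)))
  adj <- soft_adjacency(work, power = power)
  tom <- topological_overlap(adj)
  modules <- detect_modules(1 - tom, min_module_size = min_module_size,
                            cut_height = cut_height)
  eig <- module_eigengenes(work, modules)
  tc <- if (!is.null(traits) && ncol(eig) > 1) {
    module_trait_correlation(eig, traits)
  }
  structure(list(modules = modules, eigengenes = eig, trait_cor = tc,
                 power = power, n_top = nrow(expr),
                 min_module_size = min_module_size,
                 cut_height = cut_height, transform = transform),
            class = "coexpression_fit")
}

#' @export
print.coexpression_fit <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$modules$module), "grey"))
  cat(sprintf("co-expression network: %d genes, power %g, %d module(s)\n",
              nrow(x$modules), x$power, n_mod))
  print(dplyr::count(x$modules, .data$module, sort = TRUE))
  invisible(x)
}

#' @rdname run_wgcna
#' @param x a `coexpression_fit`.
#' @param ... unused.
#' @method tidy coexpression_fit
#' @export
tidy.coexpression_fit <- function(x, ...) x$modules

#' @rdname run_wgcna
#' @method glance coexpression_fit
#' @export
glance.coexpression_fit <- function(x, ...) {
  tibble(n_genes = nrow(x$modules),
         n_modules = length(setdiff(unique(x$modules$module), "grey")),
         n_grey = sum(x$modules$module == "grey"),
         power = x$power,
         min_module_size = x$min_module_size)
}
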