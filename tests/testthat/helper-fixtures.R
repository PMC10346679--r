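# Shared fixture builders; every fixture is generated in code.

# small random count table with matching lengths
tiny_counts <- function(n_genes = 20, n_samples = 6, seed = 1,
                        max_count = 500) {
  withr::with_seed(seed, {
    m <- matrix(sample.int(max_count, n_genes * n_samples, replace = TRUE),
                n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%d", seq_len(n_samples))))
    list(counts = tibble::as_tibble(cbind(
           tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))),
         lengths = tibble::tibble(gene_id = rownames(m),
                                  length = sample(500:3000, n_genes,
                                                  replace = TRUE)))
  })
}

# expression tibble with two planted correlated blocks over white noise
blocky_expression <- function(block_sizes = c(50, 50), n_noise = 0,
                              n_samples = 36, within_cor = 0.9, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    truth <- character()
    for (b in seq_along(block_sizes)) {
      z <- rnorm(n_samples)
      for (i in seq_len(block_sizes[b])) {
        rows[[length(rows) + 1]] <-
          sqrt(within_cor) * z + sqrt(1 - within_cor) * rnorm(n_samples)
        truth <- c(truth, paste0("block", b))
      }
    }
    for (i in seq_len(n_noise)) {
      rows[[length(rows) + 1]] <- rnorm(n_samples)
      truth <- c(truth, "noise")
    }
    m <- do.call(rbind, rows)
    rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    colnames(m) <- sprintf("s%02d", seq_len(n_samples))
    expr <- tibble::as_tibble(cbind(
      tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m)))
    list(expr = expr, truth = truth)
  })
}

# independent hypergeometric upper-tail oracle by exhaustive enumeration
enumerate_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # genes 1..K are "in the term"
  mean(hits >= k)
}

# independent step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
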