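test_that("top-MAD selection matches an independent MAD ranking", {
  expr <- tibble::tibble(gene_id = c("flat", "wiggly"),
                         s1 = c(5, 1), s2 = c(5, 9), s3 = c(5, 3),
                         s4 = c(5, 7))
  expect_identical(select_top_mad(expr, 1)$gene_id, "wiggly")
  expect_identical(select_top_mad(expr, 2), expr)
  expect_error(select_top_mad(expr, 3), "exceeds")

  withr::with_seed(13, {
    m <- matrix(rnorm(100 * 8), 100, 8)
    expr2 <- tibble::as_tibble(cbind(
      tibble::tibble(gene_id = sprintf("g%03d", 1:100)),
      tibble::as_tibble(m, .name_repair = "unique")))
    picked <- select_top_mad(expr2, 30)$gene_id
    oracle_mad <- apply(m, 1, function(x) {
      1.4826 * median(abs(x - median(x)))
    })
    oracle <- expr2$gene_id[order(oracle_mad, decreasing = TRUE)][1:30]
    expect_setequal(picked, oracle)
  })
})

test_that("soft adjacency is |cor|^power with unit diagonal", {
  # construct a pair with correlation exactly 0.9
  n <- 20
  withr::with_seed(44, {
    x <- scale(rnorm(n))[, 1]
    z <- rnorm(n)
    z <- scale(z - x * sum(x * z) / sum(x * x))[, 1]  # orthogonal to x
    y <- 0.9 * x + sqrt(1 - 0.81) * z
  })
  expr <- tibble::as_tibble(cbind(
    tibble::tibble(gene_id = c("a", "b", "c")),
    tibble::as_tibble(rbind(x, y, x), .name_repair = "unique")))
  adj <- soft_adjacency(expr, power = 20)
  expect_equal(adj["a", "b"], 0.9^20, tolerance = 1e-10)
  expect_equal(adj["a", "c"], 1)   # identical genes
  expect_equal(diag(adj), c(a = 1, b = 1, c = 1))

  perm <- expr[, c(1, 1 + sample(n))]
  expect_equal(unclass(soft_adjacency(perm, power = 20)), unclass(adj),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-variance genes get zero correlation with a warning", {
  expr <- tibble::tibble(gene_id = c("flat", "ok"),
                         s1 = c(1, 2), s2 = c(1, 5), s3 = c(1, 3))
  expect_warning(adj <- soft_adjacency(expr, power = 2), "zero-variance")
  expect_equal(adj["flat", "ok"], 0)
  expect_equal(diag(adj), c(flat = 1, ok = 1))
})

test_that("topological overlap matches the formula and a brute-force oracle", {
  # two genes: TOM reduces to the adjacency itself
  a2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.6, tolerance = 1e-12)

  ident <- diag(4)
  expect_equal(unique(topological_overlap(ident)[upper.tri(ident)]), 0)

  withr::with_seed(15, {
    m <- matrix(rnorm(8 * 12), 8, 12)
    adj <- abs(cor(t(m)))^4
    diag(adj) <- 1
    tom <- topological_overlap(adj)
    k <- rowSums(adj) - 1
    for (i in 1:8) {
      for (j in 1:8) {
        if (i == j) next
        l_ij <- 0
        for (u in 1:8) {
          if (u != i && u != j) l_ij <- l_ij + adj[i, u] * adj[u, j]
        }
        oracle <- (l_ij + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
        expect_equal(tom[i, j], oracle, tolerance = 1e-12)
      }
    }
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1))
  })
})

test_that("adjacency and TOM stay bounded and symmetric on random inputs", {
  withr::with_seed(16, {
    for (i in 1:5) {
      m <- matrix(rnorm(15 * 10), 15, 10)
      rownames(m) <- sprintf("g%02d", 1:15)
      adj <- soft_adjacency(tibble::as_tibble(cbind(
        tibble::tibble(gene_id = rownames(m)),
        tibble::as_tibble(m, .name_repair = "unique"))), power = sample(1:20, 1))
      expect_true(all(adj >= 0 & adj <= 1))
      expect_true(isSymmetric(unname(unclass(adj))))
      tom <- topological_overlap(adj)
      expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
      expect_true(isSymmetric(unname(tom)))
    }
  })
})

test_that("planted blocks are recovered exactly on clean data", {
  fx <- blocky_expression(c(50, 50), n_noise = 0, within_cor = 0.9,
                          seed = 18)
  adj <- soft_adjacency(fx$expr, power = 6)
  modules <- detect_modules(1 - topological_overlap(adj),
                            min_module_size = 10)
  expect_length(unique(modules$module), 2)
  expect_equal(unname(mclust::adjustedRandIndex(modules$module, fx$truth)), 1)

  # permuting gene order leaves the partition untouched
  perm <- withr::with_seed(1, sample(nrow(fx$expr)))
  modules_p <- detect_modules(
    1 - topological_overlap(soft_adjacency(fx$expr[perm, ], power = 6)),
    min_module_size = 10)
  merged <- dplyr::inner_join(modules, modules_p, by = "gene_id")
  expect_equal(unname(mclust::adjustedRandIndex(merged$module.x,
                                                merged$module.y)), 1)
})

test_that("undersized clusters become grey", {
  fx <- blocky_expression(c(8, 8), n_noise = 0, within_cor = 0.9, seed = 19)
  modules <- detect_modules(
    1 - topological_overlap(soft_adjacency(fx$expr, power = 6)),
    min_module_size = 50)
  expect_true(all(modules$module == "grey"))
})

test_that("module eigengenes summarize rank-1 structure", {
  n <- 10
  withr::with_seed(20, {
    s <- rnorm(n)
    w <- runif(6, 0.5, 2)
    m <- outer(w, s)
    rownames(m) <- sprintf("g%d", 1:6)
    colnames(m) <- sprintf("s%d", 1:n)
  })
  e <- module_eigengene(m)
  expect_equal(abs(cor(e, s)), 1, tolerance = 1e-10)
  expect_gte(cor(e, colMeans(t(scale(t(m))))), 0)  # orientation rule

  # identical profiles: the standardized common profile itself
  same <- m[c(1, 1, 1), ]
  e_same <- module_eigengene(same)
  expect_equal(abs(cor(e_same, m[1, ])), 1, tolerance = 1e-12)

  # single-gene module
  single <- module_eigengene(m[1, , drop = FALSE])
  expect_equal(unname(single), as.numeric(scale(m[1, ])), tolerance = 1e-12)
})

test_that("the eigengene matches a power-iteration oracle", {
  withr::with_seed(22, {
    m <- matrix(rnorm(20 * 10), 20, 10)
    rownames(m) <- sprintf("g%d", 1:20)
    colnames(m) <- sprintf("s%d", 1:10)
  })
  e <- module_eigengene(m)
  scaled <- t(scale(t(m)))
  cov_s <- t(scaled) %*% scaled
  v <- rep(1, 10)
  for (i in 1:500) v <- as.numeric(cov_s %*% v / sqrt(sum((cov_s %*% v)^2)))
  expect_gte(abs(cor(e, v)), 0.9999)
})

test_that("module-trait correlation is exact for aligned traits", {
  fx <- blocky_expression(c(30, 30), n_noise = 0, within_cor = 0.9,
                          seed = 25)
  adj <- soft_adjacency(fx$expr, power = 6)
  modules <- detect_modules(1 - topological_overlap(adj),
                            min_module_size = 10)
  eig <- module_eigengenes(fx$expr, modules)
  expect_identical(names(eig), c("sample_id", "M1", "M2"))

  traits <- tibble::tibble(sample_id = eig$sample_id,
                           mirror = eig$M1,
                           inverse = -eig$M2 + rnorm(nrow(eig), 0, 0.1),
                           flat = 1)
  expect_warning(expect_warning(
    tc <- module_trait_correlation(eig, traits), "constant"), "constant")
  expect_equal(tc$r[tc$module == "M1" & tc$trait == "mirror"], 1,
               tolerance = 1e-12)
  inv <- tc[tc$trait == "inverse", ]
  expect_equal(inv$module[which.min(inv$r)], "M2")
  expect_lt(min(inv$r), -0.9)
  flat <- tc[tc$trait == "flat", ]
  expect_true(all(flat$r == 0 & flat$p == 1))

  bad <- traits
  bad$sample_id[1] <- "nope"
  expect_error(module_trait_correlation(eig, bad), "different samples")
})

test_that("the full co-expression workflow recovers planted structure", {
  fx <- blocky_expression(c(40, 40), n_noise = 40, within_cor = 0.9,
                          seed = 26)
  # shift positive so the low-expression filter keeps everything
  expr <- fx$expr
  expr[-1] <- expr[-1] + 10
  w <- run_wgcna(expr, n_top = 120, power = 6, min_module_size = 15,
                 transform = "identity")
  g <- glance(w)
  expect_equal(g$n_modules, 2)
  planted <- fx$truth != "noise"
  merged <- dplyr::inner_join(tidy(w),
                              tibble::tibble(gene_id = expr$gene_id,
                                             truth = fx$truth),
                              by = "gene_id")
  in_blocks <- merged[merged$truth != "noise", ]
  expect_gte(unname(mclust::adjustedRandIndex(in_blocks$module,
                                              in_blocks$truth)), 0.9)
})
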