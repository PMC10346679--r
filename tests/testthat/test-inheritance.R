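test_that("potency ratio handles regular and degenerate cases", {
  expect_equal(potency_ratio(0, 1.5), 0)
  expect_equal(potency_ratio(3.715, 1.485), 2.502, tolerance = 1e-3)
  expect_equal(potency_ratio(1, 0), Inf)
  expect_equal(potency_ratio(-1, 0), -Inf)
  expect_equal(potency_ratio(0, 0), 0)
  expect_identical(classify_mode(potency_ratio(1, 0)), "over_dominance")
})

test_that("the classifier reproduces the published interval boundaries", {
  hp <- c(-1.21, -1.2, -0.81, -0.8, -0.21, -0.2, 0, 0.2,
          0.21, 0.8, 0.81, 1.2, 1.21, Inf, -Inf)
  want <- c("over_dominance", "over_dominance", "dominance", "dominance",
            "partial_dominance", "partial_dominance", "additive", "additive",
            "partial_dominance", "partial_dominance", "dominance",
            "dominance", "over_dominance", "over_dominance",
            "over_dominance")
  expect_identical(classify_mode(hp), want)
  expect_error(classify_mode(0, boundaries = c(0.8, 0.2, 1.2)),
               "strictly increasing")
})

test_that("the class intervals partition the extended real line", {
  grid <- c(seq(-3, 3, by = 0.01), -1.2, -0.8, -0.2, 0.2, 0.8, 1.2,
            Inf, -Inf)
  cls <- classify_mode(grid)
  expect_false(anyNA(cls))
  expect_true(all(cls %in% c("additive", "partial_dominance", "dominance",
                             "over_dominance")))
})

test_that("classification is sign symmetric away from the boundaries", {
  withr::with_seed(6, {
    hp <- runif(500, 0, 3)
    hp <- hp[apply(abs(outer(hp, c(0.2, 0.8, 1.2), "-")), 1, min) > 1e-3]
    expect_identical(classify_mode(-hp), classify_mode(hp))
  })
})

test_that("effect estimates follow their defining arithmetic", {
  eq <- estimate_effects(rep(7, 3), rep(7, 3), rep(7, 3))
  expect_equal(eq$a_hat, 0)
  expect_equal(eq$d_hat, 0)
  expect_equal(eq$mu_hat, 7)

  est <- estimate_effects(rep(10, 3), rep(6, 3), rep(9, 3))
  expect_equal(est$a_hat, 2)
  expect_equal(est$d_hat, 1)
  expect_equal(est$hp, 0.5)
  expect_equal(est$sigma2, 0)
  expect_identical(est$mode, "partial_dominance")
  expect_error(estimate_effects(1, c(1, 2), c(1, 2)), "2 replicates")
})

test_that("swapping the parents negates a and hp but keeps d and the class", {
  withr::with_seed(8, {
    for (i in 1:10) {
      p1 <- rnorm(3, 10); p2 <- rnorm(3, 7); f1 <- rnorm(3, 9)
      ab <- estimate_effects(p1, p2, f1)
      ba <- estimate_effects(p2, p1, f1)
      expect_equal(ba$a_hat, -ab$a_hat, tolerance = 1e-12)
      expect_equal(ba$d_hat, ab$d_hat, tolerance = 1e-12)
      expect_equal(ba$hp, -ab$hp, tolerance = 1e-10)
      expect_identical(ba$mode, ab$mode)
      expect_equal(ba$sigma2, ab$sigma2, tolerance = 1e-12)
    }
  })
})

test_that("noise-free fits recover planted effects exactly", {
  cfg <- trio_sim_config(n_genes = 300, library_size = 1e6, dispersion = 0,
                         sdg_shared_frac = 0, sdg_hybrid_frac = 0, seed = 17)
  sim <- simulate_trio_counts(cfg)
  # bypass counting noise: evaluate on the exact planted log2 means
  expr <- tibble::tibble(
    gene_id = sim$truth$gene_id,
    P1_r1 = 10 + sim$truth$a, P1_r2 = 10 + sim$truth$a,
    P2_r1 = 10 - sim$truth$a, P2_r2 = 10 - sim$truth$a,
    F1_r1 = 10 + sim$truth$d, F1_r2 = 10 + sim$truth$d)
  design <- tibble::tibble(
    sample_id = names(expr)[-1],
    genotype = rep(c("P1", "P2", "F1"), each = 2))
  fit <- fit_inheritance(expr, design, group_by = NULL,
                         transform = "identity")
  expect_equal(fit$effects$a_hat, sim$truth$a, tolerance = 1e-12)
  expect_equal(fit$effects$d_hat, sim$truth$d, tolerance = 1e-12)
  expect_identical(fit$effects$mode, sim$truth$class)
})

test_that("matrix fits agree with the single-gene estimator", {
  cfg <- trio_sim_config(n_genes = 40, environments = "E1",
                         timepoints = "T1", library_size = 2e5, seed = 23)
  sim <- simulate_trio_counts(cfg)
  fpkm <- compute_fpkm(sim$counts, sim$gene_lengths)
  fit <- fit_inheritance(fpkm, sim$design,
                         group_by = c("environment", "timepoint"))
  lg <- log2(as.matrix(fpkm[-1]) + 1)
  rownames(lg) <- fpkm$gene_id
  pick <- function(g) sim$design$sample_id[sim$design$genotype == g]
  for (g in c("g00003", "g00017", "g00040")) {
    single <- estimate_effects(lg[g, pick("P1")], lg[g, pick("P2")],
                               lg[g, pick("F1")])
    row <- fit$effects[fit$effects$gene_id == g, ]
    expect_equal(row$a_hat, single$a_hat, tolerance = 1e-12)
    expect_equal(row$d_hat, single$d_hat, tolerance = 1e-12)
    expect_equal(row$sigma2, single$sigma2, tolerance = 1e-10)
    expect_equal(row$se_d, single$se_d, tolerance = 1e-10)
  }
})

test_that("effect estimates are unbiased under the study conditions", {
  cfg <- trio_sim_config(n_genes = 2000, environments = "E1",
                         timepoints = "T1", dispersion = 0.1,
                         sdg_shared_frac = 0, sdg_hybrid_frac = 0,
                         seed = 29)
  sim <- simulate_trio_counts(cfg)
  fpkm <- compute_fpkm(sim$counts, sim$gene_lengths)
  fit <- fit_inheritance(fpkm, sim$design, group_by = NULL)
  expect_lt(abs(mean(fit$effects$a_hat - sim$truth$a)), 0.05)
  expect_lt(abs(mean(fit$effects$d_hat - sim$truth$d)), 0.05)
})

test_that("mode breakdowns count classes per group and sum to 100", {
  eff <- tibble::tibble(mode = classify_mode(c(0, 0.5, 1, 2)))
  bd <- mode_breakdown(eff)
  expect_equal(sort(bd$percent), rep(25, 4))

  all_add <- mode_breakdown(tibble::tibble(mode = rep("additive", 5)))
  expect_equal(all_add$percent[all_add$mode == "additive"], 100)
  expect_equal(sum(all_add$percent), 100)
  expect_equal(nrow(all_add), 4)  # empty classes still reported

  grouped <- tibble::tibble(env = rep(c("E1", "E2"), each = 4),
                            mode = classify_mode(c(0, 0, 1, 2, 0.5, 0.5, 0.5, 0.5)))
  gb <- mode_breakdown(grouped, by = "env")
  sums <- tapply(gb$percent, gb$env, sum)
  expect_equal(as.numeric(sums), c(100, 100))
  expect_error(mode_breakdown(tibble::tibble(mode = character())), "no gene")
})

test_that("the confidence-interval gate keeps clearly non-additive genes", {
  eff <- tibble::tibble(
    gene_id = c("strong", "weak"),
    a_hat = c(0.2, 1), d_hat = c(3, 1.05),
    se_a = c(0.05, 0.4), se_d = c(0.05, 0.4), df = 4)
  kept <- hp_ci_gate(eff)
  expect_identical(kept$gene_id, "strong")
})
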