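#' Configuration for the trio RNA-seq simulator
#'
#' Builds and validates the parameter set for [simulate_trio_counts()]. The
#' defaults emulate the flag-leaf study design this package targets: two
#' parents (P1, P2) and their F1 hybrid grown in two environments, sampled at
#' two timepoints with three biological replicates each, i.e.
#' 3 genotypes x 2 environments x 2 timepoints x 3 replicates = 36 libraries.
#'
#' Per-gene effects are planted on the log2-expression scale. A gene with
#' mid-parent baseline `m`, additive effect `a` and dominance effect `d` has
#' genotype means `P1 = m + a`, `P2 = m - a`, `F1 = m + d`, so the potency
#' ratio `Hp = d/a` is known exactly and classes are planted by drawing `Hp`
#' inside the interval of the requested mode of inheritance.
#'
#' @param n_genes number of genes to simulate.
#' @param n_replicates biological replicates per genotype x environment x
#'   timepoint cell.
#' @param environments,timepoints character labels for the design factors.
#' @param library_size expected total reads per library. The default 20
#'   million reads is a typical bulk RNA-seq depth.
#' @param dispersion negative-binomial dispersion `phi` in the
#'   `variance = mean + phi * mean^2` parameterization; `0` gives Poisson
#'   counts. Default 0.1, a common bulk RNA-seq magnitude.
#' @param class_proportions named proportions over the four inheritance
#'   classes (`additive`, `partial_dominance`, `dominance`,
#'   `over_dominance`); must sum to 1. The default mirrors the published
#'   early-season 1-DPA breakdown for hybrid-specific genes
#'   (22.07/41.81/10.9/25.22 percent).
#' @param effect_scale magnitude of the planted additive effect `|a|` on the
#'   log2 scale (sign is randomized per gene).
#' @param sdg_shared_frac,sdg_hybrid_frac fractions of genes given a planted
#'   timepoint shift at the second timepoint in all three genotypes
#'   (`shared`) or in the hybrid only (`hybrid`). Shifted genes are the
#'   ground truth for SDG / SDG_hp recovery; flags apply identically in
#'   every environment.
#' @param sdg_shift size of the planted timepoint shift on the log2 scale
#'   (default 2, i.e. 4-fold, leaving margin over the 2-fold DEG rule).
#' @param module_spec optional list of planted co-expression blocks, each a
#'   `list(size =, cor =)` giving the number of member genes and their
#'   within-module correlation on the log2 scale.
#' @param baseline_log2_range range of per-gene baseline log2 relative
#'   expression, drawn uniformly.
#' @param gene_length_range integer range (bp) for simulated gene lengths.
#' @param hp_max upper bound for planted `|Hp|` in the over-dominance class.
#' @param seed integer seed; identical config + seed reproduce the simulated
#'   data exactly.
#'
#' @return a validated list of class `trio_sim_config`.
#' @seealso [simulate_trio_counts()]
#' @export
trio_sim_config <- function(n_genes = 2000,
                            n_replicates = 3,
                            environments = c("E1", "E2"),
                            timepoints = c("T1", "T2"),
                            library_size = 2e7,
                            dispersion = 0.1,
                            class_proportions = c(additive = 0.2207,
                                                  partial_dominance = 0.4181,
                                                  dominance = 0.109,
                                                  over_dominance = 0.2522),
                            effect_scale = 1,
                            sdg_shared_frac = 0.02,
                            sdg_hybrid_frac = 0.02,
                            sdg_shift = 2,
                            module_spec = NULL,
                            baseline_log2_range = c(3, 10),
                            gene_length_range = c(200L, 5000L),
                            hp_max = 2.5,
                            seed = 1L) {
  if (n_genes < 1 || n_replicates < 1 || library_size < 1) {
    abort("n_genes, n_replicates and library_size must all be >= 1")
  }
  if (dispersion < 0) abort("dispersion must be nonnegative")
  classes <- c("additive", "partial_dominance", "dominance", "over_dominance")
  if (!setequal(names(class_proportions), classes)) {
    abort("class_proportions must be named with the four inheritance classes")
  }
  class_proportions <- class_proportions[classes]
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    abort("class_proportions must be nonnegative and sum to 1 (tolerance 1e-9)")
  }
  if (effect_scale <= 0) abort("effect_scale must be positive")
  if (sdg_shared_frac < 0 || sdg_hybrid_frac < 0 ||
      sdg_shared_frac + sdg_hybrid_frac > 1) {
    abort("sdg fractions must be nonnegative and sum to at most 1")
  }
  if (hp_max <= 1.2) abort("hp_max must exceed 1.2 (the over-dominance bound)")
  if (length(environments) < 1 || length(timepoints) < 1) {
    abort("at least one environment and one timepoint are required")
  }
  if (!is.null(module_spec)) {
    ok <- vapply(module_spec, function(m) {
      is.list(m) && all(c("size", "cor") %in% names(m)) &&
        m$size >= 1 && m$cor >= 0 && m$cor <= 1
    }, logical(1))
    if (!all(ok)) abort("each module_spec entry needs size >= 1 and cor in [0, 1]")
    if (sum(vapply(module_spec, `[[`, numeric(1), "size")) > n_genes) {
      abort("module_spec sizes exceed n_genes")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_replicates = as.integer(n_replicates),
         environments = as.character(environments),
         timepoints = as.character(timepoints),
         library_size = library_size,
         dispersion = dispersion,
         class_proportions = class_proportions,
         effect_scale = effect_scale,
         sdg_shared_frac = sdg_shared_frac,
         sdg_hybrid_frac = sdg_hybrid_frac,
         sdg_shift = sdg_shift,
         module_spec = module_spec,
         baseline_log2_range = baseline_log2_range,
         gene_length_range = as.integer(gene_length_range),
         hp_max = hp_max,
         seed = as.integer(seed)),
    class = "trio_sim_config"
  )
}

# deterministic class sizes by largest remainder, then shuffled over genes
plant_classes <- function(n, proportions) {
  raw <- proportions * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(names(proportions), times = base))
}

# draw a potency ratio inside the class's interval (open at the boundary
# points, so the planted class always agrees with classify_mode())
plant_hp <- function(class, hp_max) {
  n <- length(class)
  lo <- c(additive = 0, partial_dominance = 0.2,
          dominance = 0.8, over_dominance = 1.2)[class]
  hi <- c(additive = 0.2, partial_dominance = 0.8,
          dominance = 1.2, over_dominance = hp_max)[class]
  mag <- runif(n, lo, hi)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  ifelse(class == "additive", runif(n, -0.2, 0.2), mag * sgn)
}

#' Simulate a parent/parent/hybrid RNA-seq count experiment with known truth
#'
#' Generates a gene x sample count table, a gene-length table, the sample
#' design sheet, and a truth table recording every planted quantity: the
#' additive effect `a`, dominance effect `d`, potency ratio `Hp`, the
#' inheritance class implied by `Hp`, planted co-expression module
#' membership, and SDG / SDG_hp ground-truth flags.
#'
#' Counts are drawn from a negative binomial with
#' `variance = mean + dispersion * mean^2` (Poisson when `dispersion = 0`).
#' Expected counts within each library are the planted log2 means converted
#' back to the natural scale and rescaled so every library's expected total
#' equals `library_size`.
#'
#' @param config a [trio_sim_config()].
#' @return an object of class `trio_sim`: a list with tibbles `counts`
#'   (`gene_id` + one column per sample), `gene_lengths` (`gene_id`,
#'   `length`), `design` (`sample_id`, `genotype`, `environment`,
#'   `timepoint`, `replicate`) and `truth` (`gene_id`, `class`, `a`, `d`,
#'   `hp`, `module`, `is_sdg`, `is_sdg_hp`), plus the `config`.
#' @examples
#' sim <- simulate_trio_counts(trio_sim_config(n_genes = 100, seed = 7))
#' dim(sim$counts)
#' dplyr::count(sim$truth, class)
#' @export
simulate_trio_counts <- function(config = trio_sim_config()) {
  if (!inherits(config, "trio_sim_config")) {
    config <- do.call(trio_sim_config, config)
  }
  withr::with_seed(config$seed, {
    n <- config$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    lengths <- sample(seq(config$gene_length_range[1],
                          config$gene_length_range[2]), n, replace = TRUE)

    class <- plant_classes(n, config$class_proportions)
    hp <- plant_hp(class, config$hp_max)
    a <- config$effect_scale * sample(c(-1, 1), n, replace = TRUE)
    d <- hp * a
    class <- as.character(classify_mode(hp))  # exact truth consistency

    m <- runif(n, config$baseline_log2_range[1], config$baseline_log2_range[2])

    n_shared <- round(config$sdg_shared_frac * n)
    n_hybrid <- round(config$sdg_hybrid_frac * n)
    shifted <- sample(n, n_shared + n_hybrid)
    is_sdg <- seq_len(n) %in% shifted[seq_len(n_shared)]
    is_sdg_hp <- seq_len(n) %in% shifted[setdiff(seq_along(shifted),
                                                 seq_len(n_shared))]

    module <- rep(NA_character_, n)
    if (!is.null(config$module_spec)) {
      sizes <- vapply(config$module_spec, `[[`, numeric(1), "size")
      members <- sample(n, sum(sizes))
      module[members] <- rep(sprintf("M%d", seq_along(sizes)), times = sizes)
    }

    design <- tidyr::expand_grid(
      genotype = c("P1", "P2", "F1"),
      environment = config$environments,
      timepoint = config$timepoints,
      replicate = seq_len(config$n_replicates)
    )
    design <- dplyr::mutate(
      design,
      sample_id = paste(.data$genotype, .data$environment, .data$timepoint,
                        paste0("r", .data$replicate), sep = "_"),
      .before = 1
    )

    geno_eff <- cbind(P1 = a, P2 = -a, F1 = d)
    counts <- matrix(0L, n, nrow(design),
                     dimnames = list(gene_id, design$sample_id))
    t2 <- config$timepoints[min(2, length(config$timepoints))]

    # per-sample latent factors for planted co-expression blocks
    mod_ids <- unique(module[!is.na(module)])
    mod_cor <- if (length(mod_ids)) {
      setNames(vapply(config$module_spec, `[[`, numeric(1), "cor"),
               sprintf("M%d", seq_along(config$module_spec)))
    }

    for (j in seq_len(nrow(design))) {
      s <- design[j, ]
      lmu <- m + geno_eff[, s$genotype]
      if (length(config$timepoints) > 1 && s$timepoint == t2) {
        shift_here <- is_sdg | (is_sdg_hp & s$genotype == "F1")
        lmu <- lmu + config$sdg_shift * shift_here
      }
      if (length(mod_ids)) {
        z <- rnorm(length(mod_ids))
        names(z) <- mod_ids
        in_mod <- !is.na(module)
        rho <- mod_cor[module[in_mod]]
        lmu[in_mod] <- lmu[in_mod] + sqrt(rho) * z[module[in_mod]] +
          sqrt(1 - rho) * rnorm(sum(in_mod))
      }
      rel <- 2^lmu
      mu <- rel / sum(rel) * config$library_size
      counts[, j] <- if (config$dispersion == 0) {
        rpois(n, mu)
      } else {
        rnbinom(n, mu = mu, size = 1 / config$dispersion)
      }
    }

    structure(
      list(counts = as_expr_tibble(counts),
           gene_lengths = tibble(gene_id = gene_id, length = lengths),
           design = design,
           truth = tibble(gene_id = gene_id, class = class, a = a, d = d,
                          hp = hp, module = module, is_sdg = is_sdg,
                          is_sdg_hp = is_sdg_hp),
           config = config),
      class = "trio_sim"
    )
  })
}

#' @export
print.trio_sim <- function(x, ...) {
  cat(sprintf("trio simulation: %d genes x %d libraries (seed %d)\n",
              nrow(x$counts), nrow(x$design), x$config$seed))
  cat(sprintf("  dispersion %.3g, library size %.3g, |a| = %.3g\n",
              x$config$dispersion, x$config$library_size,
              x$config$effect_scale))
  print(dplyr::count(x$truth, .data$class))
  invisible(x)
}

#' Simulate replicate-level phenotype records
#'
#' Draws normal replicate values around specified genotype means, producing a
#' long phenotype table compatible with [heterosis_table()].
#'
#' @param specs a data frame with one row per trait x genotype cell and
#'   columns `trait`, `genotype`, `mean`, `sd`, `n`; any further columns
#'   (e.g. `environment`, `timepoint`) are carried through.
#' @param seed integer seed.
#' @return a tibble with the input columns plus `replicate` and `value`.
#' @examples
#' specs <- tibble::tibble(trait = "leaf_length",
#'                         genotype = c("P1", "P2", "F1"),
#'                         mean = c(28.17, 25.2, 30.4), sd = 1.5, n = 3)
#' simulate_phenotypes(specs, seed = 1)
#' @export
simulate_phenotypes <- function(specs, seed = 1L) {
  need <- c("trait", "genotype", "mean", "sd", "n")
  if (!all(need %in% names(specs))) {
    abort(paste("specs must have columns", paste(need, collapse = ", ")))
  }
  if (any(specs$sd < 0)) abort("sd must be nonnegative")
  if (any(specs$n < 1)) abort("n must be >= 1")
  withr::with_seed(as.integer(seed), {
    out <- specs |>
      dplyr::rowwise() |>
      dplyr::reframe(dplyr::across(dplyr::everything()),
                     replicate = seq_len(.data$n),
                     value = rnorm(.data$n, .data$mean, .data$sd))
    as_tibble(out)
  })
}

#' Simulate a GMT-style annotation with one planted enriched term
#'
#' Builds random term -> gene-set annotations over a gene universe, with one
#' designated term constructed to overlap a target gene set at a configured
#' rate, so over-representation analysis can be validated against known
#' truth.
#'
#' @param genes character vector of universe gene identifiers, or a single
#'   integer (the universe size, ids are generated).
#' @param n_terms number of random background terms.
#' @param term_size_range integer range of term sizes (within
#'   `[1, length(genes)]`).
#' @param enriched_term id of the planted term; `NULL` to skip planting.
#' @param target_set character vector of genes the planted term must overlap.
#' @param overlap_rate fraction of the planted term drawn from `target_set`.
#' @param seed integer seed.
#' @return an annotation tibble with columns `term`, `description` and a
#'   list-column `genes`, as read by [read_gmt()].
#' @examples
#' ann <- simulate_annotation(100, n_terms = 10, target_set = sprintf("g%05d", 1:20))
#' ann
#' @export
simulate_annotation <- function(genes, n_terms = 50,
                                term_size_range = c(10, 50),
                                enriched_term = "T_planted",
                                target_set = NULL,
                                overlap_rate = 1,
                                seed = 1L) {
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- sprintf("g%05d", seq_len(genes))
  }
  if (length(genes) == 0) abort("the gene universe must be nonempty")
  if (term_size_range[1] < 1 || term_size_range[2] > length(genes)) {
    abort("term sizes must lie within [1, number of genes]")
  }
  if (overlap_rate < 0 || overlap_rate > 1) {
    abort("overlap_rate must lie in [0, 1]")
  }
  withr::with_seed(as.integer(seed), {
    size_pool <- seq(term_size_range[1], term_size_range[2])
    sizes <- if (length(size_pool) == 1) {
      rep(size_pool, n_terms)
    } else {
      sample(size_pool, n_terms, replace = TRUE)
    }
    out <- tibble(
      term = sprintf("T%03d", seq_len(n_terms)),
      description = sprintf("random term %d", seq_len(n_terms)),
      genes = map(sizes, ~ sample(genes, .x))
    )
    if (!is.null(enriched_term) && !is.null(target_set)) {
      size <- min(max(term_size_range), max(min(term_size_range),
                                            length(target_set)))
      k <- round(overlap_rate * min(size, length(target_set)))
      filler <- setdiff(genes, target_set)
      planted <- c(sample(target_set, k),
                   if (size > k) sample(filler, size - k))
      out <- dplyr::bind_rows(
        tibble(term = enriched_term, description = "planted enriched term",
               genes = list(planted)),
        out
      )
    }
    out
  })
}
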