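#' Pipeline configuration
#'
#' Collects and validates paths, thresholds and tuning parameters for
#' [run_pipeline()]. Thresholds default to the source study's rules
#' (|log2 ratio| >= 1 with DEG FDR <= 0.005, enrichment FDR <= 0.05,
#' potency-ratio class boundaries 0.2 / 0.8 / 1.2, top 5000 MAD genes at
#' soft power 20).
#'
#' @param out_dir output directory for all written artifacts.
#' @param counts,gene_lengths,sample_design,phenotypes,annotation input
#'   file paths (TSV / GMT); any may be `NULL` when the corresponding stage
#'   is not run or when `sim` provides the data.
#' @param sim optional [trio_sim_config()]; the `simulate` stage writes its
#'   data into `out_dir` and downstream stages use them.
#' @param lfc_min,fdr_deg,fdr_enrich,hp_boundaries,top_n,power,
#'   min_module_size,cut_height,min_expressed_fraction,deg_method tuning
#'   parameters, see the stage functions.
#' @param seed integer seed echoed to the simulator and the log.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            counts = NULL, gene_lengths = NULL,
                            sample_design = NULL, phenotypes = NULL,
                            annotation = NULL, sim = NULL,
                            lfc_min = 1, fdr_deg = 0.005, fdr_enrich = 0.05,
                            hp_boundaries = c(0.2, 0.8, 1.2),
                            top_n = 5000, power = 20,
                            min_module_size = 30, cut_height = NULL,
                            min_expressed_fraction = 0.8,
                            deg_method = "exact_nb",
                            seed = 1L) {
  if (missing(out_dir) || !nzchar(out_dir)) abort("out_dir is required")
  if (lfc_min <= 0 || fdr_deg <= 0 || fdr_enrich <= 0) {
    abort("thresholds must be positive")
  }
  if (length(hp_boundaries) != 3 || any(diff(hp_boundaries) <= 0) ||
      hp_boundaries[1] <= 0) {
    abort("hp_boundaries must be three strictly increasing positive values")
  }
  for (p in c(counts, gene_lengths, sample_design, phenotypes, annotation)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("input file does not exist: %s", p))
    }
  }
  if (!is.null(sim) && !inherits(sim, "trio_sim_config")) {
    abort("sim must be a trio_sim_config()")
  }
  structure(list(out_dir = out_dir, counts = counts,
                 gene_lengths = gene_lengths, sample_design = sample_design,
                 phenotypes = phenotypes, annotation = annotation, sim = sim,
                 lfc_min = lfc_min, fdr_deg = fdr_deg,
                 fdr_enrich = fdr_enrich, hp_boundaries = hp_boundaries,
                 top_n = top_n, power = power,
                 min_module_size = min_module_size, cut_height = cut_height,
                 min_expressed_fraction = min_expressed_fraction,
                 deg_method = deg_method, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the trio heterosis pipeline
#'
#' Executes the analysis stages in order and writes each stage's tabular
#' artifacts under `config$out_dir`. Stages:
#'
#' * `simulate` — generate trio data from `config$sim` and write them.
#' * `deg` / `sets` — timepoint DEG contrasts per genotype x environment,
#'   SDG / SDG_hp / SSDG_hp sets and Venn counts.
#' * `heterosis` — trait-level MPH/HPH table from the phenotype file.
#' * `inheritance` — per-gene effects and the mode-of-inheritance
#'   breakdown over the hybrid-specific genes per environment x timepoint.
#' * `wgcna` — co-expression modules and eigengenes.
#' * `enrich` — over-representation of the SSDG_hp set (falling back to
#'   the per-environment SDG_hp union when only one environment exists).
#'
#' A `pipeline.log` records package version, seed and configuration.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages, or `"all"`.
#' @return named list of the in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (!inherits(config, "pipeline_config")) {
    abort("config must come from pipeline_config()")
  }
  all_stages <- c("simulate", "deg", "heterosis", "inheritance", "sets",
                  "wgcna", "enrich")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_lines <- c(
    sprintf("triohet %s", as.character(packageVersion("triohet"))),
    sprintf("seed: %d", config$seed),
    sprintf("stages: %s", paste(stages, collapse = ", ")),
    "config:",
    paste0("  ", utils::capture.output(utils::str(
      config[setdiff(names(config), "sim")], give.attr = FALSE)))
  )
  out <- list()

  counts <- lengths_tbl <- design <- NULL
  load_counts <- function() {
    if (!is.null(out$simulate)) {
      counts <<- out$simulate$counts
      lengths_tbl <<- out$simulate$gene_lengths
      design <<- out$simulate$design
    } else {
      if (is.null(config$counts) || is.null(config$gene_lengths) ||
          is.null(config$sample_design)) {
        abort("counts, gene_lengths and sample_design paths are required")
      }
      counts <<- read_counts(config$counts)
      lengths_tbl <<- read_gene_lengths(config$gene_lengths)
      design <<- read_sample_design(config$sample_design)
    }
  }

  if ("simulate" %in% stages) {
    sim_cfg <- config$sim %||% trio_sim_config(seed = config$seed)
    out$simulate <- simulate_trio_counts(sim_cfg)
    write_trio_sim(out$simulate, config$out_dir)
  }

  if (any(c("deg", "sets", "inheritance", "enrich") %in% stages)) {
    load_counts()
    out$sets <- sdg_analysis(counts, lengths_tbl, design,
                             method = config$deg_method,
                             lfc_min = config$lfc_min,
                             fdr_max = config$fdr_deg)
    readr::write_tsv(out$sets$deg, file.path(config$out_dir, "deg.tsv"))
    readr::write_tsv(tidy(out$sets),
                     file.path(config$out_dir, "gene_sets.tsv"))
    for (env in names(out$sets$sdg_hp)) {
      vc <- venn_counts(list(
        F1 = out$sets$sdg[[paste0("F1@", env)]],
        P1 = out$sets$sdg[[paste0("P1@", env)]],
        P2 = out$sets$sdg[[paste0("P2@", env)]]))
      jsonlite::write_json(
        vc, file.path(config$out_dir, sprintf("venn_%s.json", env)),
        auto_unbox = TRUE, digits = NA)
    }
  }

  if ("heterosis" %in% stages) {
    ph <- if (!is.null(config$phenotypes)) {
      readr::read_tsv(config$phenotypes, show_col_types = FALSE)
    } else {
      abort("the heterosis stage needs a phenotypes file")
    }
    out$heterosis <- heterosis_table(ph)
    readr::write_tsv(out$heterosis,
                     file.path(config$out_dir, "heterosis.tsv"))
  }

  if ("inheritance" %in% stages) {
    fpkm <- compute_fpkm(counts, lengths_tbl)
    fit <- fit_inheritance(fpkm, design)
    hp_genes <- unique(unlist(out$sets$sdg_hp, use.names = FALSE))
    eff <- fit$effects
    if (length(hp_genes)) {
      eff <- dplyr::filter(eff, .data$gene_id %in% hp_genes)
    }
    bd <- mode_breakdown(eff, by = fit$group_by)
    out$inheritance <- list(fit = fit, breakdown = bd)
    readr::write_tsv(fit$effects,
                     file.path(config$out_dir, "gene_effects.tsv"))
    readr::write_tsv(bd, file.path(config$out_dir, "mode_breakdown.tsv"))
  }

  if ("wgcna" %in% stages) {
    if (is.null(counts)) load_counts()
    fpkm <- compute_fpkm(counts, lengths_tbl)
    out$wgcna <- run_wgcna(
      fpkm, n_top = config$top_n, power = config$power,
      min_module_size = config$min_module_size,
      cut_height = config$cut_height %||% 0.995,
      min_expressed_fraction = config$min_expressed_fraction)
    readr::write_tsv(out$wgcna$modules,
                     file.path(config$out_dir, "modules.tsv"))
    readr::write_tsv(out$wgcna$eigengenes,
                     file.path(config$out_dir, "eigengenes.tsv"))
    if (!is.null(out$wgcna$trait_cor)) {
      readr::write_tsv(out$wgcna$trait_cor,
                       file.path(config$out_dir, "module_trait.tsv"))
    }
  }

  if ("enrich" %in% stages) {
    if (is.null(config$annotation)) {
      abort("the enrich stage needs an annotation (GMT) file")
    }
    ann <- read_gmt(config$annotation)
    query <- if (length(out$sets$ssdg_hp)) {
      out$sets$ssdg_hp
    } else {
      unique(unlist(out$sets$sdg_hp, use.names = FALSE))
    }
    universe <- intersect(unique(unlist(ann$genes, use.names = FALSE)),
                          counts$gene_id)
    out$enrich <- hypergeom_enrich(query, ann, universe = universe)
    readr::write_tsv(out$enrich,
                     file.path(config$out_dir, "enrichment.tsv"))
  }

  writeLines(log_lines, log_path)
  invisible(out)
}
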