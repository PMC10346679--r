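#' Temporal significant-difference gene set (SDG)
#'
#' An SDG set is the union of the up- and down-regulated DEG sets of the
#' timepoint contrast (e.g. 1 DPA vs 10 DPA) for one genotype in one
#' environment.
#'
#' @param up,down disjoint character vectors of gene ids from [call_degs()].
#' @return character vector (the union).
#' @export
sdg <- function(up, down) {
  if (length(intersect(up, down))) {
    abort("up and down DEG sets must be disjoint")
  }
  union(up, down)
}

#' Hybrid-specific SDG set (SDG_hp)
#'
#' Genes with a significant temporal response in the hybrid but in neither
#' parent: `sdg_f1 \ (sdg_p1 U sdg_p2)`. Exclusion uses the union of the
#' parents (the strict reading of "hybrid-specific").
#'
#' @param sdg_f1,sdg_p1,sdg_p2 SDG sets of hybrid and parents.
#' @return character vector.
#' @export
sdg_hp <- function(sdg_f1, sdg_p1, sdg_p2) {
  setdiff(sdg_f1, union(sdg_p1, sdg_p2))
}

#' Environment-shared hybrid-specific set (SSDG_hp)
#'
#' The SDG_hp genes common to both growing environments.
#'
#' @param sdg_hp_env1,sdg_hp_env2 SDG_hp sets of the two environments.
#' @return character vector (the intersection).
#' @export
ssdg_hp <- function(sdg_hp_env1, sdg_hp_env2) {
  intersect(sdg_hp_env1, sdg_hp_env2)
}

#' Three-way Venn region counts
#'
#' Counts the seven disjoint regions of a three-set Venn diagram; region
#' counts always sum to the size of the union.
#'
#' @param sets named list of exactly three character vectors.
#' @return tibble with one logical membership column per set and the region
#'   `count`, one row per nonempty-signature region (7 rows).
#' @examples
#' venn_counts(list(A = c("a", "b"), B = c("b"), C = c("c")))
#' @export
venn_counts <- function(sets) {
  if (length(sets) != 3) abort("exactly three sets are required")
  nms <- names(sets) %||% c("A", "B", "C")
  if (any(!nzchar(nms))) abort("sets must be named")
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- do.call(cbind, lapply(sets, function(s) universe %in% s))
  colnames(member) <- nms
  grid <- tidyr::expand_grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                             c = c(TRUE, FALSE))
  names(grid) <- nms
  grid <- dplyr::filter(grid, dplyr::if_any(dplyr::everything()))
  grid$count <- vapply(seq_len(nrow(grid)), function(i) {
    sig <- unlist(grid[i, nms])
    sum(apply(member, 1, function(r) all(r == sig)))
  }, numeric(1))
  grid
}

#' Derive SDG / SDG_hp / SSDG_hp sets from a trio count experiment
#'
#' Runs the timepoint DEG contrast for every genotype x environment cell,
#' forms each cell's SDG set, derives the hybrid-specific SDG_hp set per
#' environment and, when two or more environments are present, their
#' intersection SSDG_hp.
#'
#' @param counts raw count tibble (`gene_id` + sample columns).
#' @param gene_lengths tibble with `gene_id`, `length`.
#' @param design design tibble (`sample_id`, `genotype`, `environment`,
#'   `timepoint`).
#' @param timepoints length-2 character: the contrasted timepoints (first
#'   vs second).
#' @param method,lfc_min,fdr_max passed to [test_differential()] /
#'   [call_degs()].
#' @return an object of class `sdg_analysis`: list with `deg` (all DEG
#'   tables, row-bound with `genotype` and `environment` columns), `sdg`
#'   (named list, `genotype@environment`), `sdg_hp` (named list per
#'   environment) and `ssdg_hp` (character vector). [tidy()] returns a long
#'   membership table.
#' @export
sdg_analysis <- function(counts, gene_lengths, design,
                         timepoints = NULL,
                         method = "exact_nb",
                         lfc_min = 1, fdr_max = 0.005) {
  need <- c("sample_id", "genotype", "environment", "timepoint")
  if (!all(need %in% names(design))) {
    abort(paste("design needs columns", paste(need, collapse = ", ")))
  }
  timepoints <- timepoints %||% sort(unique(design$timepoint))
  if (length(timepoints) != 2) {
    abort("exactly two timepoints must be contrasted")
  }
  envs <- sort(unique(design$environment))
  genos <- c("P1", "P2", "F1")

  deg <- list(); sdg_sets <- list()
  for (env in envs) {
    for (g in genos) {
      pick <- function(tp) {
        design$sample_id[design$genotype == g &
                           design$environment == env &
                           design$timepoint == tp]
      }
      res <- test_differential(counts, gene_lengths,
                               group_a = pick(timepoints[1]),
                               group_b = pick(timepoints[2]),
                               method = method,
                               lfc_min = lfc_min, fdr_max = fdr_max)
      key <- paste0(g, "@", env)
      deg[[key]] <- dplyr::mutate(res, genotype = g, environment = env,
                                  .before = 1)
      sets <- call_degs(res, lfc_min = lfc_min, fdr_max = fdr_max)
      sdg_sets[[key]] <- sdg(sets$up, sets$down)
    }
  }
  sdg_hp_sets <- lapply(setNames(envs, envs), function(env) {
    sdg_hp(sdg_sets[[paste0("F1@", env)]],
           sdg_sets[[paste0("P1@", env)]],
           sdg_sets[[paste0("P2@", env)]])
  })
  shared <- if (length(envs) >= 2) {
    Reduce(intersect, sdg_hp_sets)
  } else character()

  structure(list(deg = purrr::list_rbind(deg), sdg = sdg_sets,
                 sdg_hp = sdg_hp_sets, ssdg_hp = shared,
                 timepoints = timepoints,
                 lfc_min = lfc_min, fdr_max = fdr_max),
            class = "sdg_analysis")
}

#' @export
print.sdg_analysis <- function(x, ...) {
  cat(sprintf("SDG analysis (%s vs %s; |log2 ratio| >= %g, FDR <= %g)\n",
              x$timepoints[1], x$timepoints[2], x$lfc_min, x$fdr_max))
  for (k in names(x$sdg)) cat(sprintf("  SDG %-8s %d genes\n", k,
                                      length(x$sdg[[k]])))
  for (k in names(x$sdg_hp)) cat(sprintf("  SDG_hp@%-5s %d genes\n", k,
                                         length(x$sdg_hp[[k]])))
  cat(sprintf("  SSDG_hp     %d genes\n", length(x$ssdg_hp)))
  invisible(x)
}

#' @rdname sdg_analysis
#' @param x an `sdg_analysis`.
#' @param ... unused.
#' @method tidy sdg_analysis
#' @export
tidy.sdg_analysis <- function(x, ...) {
  sets <- c(x$sdg,
            setNames(x$sdg_hp, paste0("SDG_hp@", names(x$sdg_hp))),
            list(SSDG_hp = x$ssdg_hp))
  purrr::imap(sets, ~ tibble(set = .y, gene_id = .x)) |>
    purrr::list_rbind()
}

#' @rdname sdg_analysis
#' @method glance sdg_analysis
#' @export
glance.sdg_analysis <- function(x, ...) {
  tibble(n_sdg_sets = length(x$sdg),
         n_sdg_hp = lengths(x$sdg_hp) |> sum(),
         n_ssdg_hp = length(x$ssdg_hp))
}
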