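#' Mid-parent value
#'
#' @param p1_mean,p2_mean parental trait means (vectorized).
#' @return `(p1_mean + p2_mean) / 2`.
#' @export
mid_parent <- function(p1_mean, p2_mean) (p1_mean + p2_mean) / 2

#' Mid-parent heterosis (percent)
#'
#' `MPH = 100 * (F1 - MP) / MP` where `MP` is the mid-parent value.
#'
#' @param p1_mean,p2_mean,f1_mean trait means (vectorized).
#' @return percent deviation of the hybrid from the parental average.
#' @examples
#' mph(28.17, 25.2, 30.4)  # early-season flag-leaf length: 13.9%
#' @export
mph <- function(p1_mean, p2_mean, f1_mean) {
  mp <- mid_parent(p1_mean, p2_mean)
  if (any(mp == 0, na.rm = TRUE)) abort("mid-parent value is zero")
  100 * (f1_mean - mp) / mp
}

#' High-parent heterosis (percent)
#'
#' `HPH = 100 * (F1 - BP) / BP` where `BP` is the better (larger-mean)
#' parent, regardless of which direction is agronomically desirable — this
#' is what reproduces negative published HPH entries.
#'
#' @inheritParams mph
#' @return percent deviation of the hybrid from the better parent.
#' @examples
#' hph(28.17, 25.2, 30.4)  # 7.9%
#' @export
hph <- function(p1_mean, p2_mean, f1_mean) {
  bp <- pmax(p1_mean, p2_mean)
  if (any(bp == 0, na.rm = TRUE)) abort("better-parent value is zero")
  100 * (f1_mean - bp) / bp
}

#' Significance of mid- and high-parent heterosis
#'
#' Welch t-tests of the hybrid replicates against (i) per-replicate-pair
#' mid-parent values `(P1_i + P2_i) / 2` and (ii) the better parent's
#' replicates. Flags follow the usual convention: `**` for p < 0.01, `*`
#' for p < 0.05.
#'
#' @param p1,p2,f1 numeric replicate vectors (>= 2 each; the parents must
#'   have equally many replicates so they can be paired).
#' @return one-row tibble: `mph_p`, `hph_p`, `mph_flag`, `hph_flag`.
#' @export
heterosis_significance <- function(p1, p2, f1) {
  if (min(length(p1), length(p2), length(f1)) < 2) {
    abort("at least 2 replicates per genotype are required")
  }
  if (length(p1) != length(p2)) {
    abort("parental replicates must be paired (equal counts)")
  }
  mid <- (p1 + p2) / 2
  better <- if (mean(p1) >= mean(p2)) p1 else p2
  mph_p <- welch_p(f1, mid)
  hph_p <- welch_p(f1, better)
  tibble(mph_p = mph_p, hph_p = hph_p,
         mph_flag = signif_flag(mph_p), hph_flag = signif_flag(hph_p))
}

#' Trait-level heterosis table
#'
#' Computes MPH and HPH (with significance when replicate-level data are
#' available) for every trait cell of a long phenotype table, reproducing
#' the layout of a published phenotype/heterosis table.
#'
#' @param phenotypes long tibble with columns `trait`, `genotype` (coded
#'   `P1`, `P2`, `F1`) and either `value` (replicate-level) or `mean`
#'   (summary-level); optional `environment` and `timepoint` columns define
#'   extra cells.
#' @return tibble with one row per trait cell: genotype means, `mph`, `hph`,
#'   and (replicate data only) `mph_p`, `hph_p` and significance flags.
#' @examples
#' ph <- tibble::tibble(trait = "leaf_length",
#'                      genotype = c("P1", "P2", "F1"),
#'                      mean = c(28.17, 25.2, 30.4))
#' heterosis_table(ph)
#' @export
heterosis_table <- function(phenotypes) {
  if (!all(c("trait", "genotype") %in% names(phenotypes))) {
    abort("phenotypes needs 'trait' and 'genotype' columns")
  }
  has_reps <- "value" %in% names(phenotypes)
  if (!has_reps && !"mean" %in% names(phenotypes)) {
    abort("phenotypes needs a 'value' (replicates) or 'mean' column")
  }
  if (!all(phenotypes$genotype %in% c("P1", "P2", "F1"))) {
    abort("genotype must be coded P1, P2, F1")
  }
  keys <- intersect(c("trait", "environment", "timepoint"), names(phenotypes))

  one_cell <- function(df, key) {
    split_g <- split(if (has_reps) df$value else df$mean, df$genotype)
    if (!all(c("P1", "P2", "F1") %in% names(split_g))) {
      abort(sprintf("trait cell '%s' is missing a genotype",
                    paste(unlist(key), collapse = "/")))
    }
    means <- vapply(split_g, mean, numeric(1))
    out <- tibble(p1_mean = means[["P1"]], p2_mean = means[["P2"]],
                  f1_mean = means[["F1"]],
                  mph = mph(means[["P1"]], means[["P2"]], means[["F1"]]),
                  hph = hph(means[["P1"]], means[["P2"]], means[["F1"]]))
    if (has_reps && min(lengths(split_g)) >= 2 &&
        length(split_g$P1) == length(split_g$P2)) {
      out <- dplyr::bind_cols(
        out, heterosis_significance(split_g$P1, split_g$P2, split_g$F1))
    } else {
      out <- dplyr::mutate(out, mph_p = NA_real_, hph_p = NA_real_,
                           mph_flag = NA_character_, hph_flag = NA_character_)
    }
    out
  }

  phenotypes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(one_cell) |>
    dplyr::ungroup()
}

#' Published flag-leaf phenotype table of the WFYT025 trio
#'
#' The packaged phenotype fixture: flag-leaf length, width, area and
#' 1000-grain/spikelet weight of the hybrid rice WFYT025 (`F1`), its female
#' parent WFB (`P1`) and male parent CHT025 (`P2`), at 1 and 10 days
#' post-anthesis in the early- and middle-season environments, together with
#' the published MPH/HPH percentages and significance flags.
#'
#' Two printed entries disagree with the printed genotype means by more than
#' rounding can explain and carry a `note`: the early-season 10-DPA TGW MPH
#' (printed 2.81, recomputed 3.05) and the early-season 10-DPA leaf-area HPH
#' (printed 0.1, recomputed 0.95).
#'
#' @param long if `TRUE`, return the replicate-free long format expected by
#'   [heterosis_table()] (one row per genotype with a `mean` column) instead
#'   of the wide published layout.
#' @return a tibble; wide format has columns `environment`, `timepoint`,
#'   `trait`, genotype means (`p1_mean`, `p2_mean`, `f1_mean`) with
#'   standard deviations where published, printed `mph_printed`,
#'   `mph_flag`, `hph_printed`, `hph_flag`, and `note`.
#' @export
flag_leaf_traits <- function(long = FALSE) {
  path <- system.file("extdata", "flag_leaf_traits.tsv", package = "triohet")
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  if (!long) return(wide)
  wide |>
    dplyr::select(dplyr::all_of(c("environment", "timepoint", "trait",
                                  "p1_mean", "p2_mean", "f1_mean"))) |>
    tidyr::pivot_longer(dplyr::all_of(c("p1_mean", "p2_mean", "f1_mean")),
                        names_to = "genotype", values_to = "mean") |>
    dplyr::mutate(genotype = toupper(sub("_mean", "", .data$genotype)))
}
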