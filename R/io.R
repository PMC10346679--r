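# Plain-text readers/writers for the pipeline's tabular artifacts. All
# tables are tab-separated with a header row; annotations use the GMT
# convention (term, description, then one gene id per field).

#' Read / write a gene x sample count or expression table
#'
#' TSV with a `gene_id` column followed by one numeric column per sample.
#'
#' @param path file path.
#' @param x table to write.
#' @return `read_counts()` returns a tibble; `write_counts()` returns `path`
#'   invisibly.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene_id = "c", .default = "d"))
}

#' @rdname read_counts
#' @export
write_counts <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a gene-length table
#'
#' TSV with columns `gene_id` and `length` (bp).
#'
#' @param path file path.
#' @return tibble.
#' @export
read_gene_lengths <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene_id = "c", length = "d"))
}

#' Read a sample design sheet
#'
#' TSV with columns `sample_id`, `genotype`, `environment`, `timepoint`,
#' `replicate`.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_sample_design <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "genotype", "environment", "timepoint", "replicate")
  if (!all(need %in% names(x))) {
    abort(paste("sample sheet must have columns",
                paste(need, collapse = ", ")))
  }
  x
}

#' Read / write GMT gene-set annotations
#'
#' Each GMT line is `term<TAB>description<TAB>gene1<TAB>gene2...`. The in-R
#' representation is a tibble with columns `term`, `description` and a
#' list-column `genes`.
#'
#' @param path file path.
#' @param annotation annotation tibble to write.
#' @return `read_gmt()` returns the annotation tibble; `write_gmt()` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) abort("GMT lines need at least term, description, one gene")
  tibble(term = vapply(parts, `[[`, character(1), 1),
         description = vapply(parts, `[[`, character(1), 2),
         genes = map(parts, ~ .x[-(1:2)]))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(seq_len(nrow(annotation)), function(i) {
    paste(c(annotation$term[i], annotation$description[i],
            annotation$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write all artifacts of a trio simulation
#'
#' Writes the counts, gene lengths, design sheet and truth table of a
#' [simulate_trio_counts()] result as TSV files under `dir`.
#'
#' @param sim a `trio_sim` object.
#' @param dir output directory (created if missing).
#' @return character vector of the written paths, invisibly.
#' @export
write_trio_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "gene_lengths.tsv",
                            "sample_design.tsv", "truth.tsv"))
  readr::write_tsv(sim$counts, paths[1])
  readr::write_tsv(sim$gene_lengths, paths[2])
  readr::write_tsv(sim$design, paths[3])
  readr::write_tsv(sim$truth, paths[4])
  invisible(paths)
}
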