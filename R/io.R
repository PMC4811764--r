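# Plain-text I/O: expression TSV (genes x samples, first column = gene id),
# sample-metadata TSV, score TSV, Ct TSV, FISH TSV, ground-truth JSON.

#' Read an expression matrix from TSV
#'
#' Expects rows = genes, first column = gene id, header = sample ids, all
#' values numeric (normalized log scale).
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  mode(x) <- "numeric"
  rownames(x) <- as.character(df[[1L]])
  check_expression_matrix(x)
  x
}

#' Write an expression matrix to TSV
#'
#' @param x Numeric matrix, genes x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  check_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, subtype) from TSV
#'
#' @param path Path to the TSV file with header `sample_id<TAB>subtype`.
#' @return Data.frame with columns `sample_id`, `subtype`.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character")
  stopifnot(all(c("sample_id", "subtype") %in% names(df)))
  df[, c("sample_id", "subtype")]
}

#' Write sample metadata to TSV
#' @param annotation Data.frame with columns `sample_id`, `subtype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  stopifnot(all(c("sample_id", "subtype") %in% names(annotation)))
  utils::write.table(annotation[, c("sample_id", "subtype")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a score table to TSV
#'
#' Columns: `sample_id`, `score`, `rank` and `in_top_fraction` (computed at
#' `fraction` with [top_fraction()]).
#'
#' @param scores A `score_table` from [signature_score()].
#' @param path Output path.
#' @param fraction Top fraction used for the membership flag (default 0.25).
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path, fraction = 0.25) {
  top <- top_fraction(scores, fraction)
  out <- data.frame(
    sample_id = scores$sample_id,
    score = scores$score,
    rank = scores$rank,
    in_top_fraction = scores$sample_id %in% top,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score TSV written by [write_scores_tsv()]
#' @param path Path to the TSV file.
#' @return Data.frame with at least `sample_id`, `score`, `rank`.
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "score", "rank") %in% names(df)))
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("score_table", "data.frame")
  df
}

#' Read a qPCR Ct table from TSV
#'
#' Columns: `well`, `sample_id`, `assay`, `role` (`standard`/`sample`),
#' `log10_quantity` (blank for sample wells), `ct`.
#'
#' @param path Path to the TSV file.
#' @return A `ct_table` data.frame.
#' @export
read_ct_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopifnot(all(c("well", "sample_id", "assay", "role", "log10_quantity",
                  "ct") %in% names(df)))
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Write a qPCR Ct table to TSV
#' @param ct_table A `ct_table` data.frame (see [simulate_qpcr()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_tsv <- function(ct_table, path) {
  utils::write.table(as.data.frame(ct_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FISH per-cell count table from TSV
#'
#' Columns: `cell_id`, `target_count`, `cen_count`.
#'
#' @param path Path to the TSV file.
#' @return A `fish_cells` data.frame.
#' @export
read_fish_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "target_count", "cen_count") %in% names(df)))
  class(df) <- c("fish_cells", "data.frame")
  df
}

#' Write a FISH per-cell count table to TSV
#' @param cells A `fish_cells` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fish_tsv <- function(cells, path) {
  utils::write.table(as.data.frame(cells), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort's ground truth as JSON
#'
#' @param sim A `sim_cohort` from [simulate_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "sim_cohort"))
  jsonlite::write_json(
    list(
      baseline = as.list(sim$truth$baseline),
      planted = sim$truth$planted,
      membership = sim$truth$membership,
      seed = sim$config$seed,
      noise_sd = sim$config$noise_sd
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Write an enrichment table to TSV
#'
#' @param x An `enrichment_result`, a list of them, or a data.frame with
#'   the standard `k`, `K`, `n`, `N`, `p` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(x, path) {
  if (inherits(x, "enrichment_result")) x <- list(x)
  if (!is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, as.data.frame))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
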