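# Auxiliary quantifications: qPCR standard-curve relative copy number
# against a control locus and a non-amplified reference sample, and FISH
# per-cell signal summaries.

#' Fit a qPCR standard curve
#'
#' Least-squares line `Ct = intercept + slope * log10(quantity)` through a
#' dilution series. Amplification efficiency is `10^(-1/slope) - 1` (1.0 =
#' 100%, the textbook slope of -3.3219 Ct per decade).
#'
#' @param log10_quantity Numeric vector of log10 template quantities; at
#'   least 2 distinct values.
#' @param ct Numeric vector of observed Ct values, same length.
#' @param assay Optional assay name carried into the result.
#' @return A list of class `standard_curve`: `assay`, `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `n_points`. A non-negative slope triggers a
#'   warning (invalid assay).
#' @examples
#' fit_standard_curve(c(2, 1, 0), c(20, 23.3219, 26.6438))
#' @export
fit_standard_curve <- function(log10_quantity, ct, assay = "") {
  if (length(log10_quantity) != length(ct))
    stop("log10_quantity and ct must have equal length")
  if (!all(is.finite(log10_quantity)) || !all(is.finite(ct)))
    stop("non-finite values in standards")
  if (length(unique(log10_quantity)) < 2L)
    stop("need >= 2 distinct log10 quantities")
  fit <- stats::lm(ct ~ log10_quantity)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope >= 0) warning("non-negative slope: not a valid dilution series")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(assay = assay, slope = slope, intercept = intercept,
         efficiency = 10^(-1 / slope) - 1, r_squared = r2,
         n_points = length(ct)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve%s: Ct = %.4f %+.4f * log10(q), efficiency = %.1f%%, r2 = %.4f\n",
    if (nzchar(x$assay)) paste0(" [", x$assay, "]") else "",
    x$intercept, x$slope, 100 * x$efficiency, x$r_squared
  ))
  invisible(x)
}

ct_to_quantity <- function(ct, curve) 10^((ct - curve$intercept) / curve$slope)

#' Relative copy number from qPCR Ct tables (standard-curve method)
#'
#' Converts Ct values to template quantities through per-assay standard
#' curves, forms the target/control quantity ratio per sample, and normalizes
#' it to the same ratio in a designated non-amplified reference sample (whose
#' relative copy number is therefore exactly 1). Technical replicates are
#' collapsed by mean Ct before the quantity transformation.
#'
#' @param ct_table Data.frame with columns `sample_id`, `assay`, `role`
#'   (`"standard"` or `"sample"`), `log10_quantity` (standards only; `NA` for
#'   samples) and `ct`, as produced by [simulate_qpcr()] or read with
#'   [read_ct_tsv()].
#' @param target Target-locus assay name (e.g. `"Met"`).
#' @param control Control-locus assay name (e.g. `"Actl6a"`).
#' @param reference Sample id of the non-amplified reference sample.
#' @param curves Optional named list of [fit_standard_curve()] results (names
#'   = assays); fitted from the table's `standard` rows when `NULL`.
#' @return A data.frame of class `cnv_result` with columns `sample_id`,
#'   `target`, `control`, `rel_copy_number` (reference = 1); the fitted
#'   curves are attached as attribute `curves`.
#' @export
relative_copy_number <- function(ct_table, target, control, reference,
                                 curves = NULL) {
  req <- c("sample_id", "assay", "role", "ct")
  stopifnot(is.data.frame(ct_table), all(req %in% names(ct_table)))
  if (!all(is.finite(ct_table$ct))) stop("non-finite Ct values")
  for (assay in c(target, control)) {
    if (!assay %in% ct_table$assay) stop("missing assay: ", assay)
  }
  if (is.null(curves)) {
    std <- ct_table[ct_table$role == "standard", , drop = FALSE]
    if (!"log10_quantity" %in% names(std))
      stop("standards need a log10_quantity column")
    curves <- lapply(stats::setNames(nm = c(target, control)), function(a) {
      s <- std[std$assay == a, , drop = FALSE]
      if (nrow(s) < 2L) stop("no standard curve for assay: ", a)
      fit_standard_curve(s$log10_quantity, s$ct, assay = a)
    })
  }
  smp <- ct_table[ct_table$role == "sample" &
                    ct_table$assay %in% c(target, control), , drop = FALSE]
  if (!reference %in% smp$sample_id) stop("reference sample not found: ",
                                          reference)
  # mean Ct over technical replicates, then Ct -> quantity
  agg <- stats::aggregate(ct ~ sample_id + assay, data = smp, FUN = mean)
  q <- function(sample, assay) {
    i <- agg$sample_id == sample & agg$assay == assay
    if (!any(i)) stop("sample ", sample, " has no wells for assay ", assay)
    ct_to_quantity(agg$ct[i], curves[[assay]])
  }
  samples <- sort(unique(agg$sample_id))
  ratio <- vapply(samples, function(s) {
    qc <- q(s, control)
    if (qc == 0) stop("control quantity is zero for sample ", s)
    q(s, target) / qc
  }, numeric(1))
  out <- data.frame(
    sample_id = samples,
    target = target,
    control = control,
    rel_copy_number = unname(ratio / ratio[[reference]]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cnv_result", "data.frame")
  attr(out, "curves") <- curves
  attr(out, "reference") <- reference
  out
}

#' Summarize FISH per-cell signal counts
#'
#' From a table of per-cell (target, centromere) signal counts, computes the
#' three amplification metrics: the target/centromere ratio, the percentage
#' of cells with more than 4 target signals (strictly greater), and the mean
#' target signal count per cell. The ratio is the ratio of means by default
#' (population-level ratio); `ratio_method = "mean_of_ratios"` averages
#' per-cell ratios instead (cells with zero centromere count are dropped for
#' that metric, with a warning).
#'
#' @param cells Data.frame with columns `cell_id`, `target_count`,
#'   `cen_count` (non-negative integers), e.g. from [simulate_fish_cells()]
#'   or [read_fish_tsv()]. At least 1 cell; fewer than 100 cells triggers a
#'   warning (scoring conventions ask for >= 100 tumor cells).
#' @param ratio_method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return A list of class `fish_summary`: `ratio`, `pct_gt4`, `mean_target`,
#'   `n_cells`, `ratio_method`.
#' @export
summarize_fish <- function(cells,
                           ratio_method = c("ratio_of_means",
                                            "mean_of_ratios")) {
  ratio_method <- match.arg(ratio_method)
  req <- c("cell_id", "target_count", "cen_count")
  stopifnot(is.data.frame(cells), all(req %in% names(cells)))
  if (nrow(cells) < 1L) stop("empty cell table")
  tc <- cells$target_count
  cc <- cells$cen_count
  if (any(tc < 0 | cc < 0) || any(tc != floor(tc) | cc != floor(cc)))
    stop("signal counts must be non-negative integers")
  if (all(cc == 0)) stop("all centromere counts are zero")
  if (nrow(cells) < 100L)
    warning("only ", nrow(cells), " cells scored; convention asks for >= 100")
  ratio <- if (ratio_method == "ratio_of_means") {
    mean(tc) / mean(cc)
  } else {
    ok <- cc > 0
    if (!all(ok)) warning(sum(!ok), " cell(s) with zero centromere count ",
                          "dropped from mean-of-ratios")
    mean(tc[ok] / cc[ok])
  }
  structure(
    list(ratio = ratio,
         pct_gt4 = 100 * mean(tc > 4),
         mean_target = mean(tc),
         n_cells = nrow(cells),
         ratio_method = ratio_method),
    class = "fish_summary"
  )
}

#' @export
print.fish_summary <- function(x, ...) {
  cat(sprintf(
    "fish_summary (%d cells): target/centromere = %.2f, %.1f%% cells > 4 signals, mean %.2f signals/cell\n",
    x$n_cells, x$ratio, x$pct_gt4, x$mean_target
  ))
  invisible(x)
}
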