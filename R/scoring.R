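# Per-sample signature scores: the signed algebraic sum of log-scale
# expression over signature genes, plus z-scores against a normal panel and
# t-test comparison of score groups.

check_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (!all(is.finite(x))) stop("expression values must be finite")
  invisible(x)
}

# rank 1 = highest score; ties broken by sample id in C-locale order so the
# ranking is reproducible across platforms
score_ranks <- function(score, sample_id) {
  ord <- order(-score, sample_id, method = "radix")
  r <- integer(length(score))
  r[ord] <- seq_along(score)
  r
}

#' Score samples with a directional gene signature
#'
#' The score of sample `s` is `S(s) = sum_g direction(g) * v(g, s)` over the
#' signature genes present in the matrix: up genes add their (log-scale)
#' expression, down genes subtract it. With `standardize = TRUE` each used
#' gene row is centred and scaled to unit standard deviation (n-1
#' denominator) across samples first, so no single high-expressed gene
#' dominates the sum. Signature genes absent from the matrix are skipped and
#' reported through the `coverage` attribute.
#'
#' @param x Numeric expression matrix, genes x samples, log scale.
#' @param sig A [gene_signature]; at least one of its genes must be in `x`.
#' @param standardize Standardize each used gene row first? Default `FALSE`
#'   (raw algebraic sum). Zero-variance genes are skipped with a warning in
#'   standardized mode.
#' @return A `score_table` data.frame with columns `sample_id`, `score`,
#'   `rank` (1 = highest; ties broken by sample id). Attributes: `coverage`
#'   (fraction of signature genes used), `genes_used`, `genes_missing`,
#'   `signature`, `standardized`.
#' @examples
#' x <- matrix(c(3, 1, 5, 2), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' sig <- gene_signature("toy", c("g1", "g2"), c(1, -1))
#' signature_score(x, sig)
#' @export
signature_score <- function(x, sig, standardize = FALSE) {
  check_expression_matrix(x)
  stopifnot(inherits(sig, "gene_signature"))
  present <- sig$entries$gene %in% rownames(x)
  if (!any(present)) stop("no signature gene found in the matrix")
  genes <- sig$entries$gene[present]
  dirs <- sig$entries$direction[present]
  v <- x[genes, , drop = FALSE]
  if (standardize) {
    sds <- apply(v, 1L, stats::sd)
    zero <- sds == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance gene(s) skipped under standardize: ",
              paste(utils::head(genes[zero], 5L), collapse = ", "))
      if (all(zero)) stop("no usable gene after dropping zero-variance rows")
      v <- v[!zero, , drop = FALSE]
      dirs <- dirs[!zero]
      genes <- genes[!zero]
      sds <- sds[!zero]
    }
    v <- (v - rowMeans(v)) / sds
  }
  score <- as.numeric(colSums(v * dirs))
  out <- data.frame(
    sample_id = colnames(x),
    score = score,
    rank = score_ranks(score, colnames(x)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_table", "data.frame")
  attr(out, "coverage") <- mean(present)
  attr(out, "genes_used") <- genes
  attr(out, "genes_missing") <- sig$entries$gene[!present]
  attr(out, "signature") <- sig$name
  attr(out, "standardized") <- standardize
  out
}

#' Z-scores against a normal-tissue panel
#'
#' `z(s) = (value(s) - mean(panel)) / sd(panel)` with the n-1 standard
#' deviation, as used to flag outlier expression of a gene in tumors relative
#' to a panel of normal tissues.
#'
#' @param values Named (or unnamed) numeric vector of per-sample values.
#' @param panel Numeric vector of normal-panel values, length >= 2 with
#'   non-zero standard deviation.
#' @return A data.frame with columns `sample_id`, `value`, `z`, `panel_mean`,
#'   `panel_sd`.
#' @export
zscore_vs_normals <- function(values, panel) {
  if (length(panel) < 2L) stop("panel needs >= 2 values")
  if (!all(is.finite(values)) || !all(is.finite(panel)))
    stop("values and panel must be finite")
  m <- mean(panel)
  s <- stats::sd(panel)
  if (s == 0) stop("degenerate panel: sd = 0")
  ids <- names(values)
  if (is.null(ids)) ids <- sprintf("sample_%d", seq_along(values))
  data.frame(
    sample_id = ids,
    value = as.numeric(values),
    z = (as.numeric(values) - m) / s,
    panel_mean = m,
    panel_sd = s,
    stringsAsFactors = FALSE
  )
}

#' Compare signature scores between two groups by t-test
#'
#' Unpaired two-sample t-test of group A versus group B. The default is the
#' heteroscedastic (Welch) statistic with Satterthwaite degrees of freedom;
#' `variance = "pooled"` gives the classical equal-variance test. One-tailed
#' tests (`tails = 1`) test the hypothesis that A exceeds B: the p-value is
#' the upper tail of the t distribution at the observed statistic.
#'
#' @param group_a,group_b Numeric vectors of scores, each of length >= 2.
#' @param tails `2` (default) or `1` (alternative: mean A > mean B).
#' @param variance `"heteroscedastic"` (default) or `"pooled"`.
#' @return A list of class `score_comparison`: `t`, `df`, `p`, `mean_a`,
#'   `mean_b`, `tails`, `variance`.
#' @examples
#' compare_scores(c(1, 2, 3), c(2, 3, 4))
#' @export
compare_scores <- function(group_a, group_b, tails = 2,
                           variance = c("heteroscedastic", "pooled")) {
  variance <- match.arg(variance)
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 values")
  na <- length(group_a); nb <- length(group_b)
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      return(structure(
        list(t = 0, df = na + nb - 2, p = if (tails == 2) 1 else 0.5,
             mean_a = ma, mean_b = mb, tails = tails, variance = variance),
        class = "score_comparison"
      ))
    }
    stop("zero variance in both groups with unequal means")
  }
  if (variance == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- if (tails == 2) 2 * stats::pt(-abs(t), df)
       else stats::pt(t, df, lower.tail = FALSE)
  structure(
    list(t = t, df = df, p = p, mean_a = ma, mean_b = mb,
         tails = tails, variance = variance),
    class = "score_comparison"
  )
}

#' @export
print.score_comparison <- function(x, ...) {
  cat(sprintf(
    "%s %d-tailed t-test: t = %.4f, df = %.2f, p = %.4g\n",
    x$variance, x$tails, x$t, x$df, x$p
  ))
  invisible(x)
}
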