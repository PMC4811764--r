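# Differential-expression-derived signatures. The test is an ordinary
# two-sample t (pooled by default, Welch selectable) followed by
# Benjamini-Hochberg; a deliberate, documented substitute for the moderated-t
# machinery large array studies use -- variance shrinkage is out of scope.

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values controlling the false discovery rate:
#' `p_adj[i] = min_{j >= i} ( m * p[(j)] / j )`, capped at 1, where `(j)`
#' indexes p-values in increasing order and `m` is the number of tests.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`; `NA`s are not allowed.
#' @return Numeric vector of adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1L) * p[o]))[ro]
}

#' Derive a gene signature by differential expression
#'
#' Runs a per-gene two-sample t-test between two sample groups of a log-scale
#' expression matrix, adjusts p-values across all tested genes by
#' Benjamini-Hochberg, and returns the genes with adjusted p at or below
#' `alpha` as a directional signature: direction `+1` when the mean is higher
#' in `group_a`, `-1` otherwise.
#'
#' Genes with zero variance in both groups get `p = 1` when the group means
#' are equal; when the means differ at zero pooled variance the gene is
#' flagged (`degenerate = TRUE`) with `p = 0` and an infinite statistic.
#'
#' @param x Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param alpha Adjusted-p cutoff for signature membership (default 0.05).
#' @param var_equal Pooled-variance t when `TRUE` (default); Welch otherwise.
#' @param name Name for the derived signature.
#' @return A list of class `de_result` with `table` (data.frame: `gene`,
#'   `statistic`, `df`, `p`, `p_adj`, `direction`, `degenerate`) and
#'   `signature` (a [gene_signature]).
#' @export
derive_de_signature <- function(x, group_a, group_b, alpha = 0.05,
                                var_equal = TRUE, name = "de_signature") {
  check_expression_matrix(x)
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 samples")
  missing <- setdiff(c(group_a, group_b), colnames(x))
  if (length(missing))
    stop("samples not in matrix: ", paste(missing, collapse = ", "))

  a <- x[, group_a, drop = FALSE]
  b <- x[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var)
  vb <- apply(b, 1L, stats::var)

  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(x))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  stat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(stat), df)

  degenerate <- se == 0
  eq_mean <- degenerate & (ma == mb)
  stat[eq_mean] <- 0; p[eq_mean] <- 1; df[eq_mean] <- na + nb - 2
  flagged <- degenerate & !eq_mean
  stat[flagged] <- sign(ma - mb)[flagged] * Inf
  p[flagged] <- 0; df[flagged] <- na + nb - 2
  if (any(flagged))
    warning(sum(flagged), " gene(s) with zero variance but unequal means")

  tab <- data.frame(
    gene = rownames(x),
    statistic = stat,
    df = df,
    p = p,
    p_adj = bh_adjust(p),
    direction = ifelse(ma >= mb, 1L, -1L),
    degenerate = flagged,
    stringsAsFactors = FALSE
  )
  sel <- tab$p_adj <= alpha
  sig <- gene_signature(
    name, tab$gene[sel], tab$direction[sel],
    provenance = sprintf("differential expression, BH-adjusted p <= %g", alpha)
  )
  structure(list(table = tab, signature = sig, alpha = alpha,
                 var_equal = var_equal),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf(
    "de_result: %d genes tested, %d at adjusted p <= %g (%s t-test)\n",
    nrow(x$table), length(x$signature), x$alpha,
    if (x$var_equal) "pooled" else "Welch"
  ))
  invisible(x)
}
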