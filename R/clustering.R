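# Unsupervised hierarchical clustering of samples on signature genes, with
# per-cluster subtype enrichment annotation. Defaults (Euclidean distance,
# complete linkage, per-gene standardized rows) are the common choices for
# this analysis style; both are flags because the field has no single
# convention.

#' Hierarchically cluster samples on a signature's genes
#'
#' Restricts the expression matrix to the signature genes found on the
#' platform, optionally standardizes each gene row (mean 0, sd 1 across
#' samples), and runs agglomerative hierarchical clustering of the sample
#' columns, cutting the tree into exactly `k` clusters.
#'
#' @param x Numeric expression matrix, genes x samples.
#' @param sig A [gene_signature]; at least one gene must be on the platform.
#' @param k Number of clusters, `1 <= k <= ncol(x)`. Default 5, the
#'   subdivision that separates normal muscle from tumor samples in the
#'   cohorts this analysis style comes from.
#' @param distance Distance between sample profiles: `"euclidean"` (default)
#'   or `"manhattan"`.
#' @param linkage Agglomeration method, any method of [stats::hclust()];
#'   default `"complete"`.
#' @param standardize Standardize gene rows before computing distances?
#'   Default `TRUE`; zero-variance rows are dropped with a warning.
#' @return A list of class `cluster_assignment`: `assignment` (named integer
#'   vector, sample id -> cluster 1..k), `hclust` (the full tree, with merge
#'   order and heights), `k`, `genes_used`, `coverage`.
#' @export
cluster_samples <- function(x, sig, k = 5L,
                            distance = c("euclidean", "manhattan"),
                            linkage = "complete", standardize = TRUE) {
  distance <- match.arg(distance)
  check_expression_matrix(x)
  stopifnot(inherits(sig, "gene_signature"))
  if (k < 1L || k > ncol(x)) stop("k must be between 1 and the sample count")
  present <- sig$entries$gene[sig$entries$gene %in% rownames(x)]
  if (!length(present)) stop("no signature gene found on the platform")
  v <- x[present, , drop = FALSE]
  if (standardize) {
    sds <- apply(v, 1L, stats::sd)
    zero <- sds == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance gene row(s) dropped")
      v <- v[!zero, , drop = FALSE]
      sds <- sds[!zero]
    }
    if (nrow(v) == 0L) stop("no usable gene after dropping zero-variance rows")
    v <- (v - rowMeans(v)) / sds
  }
  d <- stats::dist(t(v), method = distance)
  hc <- stats::hclust(d, method = linkage)
  assignment <- stats::cutree(hc, k = k)
  structure(
    list(assignment = assignment, hclust = hc, k = as.integer(k),
         genes_used = rownames(v),
         coverage = length(present) / max(1L, length(sig))),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "cluster_assignment: %d samples in %d clusters on %d signature genes\n",
    length(x$assignment), x$k, length(x$genes_used)
  ))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Annotate clusters with subtype enrichment
#'
#' For every (cluster, subtype label) pair, tests over-representation of the
#' label inside the cluster against the whole cohort with the one-sided
#' hypergeometric test; the label with the smallest p per cluster is flagged
#' as the cluster's dominant subtype. No multiple-testing correction is
#' applied by default (raw hypergeometric p-values, as usually starred on
#' cluster heatmaps); `adjust = TRUE` adds a BH-adjusted column across the
#' whole table.
#'
#' @param ca A `cluster_assignment` from [cluster_samples()].
#' @param annotation A data.frame with columns `sample_id`, `subtype`
#'   covering every clustered sample.
#' @param adjust Add a `p_adj` (Benjamini-Hochberg) column? Default `FALSE`.
#' @return A data.frame with one row per (cluster, label): `cluster`,
#'   `label`, `k`, `K`, `n`, `N`, `p`, `dominant` (and `p_adj` if requested).
#' @export
annotate_clusters <- function(ca, annotation, adjust = FALSE) {
  stopifnot(inherits(ca, "cluster_assignment"))
  stopifnot(is.data.frame(annotation),
            all(c("sample_id", "subtype") %in% names(annotation)))
  ids <- names(ca$assignment)
  lab <- annotation$subtype[match(ids, annotation$sample_id)]
  if (anyNA(lab)) {
    stop("unannotated samples: ",
         paste(utils::head(ids[is.na(lab)], 5L), collapse = ", "))
  }
  labels <- sort(unique(lab))
  N <- length(ids)
  rows <- list()
  for (cl in sort(unique(ca$assignment))) {
    in_cl <- ca$assignment == cl
    n <- sum(in_cl)
    for (l in labels) {
      res <- hypergeometric_enrichment(
        k = sum(in_cl & lab == l), K = sum(lab == l), n = n, N = N,
        category = l
      )
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, label = l, k = res$k, K = res$K, n = res$n, N = res$N,
        p = res$p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  # dominant label = minimal p within a cluster; ties to the first label
  # alphabetically (labels are iterated sorted)
  out$dominant <- FALSE
  for (cl in unique(out$cluster)) {
    i <- which(out$cluster == cl)
    out$dominant[i[which.min(out$p[i])]] <- TRUE
  }
  if (adjust) out$p_adj <- bh_adjust(out$p)
  out
}

#' Write a cluster dendrogram as Newick text
#'
#' Dumps the hierarchical tree of a [cluster_samples()] result as a Newick
#' string (label:height nesting) for external inspection.
#'
#' @param ca A `cluster_assignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(ca, path) {
  stopifnot(inherits(ca, "cluster_assignment"))
  phy <- ape::as.phylo(ca$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
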