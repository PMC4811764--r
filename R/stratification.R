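# Sample stratification: top-fraction selection on ranked scores and
# one-sided hypergeometric over-representation tests (subtype enrichment in a
# selection; Venn-style overlap between two selections).

#' Select the top-scoring fraction of samples
#'
#' Takes the `ceiling(fraction * n)` (or `floor`, if requested) samples with
#' the highest scores from a score table. Boundary ties are resolved by the
#' table's deterministic rank order (ties broken by sample id).
#'
#' @param scores A `score_table` from [signature_score()] (any data.frame
#'   with `sample_id`, `score`, `rank` columns works).
#' @param fraction Fraction in `(0, 1]`; default 0.25 ("top quartile").
#' @param size_rule `"ceiling"` (default, inclusive reading of "top 25%") or
#'   `"floor"`.
#' @return Character vector of selected sample ids, in rank order.
#' @export
top_fraction <- function(scores, fraction = 0.25,
                         size_rule = c("ceiling", "floor")) {
  size_rule <- match.arg(size_rule)
  stopifnot(is.data.frame(scores),
            all(c("sample_id", "score", "rank") %in% names(scores)))
  n <- nrow(scores)
  if (n == 0L) stop("empty score table")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  m <- if (size_rule == "ceiling") ceiling(fraction * n) else floor(fraction * n)
  scores$sample_id[order(scores$rank)][seq_len(m)]
}

#' One-sided hypergeometric enrichment test
#'
#' Upper-tail probability `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: the chance of drawing at least `k`
#' category members in a size-`n` selection from a universe of `N` containing
#' `K` members, when the selection is random. Terms are accumulated in log
#' space (via `lchoose`) so universes of hundreds of samples do not overflow.
#'
#' @param k Observed successes in the selection.
#' @param K Successes in the universe.
#' @param n Selection size.
#' @param N Universe size.
#' @param category Optional label carried into the result.
#' @return An `enrichment_result` list: `category`, `k`, `K`, `n`, `N`, `p`.
#' @examples
#' hypergeometric_enrichment(k = 3, K = 4, n = 5, N = 10)  # p = 66/252
#' @export
hypergeometric_enrichment <- function(k, K, n, N, category = NA_character_) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (any(c(k, K, n, N) < 0) || any(c(k, K, n, N) != floor(c(k, K, n, N))))
    stop("k, K, n, N must be non-negative integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  if (k <= max(0, n + K - N)) {
    p <- 1  # at or below the attainable minimum: the event is certain
  } else {
    i <- k:min(K, n)
    p <- sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
    p <- min(1, max(p, .Machine$double.xmin))
  }
  structure(
    list(category = category, k = as.integer(k), K = as.integer(K),
         n = as.integer(n), N = as.integer(N), p = p),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment%s: k=%d of n=%d selected, K=%d of N=%d in universe, p = %.4g\n",
    if (is.na(x$category)) "" else paste0(" [", x$category, "]"),
    x$k, x$n, x$K, x$N, x$p
  ))
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(category = x$category, k = x$k, K = x$K, n = x$n, N = x$N,
             p = x$p, stringsAsFactors = FALSE)
}

#' Hypergeometric test of the overlap of two sample sets
#'
#' Tests whether the overlap `k = |A` \eqn{\cap} `B|` is larger than expected
#' when two subsets of a common universe are drawn independently, as in a
#' Venn-diagram intersection of two top-quartile selections. Computed as
#' [hypergeometric_enrichment()]`(k, |A|, |B|, |universe|)`; the test is
#' symmetric in A and B.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible ids.
#' @return An `enrichment_result`.
#' @export
intersection_test <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be contained in the universe")
  hypergeometric_enrichment(
    k = length(intersect(set_a, set_b)),
    K = length(set_a),
    n = length(set_b),
    N = length(universe),
    category = "intersection"
  )
}
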