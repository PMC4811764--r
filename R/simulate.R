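# Synthetic-data module: expression cohorts with planted signature shifts,
# qPCR plates with planted copy numbers, and FISH cell tables. Every
# generator takes an explicit seed and is bit-reproducible; all randomness
# within one call is drawn under a single seed in a fixed, documented order.

#' Configure a synthetic expression cohort
#'
#' Describes a multi-subtype cohort on the log2 scale: per-gene baselines
#' drawn around `baseline_mean`, i.i.d. Gaussian noise, and additive shifts
#' planted on the genes of named signatures in chosen subtypes.
#'
#' @param n_genes Number of background genes (signature genes absent from
#'   this universe are appended by [simulate_expression()]).
#' @param subtypes Named integer vector: subtype label -> sample count
#'   (each >= 1; labels unique).
#' @param baseline_mean Mean of per-gene baseline log2 expression
#'   (default 7, a typical mid-range normalized array intensity).
#' @param baseline_sd Standard deviation of per-gene baselines (default 1).
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise on the
#'   log2 scale (>= 0; default 1, a typical between-sample spread for one
#'   gene on normalized arrays).
#' @param planted_effects `NULL`, or data.frame with columns `signature`,
#'   `subtype`, `delta`: samples of `subtype` get `direction(g) * delta`
#'   added to every gene `g` of `signature`.
#' @param seed Integer seed; identical configs with identical seeds produce
#'   byte-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes, subtypes, baseline_mean = 7,
                          baseline_sd = 1, noise_sd = 1,
                          planted_effects = NULL, seed = 1L) {
  if (is.null(names(subtypes)) || any(!nzchar(names(subtypes))))
    stop("subtypes must be a named vector (label -> sample count)")
  if (anyDuplicated(names(subtypes))) stop("duplicate subtype labels")
  if (any(subtypes < 1L)) stop("all sample counts must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (baseline_sd < 0) stop("baseline_sd must be >= 0")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("signature", "subtype", "delta") %in%
                    names(planted_effects)))
    bad <- setdiff(planted_effects$subtype, names(subtypes))
    if (length(bad)) stop("planted effect on unknown subtype: ",
                          paste(bad, collapse = ", "))
  }
  structure(
    list(n_genes = as.integer(n_genes),
         subtypes = subtypes,
         baseline_mean = baseline_mean,
         baseline_sd = baseline_sd,
         noise_sd = noise_sd,
         planted_effects = planted_effects,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate an expression cohort with planted signature shifts
#'
#' Generates `value(g, s) = baseline(g) + direction(g) * delta + noise` on
#' the log2 scale, where the `delta` term applies when gene `g` belongs to a
#' planted signature and sample `s` to the matching subtype, and the noise is
#' i.i.d. `N(0, noise_sd^2)`. Signature genes missing from the configured
#' gene universe are appended (never silently dropped), so planted effects
#' are always realizable.
#'
#' Draw order under the single seed: per-gene baselines first, then the
#' noise matrix, column-major.
#'
#' @param config A [cohort_config()].
#' @param signatures List of [gene_signature] objects referenced by
#'   `config$planted_effects` (may be empty when no effects are planted).
#' @return A list of class `sim_cohort`: `expr` (genes x samples matrix),
#'   `annotation` (data.frame `sample_id`, `subtype`), `truth` (list:
#'   per-gene `baseline`, `planted` shifts data.frame with columns `gene`,
#'   `subtype`, `shift`, and signature `membership` table), `config`.
#' @examples
#' cfg <- cohort_config(20, c(ERMS = 4, MUSCLE = 4), noise_sd = 0.5,
#'                      seed = 7)
#' sim <- simulate_expression(cfg)
#' dim(sim$expr)
#' @export
simulate_expression <- function(config, signatures = list()) {
  stopifnot(inherits(config, "cohort_config"))
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  names(signatures) <- vapply(signatures, `[[`, "", "name")

  eff <- config$planted_effects
  if (!is.null(eff)) {
    bad <- setdiff(eff$signature, names(signatures))
    if (length(bad)) stop("planted effect references unknown signature: ",
                          paste(bad, collapse = ", "))
  }

  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  sig_universe <- unique(unlist(lapply(signatures, sig_genes)))
  genes <- union(genes, sig_universe)  # append foreign signature genes
  G <- length(genes)

  counts <- config$subtypes
  sample_id <- unlist(lapply(names(counts), function(l) {
    sprintf("%s_%03d", l, seq_len(counts[[l]]))
  }), use.names = FALSE)
  subtype <- rep(names(counts), counts)
  S <- length(sample_id)

  draws <- withr::with_seed(config$seed, {
    list(
      baseline = stats::rnorm(G, config$baseline_mean, config$baseline_sd),
      noise = matrix(stats::rnorm(G * S, 0, config$noise_sd), G, S)
    )
  })
  baseline <- stats::setNames(draws$baseline, genes)

  expr <- matrix(baseline, G, S) + draws$noise
  dimnames(expr) <- list(genes, sample_id)

  planted <- data.frame(gene = character(), subtype = character(),
                        shift = numeric(), stringsAsFactors = FALSE)
  if (!is.null(eff)) {
    for (i in seq_len(nrow(eff))) {
      sig <- signatures[[eff$signature[i]]]
      shift <- sig$entries$direction * eff$delta[i]
      cols <- subtype == eff$subtype[i]
      expr[sig$entries$gene, cols] <-
        expr[sig$entries$gene, cols, drop = FALSE] + shift
      planted <- rbind(planted, data.frame(
        gene = sig$entries$gene, subtype = eff$subtype[i], shift = shift,
        stringsAsFactors = FALSE
      ))
    }
  }

  membership <- if (length(signatures)) {
    do.call(rbind, lapply(signatures, function(s) {
      data.frame(signature = s$name, gene = s$entries$gene,
                 direction = s$entries$direction, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(signature = character(), gene = character(),
               direction = integer(), stringsAsFactors = FALSE)
  }
  rownames(membership) <- NULL

  structure(
    list(
      expr = expr,
      annotation = data.frame(sample_id = sample_id, subtype = subtype,
                              stringsAsFactors = FALSE),
      truth = list(baseline = baseline, planted = planted,
                   membership = membership),
      config = config
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d genes x %d samples (%s), noise_sd = %g, seed = %d\n",
    nrow(x$expr), ncol(x$expr),
    paste(sprintf("%s:%d", names(x$config$subtypes), x$config$subtypes),
          collapse = ", "),
    x$config$noise_sd, x$config$seed
  ))
  invisible(x)
}

#' Simulate qPCR Ct tables for a copy-number experiment
#'
#' Generates a long Ct table containing, per assay, a dilution-series
#' standard curve (`Ct = intercept + slope * log10(quantity) + noise`) and
#' sample wells whose true target quantities are proportional to planted
#' relative copy numbers. Control-locus quantities are equal across samples;
#' the planted copy number of the reference sample should be 1.
#'
#' @param copy_number Named numeric vector: sample id -> planted relative
#'   copy number (> 0).
#' @param target,control Assay names (default `"Met"` / `"Actl6a"`).
#' @param curves Data.frame with columns `assay`, `slope`, `intercept`
#'   covering both assays; defaults to 100%-efficiency curves
#'   (slope `-1/log10(2)`).
#' @param standard_log10 Log10 quantities of the dilution series (>= 2
#'   distinct values; default `4:0`, a 10-fold series).
#' @param base_log10 Log10 of the control-locus template quantity shared by
#'   all samples (default 2).
#' @param noise_sd Gaussian Ct noise standard deviation (default 0).
#' @param replicates Technical replicates per sample well (default 1).
#' @param seed Integer seed.
#' @return A data.frame (class `ct_table`) with columns `well`, `sample_id`,
#'   `assay`, `role` (`standard`/`sample`), `log10_quantity` (`NA` for
#'   sample wells) and `ct`.
#' @export
simulate_qpcr <- function(copy_number, target = "Met", control = "Actl6a",
                          curves = NULL, standard_log10 = 4:0,
                          base_log10 = 2, noise_sd = 0, replicates = 1L,
                          seed = 1L) {
  if (is.null(names(copy_number)) || any(!nzchar(names(copy_number))))
    stop("copy_number must be a named vector (sample id -> copy number)")
  if (any(copy_number <= 0)) stop("planted copy numbers must be > 0")
  if (length(unique(standard_log10)) < 2L)
    stop("dilution series needs >= 2 distinct log10 quantities")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(curves)) {
    curves <- data.frame(assay = c(target, control),
                         slope = -1 / log10(2),
                         intercept = c(28, 27))
  }
  stopifnot(all(c("assay", "slope", "intercept") %in% names(curves)))
  if (!all(is.finite(curves$slope)) || !all(is.finite(curves$intercept)))
    stop("non-finite curve parameters")
  for (a in c(target, control)) {
    if (!a %in% curves$assay) stop("no curve parameters for assay: ", a)
  }
  cv <- function(a) curves[match(a, curves$assay), ]

  rows <- list()
  add <- function(well, sample_id, assay, role, lq, true_ct) {
    rows[[length(rows) + 1L]] <<- data.frame(
      well = well, sample_id = sample_id, assay = assay, role = role,
      log10_quantity = lq, ct = true_ct, stringsAsFactors = FALSE
    )
  }
  for (a in c(target, control)) {
    p <- cv(a)
    for (i in seq_along(standard_log10)) {
      add(sprintf("std_%s_%02d", a, i), NA_character_, a, "standard",
          standard_log10[i], p$intercept + p$slope * standard_log10[i])
    }
  }
  for (s in names(copy_number)) {
    for (a in c(target, control)) {
      p <- cv(a)
      lq <- base_log10 + if (a == target) log10(copy_number[[s]]) else 0
      for (r in seq_len(replicates)) {
        add(sprintf("%s_%s_r%d", s, a, r), s, a, "sample", NA_real_,
            p$intercept + p$slope * lq)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$ct <- out$ct + withr::with_seed(seed,
                                      stats::rnorm(nrow(out), 0, noise_sd))
  class(out) <- c("ct_table", "data.frame")
  attr(out, "truth") <- list(copy_number = copy_number, curves = curves,
                             base_log10 = base_log10)
  out
}

#' Simulate a FISH per-cell signal-count table
#'
#' Draws reproducible per-cell (target, centromere) signal counts from the
#' stated distributions. A distribution is either a single non-negative
#' integer (constant count for every cell) or a function `f(n)` returning
#' `n` non-negative integer counts (e.g. a Poisson mixture).
#'
#' @param n_cells Number of cells (>= 1).
#' @param target_dist,cen_dist Constant count or generator function for the
#'   target-locus and centromere signals (defaults: diploid, 2 and 2).
#' @param seed Integer seed governing both draws (target first).
#' @return A data.frame (class `fish_cells`) with columns `cell_id`,
#'   `target_count`, `cen_count`.
#' @examples
#' simulate_fish_cells(5, target_dist = 9, cen_dist = 2, seed = 1)
#' @export
simulate_fish_cells <- function(n_cells, target_dist = 2, cen_dist = 2,
                                seed = 1L) {
  if (n_cells < 1L) stop("n_cells must be >= 1")
  draw <- function(d) {
    v <- if (is.function(d)) d(n_cells) else rep(d, n_cells)
    if (length(v) != n_cells || any(v < 0) || any(v != floor(v)))
      stop("distribution must yield n_cells non-negative integer counts")
    as.integer(v)
  }
  counts <- withr::with_seed(seed, {
    list(target = draw(target_dist), cen = draw(cen_dist))
  })
  out <- data.frame(
    cell_id = sprintf("cell_%04d", seq_len(n_cells)),
    target_count = counts$target,
    cen_count = counts$cen,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fish_cells", "data.frame")
  out
}
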