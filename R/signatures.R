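# Directional gene signatures: a named set of genes each tagged +1 (up) or
# -1 (down). Scores downstream are signed sums, so the sign is the only
# per-gene weight carried around.

#' Create a directional gene signature
#'
#' A gene signature is a named set of `(gene, direction)` entries, where
#' `direction` is `+1` for genes up in the state the signature summarizes and
#' `-1` for genes down. Directions are recycled along `genes`.
#'
#' @param name Signature name (single string).
#' @param genes Character vector of gene identifiers; must be unique.
#' @param directions Integer vector of `+1`/`-1`, recycled to `length(genes)`.
#' @param provenance Free-text provenance metadata.
#' @return An object of class `gene_signature` with elements `name`,
#'   `entries` (data.frame with columns `gene`, `direction`) and `provenance`.
#' @examples
#' sig <- gene_signature("met", c("MET", "HGF", "CDKN2A"), c(1, 1, -1))
#' sig
#' @export
gene_signature <- function(name, genes, directions = 1L, provenance = "") {
  stopifnot(is.character(name), length(name) == 1L)
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids in signature '", name, "'")
  }
  directions <- as.integer(rep_len(directions, length(genes)))
  if (length(genes) > 0L && !all(directions %in% c(-1L, 1L))) {
    stop("directions must be +1 or -1")
  }
  structure(
    list(
      name = name,
      entries = data.frame(
        gene = genes, direction = directions,
        stringsAsFactors = FALSE
      ),
      provenance = provenance
    ),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  n_up <- sum(x$entries$direction == 1L)
  n_dn <- sum(x$entries$direction == -1L)
  cat(sprintf(
    "gene_signature '%s': %d genes (%d up, %d down)\n",
    x$name, nrow(x$entries), n_up, n_dn
  ))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) nrow(x$entries)

#' @export
as.data.frame.gene_signature <- function(x, ...) x$entries

sig_genes <- function(sig, direction = NULL) {
  e <- sig$entries
  if (is.null(direction)) e$gene else e$gene[e$direction == direction]
}

#' Read signatures from a GMT file
#'
#' Signatures are stored as standard GMT records (name, description, genes,
#' tab-separated). A signature with both up and down genes occupies two
#' records, `NAME_UP` and `NAME_DN`; a record without the suffix is read as
#' all-up.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_signature] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed GMT record at line(s): ",
                     paste(which(bad), collapse = ", "))
  rec_name <- vapply(parts, `[[`, "", 1L)
  rec_desc <- vapply(parts, `[[`, "", 2L)
  rec_genes <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))

  base <- sub("_(UP|DN)$", "", rec_name)
  side <- ifelse(grepl("_DN$", rec_name), -1L, 1L)
  out <- list()
  for (nm in unique(base)) {
    idx <- which(base == nm)
    genes <- character()
    dirs <- integer()
    for (i in idx) {
      g <- setdiff(rec_genes[[i]], genes)  # first record wins on conflict
      genes <- c(genes, g)
      dirs <- c(dirs, rep(side[i], length(g)))
    }
    out[[nm]] <- gene_signature(nm, genes, dirs,
                                provenance = rec_desc[[idx[1L]]])
  }
  out
}

#' Write signatures to a GMT file
#'
#' Each signature is written as an `NAME_UP` record and, when it has down
#' genes, an `NAME_DN` record.
#'
#' @param sigs A [gene_signature] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  lines <- character()
  for (sig in sigs) {
    up <- sig_genes(sig, 1L)
    dn <- sig_genes(sig, -1L)
    desc <- if (nzchar(sig$provenance)) sig$provenance else sig$name
    if (length(up) || !length(dn)) {
      lines <- c(lines, paste(c(paste0(sig$name, "_UP"), desc, up),
                              collapse = "\t"))
    }
    if (length(dn)) {
      lines <- c(lines, paste(c(paste0(sig$name, "_DN"), desc, dn),
                              collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- homolog mapping --------------------------------------------------------

#' Build a homolog map from source/target gene pairs
#'
#' @param source Character vector of source-namespace gene ids.
#' @param target Character vector of target-namespace gene ids, same length.
#' @return A `homolog_map`: a named list mapping each source id to its set of
#'   target ids. Lookup of an unmapped id yields an empty set, not an error;
#'   empty target sets are never stored.
#' @export
homolog_map <- function(source, target) {
  source <- as.character(source)
  target <- as.character(target)
  if (length(source) != length(target)) {
    stop("source and target must have equal length")
  }
  keep <- nzchar(source) & nzchar(target) & !is.na(source) & !is.na(target)
  if (!all(keep)) stop("malformed map rows (empty or missing ids)")
  m <- lapply(split(target, source), unique)
  structure(m, class = "homolog_map")
}

#' Read a homolog map from a two-column TSV
#'
#' One row per `(source_id, target_id)` pair; an optional header row
#' (`source_id<TAB>target_id`) is skipped.
#'
#' @param path Path to the TSV file.
#' @return A [homolog_map].
#' @export
read_homolog_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          col.names = c("source", "target"))
  if (nrow(df) && identical(tolower(df$source[1L]), "source_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  homolog_map(df$source, df$target)
}

#' Map a gene set across species through a homolog map
#'
#' Translates a set of gene identifiers into another namespace (e.g. mouse to
#' human orthologs). One-to-many mappings are handled per `policy`:
#' `"expand"` takes the union of all targets, `"unique_only"` keeps only
#' sources with exactly one target. Genes the map does not cover are recorded
#' in the report rather than silently lost.
#'
#' @param genes Character vector of source gene ids.
#' @param map A [homolog_map].
#' @param policy `"expand"` (default) or `"unique_only"`.
#' @return A list of class `homolog_report`: `genes` (mapped target ids,
#'   deduplicated), `unmapped` (sources with no mapping) and `ambiguous`
#'   (sources dropped under `unique_only` for having several targets).
#' @export
map_homologs <- function(genes, map, policy = c("expand", "unique_only")) {
  policy <- match.arg(policy)
  stopifnot(inherits(map, "homolog_map"))
  genes <- unique(as.character(genes))
  hits <- lapply(genes, function(g) {
    t <- map[[g]]
    if (is.null(t)) character() else t
  })
  n_t <- lengths(hits)
  unmapped <- genes[n_t == 0L]
  ambiguous <- character()
  if (policy == "unique_only") {
    ambiguous <- genes[n_t > 1L]
    hits[n_t > 1L] <- list(character())
  }
  structure(
    list(
      genes = unique(unlist(hits, use.names = FALSE)),
      unmapped = unmapped,
      ambiguous = ambiguous,
      policy = policy
    ),
    class = "homolog_report"
  )
}

#' @export
print.homolog_report <- function(x, ...) {
  cat(sprintf(
    "homolog_report (policy=%s): %d mapped targets, %d unmapped, %d ambiguous\n",
    x$policy, length(x$genes), length(x$unmapped), length(x$ambiguous)
  ))
  invisible(x)
}

# ---- signature set operations ----------------------------------------------

#' Intersect two directional signatures
#'
#' The result keeps genes present in both signatures whose directions agree;
#' discordant-direction genes cannot be assigned a sign, so they are dropped
#' and recorded in the `discordant` attribute (with a warning). Both
#' signatures must already be in the same gene namespace.
#'
#' @param a,b [gene_signature] objects.
#' @param name Name for the result; default `"<a>_x_<b>"`.
#' @return A [gene_signature]; attribute `discordant` lists dropped genes.
#'   An empty intersection is allowed (with a warning).
#' @export
intersect_signatures <- function(a, b, name = NULL) {
  stopifnot(inherits(a, "gene_signature"), inherits(b, "gene_signature"))
  if (is.null(name)) name <- paste0(a$name, "_x_", b$name)
  common <- intersect(a$entries$gene, b$entries$gene)
  da <- a$entries$direction[match(common, a$entries$gene)]
  db <- b$entries$direction[match(common, b$entries$gene)]
  concordant <- da == db
  discordant <- common[!concordant]
  if (length(discordant)) {
    warning(length(discordant), " discordant-direction gene(s) dropped: ",
            paste(utils::head(discordant, 5L), collapse = ", "),
            if (length(discordant) > 5L) ", ..." else "")
  }
  out <- gene_signature(
    name, common[concordant], da[concordant],
    provenance = sprintf("overlap(%s, %s)", a$name, b$name)
  )
  if (length(out) == 0L) warning("empty signature after intersection")
  attr(out, "discordant") <- discordant
  out
}

#' Restrict a signature to the genes measured on a platform
#'
#' @param sig A [gene_signature].
#' @param platform_genes Character vector of gene ids present on the platform.
#' @return The filtered [gene_signature]; attribute `coverage` holds the
#'   fraction of signature genes found on the platform, attribute `missing`
#'   the genes dropped.
#' @export
restrict_to_platform <- function(sig, platform_genes) {
  stopifnot(inherits(sig, "gene_signature"))
  platform_genes <- as.character(platform_genes)
  keep <- sig$entries$gene %in% platform_genes
  out <- gene_signature(sig$name, sig$entries$gene[keep],
                        sig$entries$direction[keep],
                        provenance = sig$provenance)
  attr(out, "coverage") <- if (length(sig) == 0L) 1 else mean(keep)
  attr(out, "missing") <- sig$entries$gene[!keep]
  out
}
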