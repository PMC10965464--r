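#' Gene sets and the packaged dietary-restriction signature
#'
#' A `gene_set` is a named, ordered collection of unique gene symbols; a
#' `signature_pair` couples a positive and a negative set whose enrichment
#' difference defines the DR score. The packaged DR signature pairs 220
#' positively DR-related genes with 56 negatively DR-related genes (276 in
#' total, disjoint). Because the original symbol lists are not distributed
#' with this package, the shipped GMT is a synthetic stand-in that preserves
#' the sizes and structure of the signature; substitute your own GMT for
#' real analyses.
#'
#' @name gene-sets
NULL

#' Construct a gene set
#'
#' @param name Set label (single non-empty string).
#' @param genes Character vector of gene symbols; must be non-empty, unique,
#'   and contain no empty strings.
#' @return An object of class `gene_set` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("gene set name must be a single non-empty string")
  genes <- as.character(genes)
  if (length(genes) == 0L) stopf("gene set '%s' is empty", name)
  if (any(!nzchar(genes))) stopf("gene set '%s' contains empty identifiers", name)
  if (anyDuplicated(genes)) stopf("gene set '%s' contains duplicate identifiers", name)
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @method print gene_set
#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Construct a positive/negative signature pair
#'
#' @param positive,negative `gene_set` objects; must be disjoint.
#' @return An object of class `signature_pair`.
#' @export
signature_pair <- function(positive, negative) {
  stopifnot(inherits(positive, "gene_set"), inherits(negative, "gene_set"))
  shared <- intersect(positive$genes, negative$genes)
  if (length(shared))
    stopf("positive and negative sets overlap (%s, ...)", shared[1L])
  structure(list(positive = positive, negative = negative), class = "signature_pair")
}

#' @method print signature_pair
#' @export
print.signature_pair <- function(x, ...) {
  cat(sprintf("<signature_pair> positive: %d genes, negative: %d genes\n",
              length(x$positive$genes), length(x$negative$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description (discarded), then gene symbols, all
#' tab-separated. Duplicate genes within a line are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("GMT file is empty: %s", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stopf("malformed GMT line %d: fewer than 3 tab-separated fields", i)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warnf("GMT line %d ('%s'): duplicate genes removed", i, fields[1L])
      genes <- genes[!duplicated(genes)]
    }
    sets[[i]] <- gene_set(fields[1L], genes)
  }
  nms <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nms))
    stopf("duplicate gene set names in %s: %s", path, nms[duplicated(nms)][1L])
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of `gene_set` objects.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Load the packaged DR signature
#'
#' Returns the packaged dietary-restriction `signature_pair` (220 positive,
#' 56 negative, 276 in total, disjoint) and validates those counts on every
#' call. The shipped gene list is a synthetic stand-in (see [gene-sets]).
#'
#' @return A `signature_pair`.
#' @export
load_dr_signature <- function() {
  path <- system.file("extdata", "dr_signature_synthetic.gmt", package = "drtme")
  if (!nzchar(path) || !file.exists(path))
    stopf("packaged DR signature file is missing; reinstall the package")
  sets <- read_gmt(path)
  if (!all(c("DR_POSITIVE", "DR_NEGATIVE") %in% names(sets)))
    stopf("packaged DR signature is corrupt: expected sets DR_POSITIVE and DR_NEGATIVE")
  pair <- signature_pair(sets$DR_POSITIVE, sets$DR_NEGATIVE)
  np <- length(pair$positive$genes); nn <- length(pair$negative$genes)
  if (np != 220L || nn != 56L)
    stopf("packaged DR signature is corrupt: %d positive / %d negative genes (expected 220 / 56)", np, nn)
  if (length(union(pair$positive$genes, pair$negative$genes)) != 276L)
    stopf("packaged DR signature is corrupt: union is not 276 genes")
  if (any(pair$positive$genes != toupper(pair$positive$genes)) ||
      any(pair$negative$genes != toupper(pair$negative$genes)))
    stopf("packaged DR signature is corrupt: non-uppercase symbols")
  pair
}

#' Intersect a gene set with a matrix's genes
#'
#' Matching is exact and case-sensitive on the symbols; set `uppercase = TRUE`
#' to uppercase both sides first (off by default so mapping problems surface
#' rather than being silently case-folded away).
#'
#' @param mat An expression matrix (see [expression_matrix]) or any matrix
#'   with gene-symbol rownames.
#' @param set A `gene_set`.
#' @param uppercase Uppercase both sides before matching.
#' @return List with `matched` (a `gene_set` in the original set order, or
#'   `NULL` when the intersection is empty) and `coverage` (fraction of the
#'   set found in the matrix).
#' @export
match_genes <- function(mat, set, uppercase = FALSE) {
  stopifnot(inherits(set, "gene_set"))
  ids <- rownames(mat)
  genes <- set$genes
  if (uppercase) { ids <- toupper(ids); genes <- toupper(genes) }
  keep <- set$genes[genes %in% ids]
  list(
    matched = if (length(keep)) gene_set(set$name, keep) else NULL,
    coverage = length(keep) / length(set$genes)
  )
}
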