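#' Single-sample gene set enrichment (ssGSEA)
#'
#' Per-sample, rank-based enrichment scoring. Within each sample, genes are
#' ranked by expression (1 = lowest, ties averaged) and walked in decreasing
#' rank order; the enrichment score of a set is the sum over positions of the
#' difference between the weighted in-set cumulative distribution (weights
#' `rank^tau`) and the unweighted out-of-set cumulative distribution. Raw
#' scores are normalised by the global range of the score matrix across all
#' sets and samples, so the reported NES matrix has range exactly 1 whenever
#' the raw range is nonzero. Because only within-sample ranks enter, any
#' strictly monotone transform of a sample's expression (log, TPM rescaling)
#' leaves its scores unchanged — which is why the engine never asks whether
#' input was log-transformed.
#'
#' A `kcdf` choice can be recorded in the parameters for provenance, but it
#' is inert here: kernel CDFs apply to other enrichment variants, not to the
#' rank-based ssGSEA statistic.
#'
#' @name ssgsea-engine
NULL

#' ssGSEA parameters
#'
#' @param tau Rank weighting exponent (>= 0). Default 0.25.
#' @param min_size Minimum matched set size; smaller sets are dropped with a
#'   warning. Default 10.
#' @param normalize Divide raw scores by the global range. Default `TRUE`.
#' @param per_set Normalise each set's row by its own range instead of the
#'   global range. Default `FALSE`.
#' @param kcdf Recorded for provenance only; has no effect on the rank-based
#'   statistic.
#' @return A list of class `ssgsea_params`.
#' @export
ssgsea_params <- function(tau = 0.25, min_size = 10L, normalize = TRUE,
                          per_set = FALSE, kcdf = "Poisson") {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stopf("`tau` must be a single number >= 0")
  if (!is.numeric(min_size) || length(min_size) != 1L || min_size < 1)
    stopf("`min_size` must be >= 1")
  structure(list(tau = tau, min_size = as.integer(min_size),
                 normalize = isTRUE(normalize), per_set = isTRUE(per_set),
                 kcdf = kcdf),
            class = "ssgsea_params")
}

#' Rank one sample's expression values
#'
#' @param x Numeric vector of finite expression values (optionally named).
#' @return Ranks in `1..length(x)` with 1 = lowest; ties receive the average
#'   of the ranks they span.
#' @export
rank_sample <- function(x) {
  if (!length(x)) stopf("empty expression vector")
  if (any(!is.finite(x))) stopf("non-finite expression values cannot be ranked")
  rank(x, ties.method = "average")
}

#' Raw enrichment score of one set in one sample
#'
#' Genes are ordered by decreasing rank (ties broken by ascending gene
#' identifier for bit-reproducibility). With in-set weights `rank^tau`, the
#' score is `sum_i (P_in(i) - P_out(i))` over ordered positions `i`, where
#' `P_in` is the weighted in-set CDF and `P_out` the unweighted out-of-set
#' CDF.
#'
#' @param ranks Named numeric vector of within-sample ranks (see
#'   [rank_sample()]).
#' @param set_genes Character vector of gene identifiers; must be a non-empty
#'   subset of `names(ranks)` and a proper subset of all genes.
#' @param tau Weighting exponent.
#' @return The raw enrichment score (a single number).
#' @export
es_single <- function(ranks, set_genes, tau = 0.25) {
  ids <- names(ranks)
  if (is.null(ids)) stopf("`ranks` must be named by gene identifier")
  if (!length(set_genes)) stopf("empty gene set")
  if (!all(set_genes %in% ids)) stopf("set contains genes absent from `ranks`")
  n <- length(ranks)
  m <- length(unique(set_genes))
  if (m == n)
    stopf("set covers every gene; out-of-set CDF undefined (filter by min/max set size)")
  ord <- order(-ranks, ids, method = "radix")
  in_set <- ids[ord] %in% set_genes
  w <- ranks[ord]^tau
  w_in <- ifelse(in_set, w, 0)
  p_in <- cumsum(w_in) / sum(w_in)
  p_out <- cumsum(!in_set) / (n - m)
  sum(p_in - p_out)
}

#' ssGSEA enrichment matrix
#'
#' @param mat An [expression_matrix()] or numeric matrix (genes x samples)
#'   with dimnames.
#' @param sets A list of `gene_set` objects (or a single one).
#' @param params An [ssgsea_params()] object.
#' @return Numeric matrix of normalised enrichment scores, kept sets in rows,
#'   samples in columns. Raw (unnormalised) scores are attached as attribute
#'   `"raw"`.
#' @export
ssgsea <- function(mat, sets, params = ssgsea_params()) {
  stopifnot(inherits(params, "ssgsea_params"))
  if (inherits(sets, "gene_set")) sets <- list(sets)
  x <- unclass(mat)
  if (!is.matrix(x) || !is.numeric(x)) stopf("`mat` must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("`mat` needs gene rownames and sample colnames")

  matched <- lapply(sets, function(s) match_genes(x, s)$matched)
  sizes <- vapply(matched, function(s) if (is.null(s)) 0L else length(s$genes), 0L)
  keep <- sizes >= params$min_size
  if (any(!keep)) {
    dropped <- vapply(sets[!keep], `[[`, "", "name")
    warnf("dropping %d set(s) with fewer than %d matched genes: %s",
          sum(!keep), params$min_size, paste(dropped, collapse = ", "))
  }
  if (!any(keep))
    stopf("no gene set has >= %d matched genes (min_size filter)", params$min_size)
  matched <- matched[keep]

  n <- nrow(x)
  es <- matrix(NA_real_, nrow = length(matched), ncol = ncol(x),
               dimnames = list(unname(vapply(matched, `[[`, "", "name")),
                               colnames(x)))
  for (j in seq_len(ncol(x))) {
    r <- rank_sample(x[, j])
    names(r) <- rownames(x)
    # one ordering per sample, shared across sets
    ord <- order(-r, rownames(x), method = "radix")
    ids_ord <- rownames(x)[ord]
    w_ord <- r[ord]^params$tau
    for (k in seq_along(matched)) {
      in_set <- ids_ord %in% matched[[k]]$genes
      m <- sum(in_set)
      if (m == n) stopf("set '%s' covers every gene", matched[[k]]$name)
      w_in <- ifelse(in_set, w_ord, 0)
      es[k, j] <- sum(cumsum(w_in) / sum(w_in) - cumsum(!in_set) / (n - m))
    }
  }

  out <- es
  if (params$normalize) {
    if (params$per_set) {
      for (k in seq_len(nrow(out))) {
        rng <- diff(range(out[k, ]))
        if (rng > 0) out[k, ] <- out[k, ] / rng
        else warnf("set '%s' has zero raw score range; left unscaled", rownames(out)[k])
      }
    } else {
      rng <- diff(range(es))
      if (rng > 0) out <- es / rng
      else warnf("zero raw enrichment range; returning unscaled scores")
    }
  }
  attr(out, "raw") <- es
  out
}
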