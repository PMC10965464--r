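#' The dietary-restriction (DR) score
#'
#' The DR score of a sample (or cell, or spot) is the difference between the
#' normalised enrichment scores of the positively and negatively DR-related
#' gene sets, `DR = NES1 - NES2`. Significance is assessed per sample by
#' drawing random disjoint gene-set pairs of the same matched sizes from the
#' matrix's genes and recomputing the null score; cohorts are stratified by
#' the median (high/low) or by quartiles (high/medium/low).
#'
#' @name dr-score
NULL

#' Permutation-test configuration
#'
#' @param n_reps Number of random gene-set pairs per sample. Default 1000.
#' @param seed RNG seed (single integer).
#' @param sidedness `"greater"` (DR activity present; default) or
#'   `"two-sided"`.
#' @return A list of class `permutation_config`.
#' @export
permutation_config <- function(n_reps = 1000L, seed = 1L,
                               sidedness = c("greater", "two-sided")) {
  if (!is.numeric(n_reps) || n_reps < 1) stopf("`n_reps` must be >= 1")
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 sidedness = match.arg(sidedness)),
            class = "permutation_config")
}

#' Compute per-sample DR scores
#'
#' @param mat An [expression_matrix()] or numeric matrix (genes x samples).
#' @param signature A [signature_pair()]; defaults to the packaged DR
#'   signature.
#' @param params [ssgsea_params()].
#' @return A `data.frame` with columns `sample_id`, `nes_positive`,
#'   `nes_negative`, `dr_score` (one row per sample).
#' @export
compute_dr_scores <- function(mat, signature = load_dr_signature(),
                              params = ssgsea_params()) {
  stopifnot(inherits(signature, "signature_pair"))
  nes <- ssgsea(mat, list(signature$positive, signature$negative), params)
  if (nrow(nes) != 2L)
    stopf("both signature sets must pass the min_size filter")
  data.frame(
    sample_id = colnames(nes),
    nes_positive = nes[1L, ],
    nes_negative = nes[2L, ],
    dr_score = nes[1L, ] - nes[2L, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Per-sample permutation significance of the DR score
#'
#' For each sample, `n_reps` disjoint random gene-set pairs of sizes equal to
#' the matched positive/negative signature sizes are drawn uniformly without
#' replacement from the matrix's genes; the null DR statistic is the raw
#' enrichment-score difference within that sample (normalisation is a shared
#' positive rescaling and cancels from the comparison). The p-value uses the
#' add-one estimator `p = (1 + #[null >= observed]) / (n_reps + 1)`, so it is
#' never zero; `"two-sided"` compares absolute values. One RNG stream,
#' seeded from the configuration, is consumed in sample order.
#'
#' @param mat Expression matrix (genes x samples).
#' @param signature A [signature_pair()].
#' @param cfg A [permutation_config()].
#' @param params [ssgsea_params()].
#' @return `data.frame` with columns `sample_id`, `observed` (raw score
#'   difference) and `perm_p`.
#' @export
permutation_test <- function(mat, signature = load_dr_signature(),
                             cfg = permutation_config(),
                             params = ssgsea_params()) {
  stopifnot(inherits(signature, "signature_pair"),
            inherits(cfg, "permutation_config"))
  x <- unclass(mat)
  ids <- rownames(x)
  n <- nrow(x)
  m1 <- sum(signature$positive$genes %in% ids)
  m2 <- sum(signature$negative$genes %in% ids)
  if (m1 < params$min_size || m2 < params$min_size)
    stopf("matched signature sets (%d, %d) below min_size %d", m1, m2, params$min_size)
  if (n < m1 + m2)
    stopf("matrix has %d genes; cannot draw disjoint null sets of sizes %d + %d", n, m1, m2)

  pos <- signature$positive$genes[signature$positive$genes %in% ids]
  neg <- signature$negative$genes[signature$negative$genes %in% ids]
  tau <- params$tau
  stat <- function(in1, in2, w_ord) {
    # in1/in2: logical membership in ordered-position space
    s1 <- {
      w_in <- ifelse(in1, w_ord, 0)
      sum(cumsum(w_in) / sum(w_in) - cumsum(!in1) / (n - sum(in1)))
    }
    s2 <- {
      w_in <- ifelse(in2, w_ord, 0)
      sum(cumsum(w_in) / sum(w_in) - cumsum(!in2) / (n - sum(in2)))
    }
    s1 - s2
  }

  with_seed(cfg$seed, {
    res <- vapply(seq_len(ncol(x)), function(j) {
      r <- rank_sample(x[, j]); names(r) <- ids
      ord <- order(-r, ids, method = "radix")
      ids_ord <- ids[ord]
      w_ord <- r[ord]^tau
      obs <- stat(ids_ord %in% pos, ids_ord %in% neg, w_ord)
      nulls <- vapply(seq_len(cfg$n_reps), function(b) {
        draw <- sample.int(n, m1 + m2)
        in1 <- logical(n); in1[draw[seq_len(m1)]] <- TRUE
        in2 <- logical(n); in2[draw[m1 + seq_len(m2)]] <- TRUE
        stat(in1, in2, w_ord)
      }, 0)
      p <- if (cfg$sidedness == "greater") {
        (1 + sum(nulls >= obs)) / (cfg$n_reps + 1)
      } else {
        (1 + sum(abs(nulls) >= abs(obs))) / (cfg$n_reps + 1)
      }
      c(obs, p)
    }, c(0, 0))
    data.frame(sample_id = colnames(x), observed = res[1L, ],
               perm_p = res[2L, ], row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Median stratification into high/low DR groups
#'
#' Samples with DR score strictly above the cohort median are `"high"`; all
#' others, including ties at the median, are `"low"` (the deterministic
#' direction chosen for ties).
#'
#' @param table A `data.frame` with a `dr_score` column (see
#'   [compute_dr_scores()]).
#' @return The table with a `stratum` column (`"high"`/`"low"`).
#' @export
stratify_median <- function(table) {
  s <- table$dr_score
  if (length(s) < 2L) stopf("median stratification needs >= 2 samples")
  if (diff(range(s)) == 0) stopf("degenerate stratification: all DR scores identical")
  med <- stats::median(s)
  table$stratum <- ifelse(s > med, "high", "low")
  table
}

#' Quartile stratification into high/medium/low DR groups
#'
#' `"high"` above the third quartile, `"low"` below the first, `"medium"`
#' otherwise. Quartiles use the default linear-interpolation sample-quantile
#' convention (`stats::quantile`, type 7).
#'
#' @inheritParams stratify_median
#' @return The table with a `stratum` column (`"high"`/`"medium"`/`"low"`).
#' @export
stratify_quartiles <- function(table) {
  s <- table$dr_score
  if (length(s) < 4L) stopf("quartile stratification needs >= 4 samples")
  q <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1L] == q[2L]) stopf("degenerate stratification: Q1 equals Q3")
  table$stratum <- ifelse(s > q[2L], "high", ifelse(s < q[1L], "low", "medium"))
  table
}
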