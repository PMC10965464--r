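#' Immune scoring, the CYT score, and the LIHC-DR predictor
#'
#' The immune panel couples 16 immune cell-type gene sets with 13
#' immunological-pathway gene sets scored per sample by the ssGSEA engine.
#' The packaged panel GMT carries the canonical set names but synthetic,
#' marker-seeded memberships (the reference lists are not redistributed
#' here); it is an editable stand-in and users should substitute a curated
#' panel for real analyses. The CYT (cytolytic activity) score is the
#' average of GZMA and PRF1 transcript levels; the LIHC-DR predictor is the
#' fixed two-gene linear risk score
#' `0.001906 * FZD1 + 0.000974 * G6PD` for hepatocellular carcinoma.
#'
#' @name immune-scores
NULL

.predictor_coefs <- c(FZD1 = 0.001906, G6PD = 0.000974)

#' Load the packaged immune panel
#'
#' @return List with `cell_sets` (16 `gene_set`s) and `pathway_sets` (13).
#' @export
load_immune_panel <- function() {
  path <- system.file("extdata", "immune_panel_synthetic.gmt", package = "drtme")
  if (!nzchar(path) || !file.exists(path))
    stopf("packaged immune panel file is missing; reinstall the package")
  sets <- read_gmt(path)
  if (length(sets) != 29L)
    stopf("packaged immune panel is corrupt: expected 29 sets, found %d", length(sets))
  list(cell_sets = sets[1:16], pathway_sets = sets[17:29])
}

#' Score the immune panel per sample
#'
#' Delegates to [ssgsea()] over the panel's 29 sets; output rows are ordered
#' cell sets first, then pathway sets (sets failing the min-size filter are
#' dropped with a warning).
#'
#' @param mat Expression matrix (genes x samples).
#' @param panel A panel as returned by [load_immune_panel()], or any list
#'   with `cell_sets` and `pathway_sets` entries.
#' @param params [ssgsea_params()].
#' @return Enrichment matrix, sets x samples.
#' @export
immune_panel_scores <- function(mat, panel = load_immune_panel(),
                                params = ssgsea_params()) {
  sets <- c(panel$cell_sets, panel$pathway_sets)
  nms <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("panel set names must be unique")
  ssgsea(mat, sets, params)
}

#' Cytolytic activity (CYT) score
#'
#' Per sample, the average of GZMA and PRF1 transcript levels. The default
#' `"log-arithmetic"` mode averages `log2(TPM + 1)` of the two genes
#' (computed from TPM input, or used directly for `log2(TPM+1)` input); the
#' `"geometric"` mode is the classical geometric mean of `TPM + 0.01` and
#' requires TPM input.
#'
#' @param mat An [expression_matrix()] with unit `"TPM"` or `"log2(TPM+1)"`.
#' @param mode `"log-arithmetic"` (default) or `"geometric"`.
#' @return `data.frame` with columns `sample_id`, `cyt`.
#' @export
cyt_score <- function(mat, mode = c("log-arithmetic", "geometric")) {
  mode <- match.arg(mode)
  unit <- expr_unit(mat)
  for (g in c("GZMA", "PRF1"))
    if (!g %in% rownames(mat)) stopf("gene %s is missing from the matrix", g)
  gz <- unclass(mat)["GZMA", ]
  pf <- unclass(mat)["PRF1", ]
  cyt <- switch(mode,
    "log-arithmetic" = {
      if (unit == "TPM") (log2(gz + 1) + log2(pf + 1)) / 2
      else if (unit == "log2(TPM+1)") (gz + pf) / 2
      else stopf("CYT score needs TPM or log2(TPM+1) input, not %s", unit)
    },
    geometric = {
      if (unit != "TPM") stopf("geometric CYT score needs TPM input, not %s", unit)
      sqrt((gz + 0.01) * (pf + 0.01))
    })
  data.frame(sample_id = colnames(mat), cyt = unname(cyt),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' The two-gene LIHC-DR prognostic predictor
#'
#' `score = 0.001906 * FZD1 + 0.000974 * G6PD`, evaluated on the matrix's
#' expression values as given (the score scales with the expression unit;
#' the median-split risk grouping is scale-invariant). The unit is recorded
#' as an attribute of the result.
#'
#' @param mat Expression matrix containing FZD1 and G6PD.
#' @param risk_group Also assign `"high"`/`"low"` risk by the cohort median
#'   of the score (strictly above the median is high).
#' @return `data.frame` with columns `sample_id`, `fzd1`, `g6pd`, `score`
#'   (and `risk_group` when requested), with attribute `"unit"`.
#' @export
lihc_dr_predictor <- function(mat, risk_group = FALSE) {
  for (g in c("FZD1", "G6PD"))
    if (!g %in% rownames(mat)) stopf("gene %s is missing from the matrix", g)
  f <- unclass(mat)["FZD1", ]
  g6 <- unclass(mat)["G6PD", ]
  score <- .predictor_coefs[["FZD1"]] * f + .predictor_coefs[["G6PD"]] * g6
  out <- data.frame(sample_id = colnames(mat), fzd1 = unname(f),
                    g6pd = unname(g6), score = unname(score),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (risk_group) {
    med <- stats::median(out$score)
    out$risk_group <- ifelse(out$score > med, "high", "low")
  }
  attr(out, "unit") <- if (inherits(mat, "expr_matrix")) expr_unit(mat) else NA_character_
  out
}
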