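#' Copy-number burden scoring
#'
#' Segmented copy-number log2 ratios (GISTIC-2.0-style arm-level values plus
#' optional focal regions) are binned into integer scores
#' `{-2, -1, 0, 1, 2}` and summed into an arm score, a focal score, a
#' chromosome score (chromosome-level events are chromosomes whose two arms
#' carry the same log2 ratio, counted once at the shared bin when that bin is
#' non-neutral), and an overall score = arm + focal + chromosome. Arm-level
#' gain/loss calls use strict thresholds `> 0.25` / `< -0.25`.
#'
#' Note one deliberate boundary asymmetry, preserved exactly as defined:
#' `bin_log2(0.25)` scores 1, while `call_arm_events` labels 0.25 neutral
#' (its gain rule is strict). The two rules serve different outputs and are
#' not harmonised.
#'
#' @name cnv-scoring
NULL

#' Bin a log2 copy-number ratio into an integer score
#'
#' 2 if `x >= 1`; 1 if `0.25 <= x < 1`; 0 if `-0.25 <= x < 0.25`;
#' -1 if `-1 <= x < -0.25`; -2 if `x < -1`. Vectorised.
#'
#' @param x Finite numeric log2 ratio(s).
#' @return Integer score(s) in `{-2, -1, 0, 1, 2}`.
#' @export
bin_log2 <- function(x) {
  if (any(!is.finite(x))) stopf("non-finite log2 ratio")
  ifelse(x >= 1, 2L,
  ifelse(x >= 0.25, 1L,
  ifelse(x >= -0.25, 0L,
  ifelse(x >= -1, -1L, -2L))))
}

#' Construct a per-sample copy-number profile
#'
#' @param sample_id Sample label.
#' @param arm_log2 Named numeric vector of arm-level log2 ratios; names are
#'   arm labels such as `"1p"`, `"1q"`, ..., `"22q"`.
#' @param focal_log2 Named numeric vector of focal-region log2 ratios (may be
#'   empty).
#' @param arm_pairing Named list mapping chromosome label to its
#'   `c(p_arm, q_arm)` labels; derived from `arm_log2` names by default.
#'   Acrocentric chromosomes may list a single arm and are skipped by
#'   chromosome-level scoring.
#' @return A list of class `cnv_profile`.
#' @export
cnv_profile <- function(sample_id, arm_log2, focal_log2 = numeric(),
                        arm_pairing = NULL) {
  if (!length(arm_log2)) stopf("profile needs at least one arm")
  if (is.null(names(arm_log2)) || any(!nzchar(names(arm_log2))))
    stopf("arm_log2 must be named by arm label")
  if (anyDuplicated(names(arm_log2)))
    stopf("duplicate arm labels in profile '%s'", sample_id)
  if (any(!is.finite(arm_log2)) || any(!is.finite(focal_log2)))
    stopf("non-finite log2 values in profile '%s'", sample_id)
  if (is.null(arm_pairing)) {
    chroms <- unique(sub("[pq]$", "", names(arm_log2)))
    arm_pairing <- lapply(chroms, function(ch) {
      arms <- intersect(paste0(ch, c("p", "q")), names(arm_log2))
      arms
    })
    names(arm_pairing) <- chroms
  } else {
    missing <- setdiff(unlist(arm_pairing), names(arm_log2))
    if (length(missing))
      stopf("arm_pairing references unknown arms: %s", paste(missing, collapse = ", "))
  }
  structure(list(sample_id = as.character(sample_id), arm_log2 = arm_log2,
                 focal_log2 = focal_log2, arm_pairing = arm_pairing),
            class = "cnv_profile")
}

#' Arm score: sum of binned arm-level log2 ratios
#' @param profile A [cnv_profile()].
#' @return Integer sum.
#' @export
arm_score <- function(profile) {
  stopifnot(inherits(profile, "cnv_profile"))
  sum(bin_log2(profile$arm_log2))
}

#' Focal score: sum of binned focal-region log2 ratios
#' @param profile A [cnv_profile()].
#' @return Integer sum (0 when the profile has no focal regions).
#' @export
focal_score <- function(profile) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (!length(profile$focal_log2)) return(0L)
  sum(bin_log2(profile$focal_log2))
}

#' Chromosome score: sum over whole-chromosome events
#'
#' A chromosome with both arms present contributes its shared binned score
#' when the two arm log2 ratios agree within `tol` and that bin is
#' non-neutral; chromosomes with a single arm (acrocentric) or disagreeing
#' arms contribute 0. `tol = 0` is the literal same-value rule; a small
#' tolerance (e.g. `1e-6`) is recommended for real segmentation output,
#' where equal arms are never bit-identical.
#'
#' @param profile A [cnv_profile()].
#' @param tol Nonnegative agreement tolerance on the log2 scale.
#' @param binned Compare binned scores instead of raw log2 values (the
#'   looser reading of "the same"); default `FALSE`.
#' @return Integer sum.
#' @export
chromosome_score <- function(profile, tol = 0, binned = FALSE) {
  stopifnot(inherits(profile, "cnv_profile"), tol >= 0)
  total <- 0L
  for (arms in profile$arm_pairing) {
    if (length(arms) != 2L) next
    p <- profile$arm_log2[[arms[1L]]]
    q <- profile$arm_log2[[arms[2L]]]
    agree <- if (binned) bin_log2(p) == bin_log2(q) else abs(p - q) <= tol
    if (agree) {
      b <- bin_log2((p + q) / 2)
      if (b != 0L) total <- total + b
    }
  }
  total
}

#' Overall CNV score of one sample
#'
#' @param profile A [cnv_profile()].
#' @param tol Passed to [chromosome_score()].
#' @return One-row `data.frame`: `sample_id`, `arm_score`, `focal_score`,
#'   `chromosome_score`, `overall_score` (= sum of the three components).
#' @export
overall_cnv_score <- function(profile, tol = 0) {
  a <- arm_score(profile)
  f <- focal_score(profile)
  ch <- chromosome_score(profile, tol = tol)
  data.frame(sample_id = profile$sample_id, arm_score = a, focal_score = f,
             chromosome_score = ch, overall_score = a + f + ch,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Arm-level gain/loss calls
#'
#' Gain if log2 ratio `> 0.25`, loss if `< -0.25`, neutral otherwise (both
#' thresholds strict; 0.25 exactly is neutral here even though [bin_log2()]
#' scores it 1 — see [cnv-scoring]).
#'
#' @param profile A [cnv_profile()].
#' @return Named character vector over arms with values
#'   `"gain"`/`"loss"`/`"neutral"`.
#' @export
call_arm_events <- function(profile) {
  stopifnot(inherits(profile, "cnv_profile"))
  x <- profile$arm_log2
  out <- ifelse(x > 0.25, "gain", ifelse(x < -0.25, "loss", "neutral"))
  names(out) <- names(x)
  out
}

#' Score a collection of CNV profiles
#'
#' @param profiles List of [cnv_profile()] objects.
#' @param tol Passed to [chromosome_score()].
#' @return `data.frame` with one row per profile (the CNV score table).
#' @export
cnv_score_table <- function(profiles, tol = 0) {
  do.call(rbind, lapply(profiles, overall_cnv_score, tol = tol))
}

#' Read arm-level log2 ratios from a GISTIC-style broad-values table
#'
#' Expects a TSV with arm labels in the first column and one column per
#' sample (the `broad_values_by_arm` dialect).
#'
#' @param path Path to the TSV.
#' @param focal Optional named list mapping sample id to a named numeric
#'   vector of focal-region log2 ratios.
#' @return List of [cnv_profile()] objects, one per sample column.
#' @export
read_gistic_arms <- function(path, focal = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  arms <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- arms
  lapply(colnames(m), function(s) {
    f <- if (!is.null(focal) && s %in% names(focal)) focal[[s]] else numeric()
    cnv_profile(s, stats::setNames(m[, s], arms), focal_log2 = f)
  })
}
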