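#' Covariate-adjusted association and survival models
#'
#' Associations between DR scores and genomic burdens are estimated with
#' multiple linear (continuous burden) or logistic (arm gain/loss) regression
#' adjusted for age, sex and race, with Benjamini-Hochberg correction across
#' strata within one analysis family. Survival contrasts use the
#' Kaplan-Meier estimator, the log-rank test, and Cox proportional-hazards
#' models (Efron ties), all via the survival package; landmark AUC with a
#' percentile bootstrap CI quantifies discrimination of a risk score for
#' event-by-horizon status.
#'
#' @name clinical-models
NULL

#' Build a clinical record table
#'
#' @param sample_id Labels.
#' @param time Follow-up durations (> 0).
#' @param event 0/1 event indicators (1 = death or cancer-specific death).
#' @param age,sex,race,cancer_type Optional covariates; categorical ones are
#'   stored as factors with alphabetically-first reference level.
#' @return `data.frame` of class `clinical_records`.
#' @export
clinical_records <- function(sample_id, time, event, age = NULL, sex = NULL,
                             race = NULL, cancer_type = NULL) {
  if (any(time <= 0)) stopf("follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stopf("event must be 0/1")
  out <- data.frame(sample_id = as.character(sample_id), time = time,
                    event = as.integer(event), stringsAsFactors = FALSE)
  if (!is.null(age)) out$age <- age
  for (nm in c("sex", "race", "cancer_type")) {
    v <- get(nm)
    if (!is.null(v)) out[[nm]] <- factor(v, levels = sort(unique(as.character(v))))
  }
  class(out) <- c("clinical_records", "data.frame")
  out
}

.check_design <- function(fit) {
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stopf("rank-deficient design; aliased terms: %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
}

#' Linear association of a burden with the DR score, covariate-adjusted
#'
#' Ordinary least squares of `y` on the DR score plus age/sex/race; the
#' reported coefficient, 95% CI and p-value are for the DR-score term (the
#' single-df partial F test, identical to the t test).
#'
#' @param y Numeric burden vector (e.g. mutation load or CNV score).
#' @param x Numeric DR scores.
#' @param covars Optional `data.frame` of covariates (age, sex, race, ...);
#'   character columns are treated as factors with alphabetically-first
#'   reference level.
#' @param stratum Label carried into the result (e.g. cancer type).
#' @return One-row `data.frame`: `stratum`, `coef`, `ci_low`, `ci_high`, `p`.
#' @export
linear_association <- function(y, x, covars = NULL, stratum = NA_character_) {
  dat <- data.frame(y = y, x = x)
  if (!is.null(covars)) dat <- cbind(dat, covars)
  if (nrow(dat) <= ncol(stats::model.matrix(~ ., dat[-1])))
    stopf("too few observations for the number of parameters")
  fit <- stats::lm(y ~ ., data = dat)
  .check_design(fit)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, "x", level = 0.95)
  data.frame(stratum = stratum, coef = sm["x", "Estimate"],
             ci_low = ci[1L], ci_high = ci[2L], p = sm["x", "Pr(>|t|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Logistic association of a binary event with the DR score
#'
#' Maximum-likelihood logit fit (convergence tolerance 1e-8, at most 100
#' iterations); the coefficient is the log-odds per unit DR score. Perfect
#' separation raises an error rather than returning a divergent fit.
#'
#' @param y Binary 0/1 outcome (e.g. arm gain).
#' @param x Numeric DR scores.
#' @inheritParams linear_association
#' @return One-row `data.frame`: `stratum`, `coef`, `ci_low`, `ci_high`, `p`.
#' @export
logistic_association <- function(y, x, covars = NULL, stratum = NA_character_) {
  if (!all(y %in% c(0, 1))) stopf("`y` must be binary 0/1")
  if (length(unique(y)) < 2L) stopf("both outcome classes must be present")
  if (stats::var(x) == 0) stopf("rank-deficient design; aliased terms: x")
  dat <- data.frame(y = y, x = x)
  if (!is.null(covars)) dat <- cbind(dat, covars)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || any(abs(stats::coef(fit)[-1L]) > 20))
    stopf("perfect or quasi-perfect separation detected")
  .check_design(fit)
  sm <- summary(fit)$coefficients
  se <- sm["x", "Std. Error"]
  est <- sm["x", "Estimate"]
  data.frame(stratum = stratum, coef = est,
             ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
             p = sm["x", "Pr(>|z|)"], row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction across one analysis family.
#'
#' @param pvals Numeric p-values, all in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Kaplan-Meier curves per group
#'
#' @param records A [clinical_records()] table (columns `time`, `event`).
#' @param groups Group label per record.
#' @return `data.frame` with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv` (product-limit estimate).
#' @export
km_curve <- function(records, groups) {
  groups <- as.character(groups)
  if (any(table(groups) == 0L) || any(!nzchar(groups))) stopf("empty group label")
  if (sum(records$event) < 1L) stopf("no events in the data")
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ groups)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(groups), length(sm$time))
         else sub("^groups=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, surv = sm$surv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' @param records A [clinical_records()] table.
#' @param groups Two-level group label per record.
#' @return List with `chisq` (1 df) and `p`.
#' @export
logrank_test <- function(records, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2L) stopf("exactly two groups required")
  if (min(table(groups)) < 1L) stopf("empty group")
  if (sum(records$event) < 1L) stopf("no events in the data")
  sd <- survival::survdiff(survival::Surv(records$time, records$event) ~ groups)
  chisq <- sd$chisq
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling over the supplied
#' covariates (typically DR score, sex, cancer type and age); hazard ratios
#' with Wald 95% CIs.
#'
#' @param records A [clinical_records()] table.
#' @param covars `data.frame` of covariates, one row per record.
#' @return `data.frame` with one row per model term: `term`, `coef`, `hr`,
#'   `hr_low`, `hr_high`, `se`, `p`.
#' @export
cox_ph <- function(records, covars) {
  if (sum(records$event) < 1L) stopf("no events in the data")
  const <- vapply(covars, function(v) length(unique(v)) < 2L, TRUE)
  if (any(const))
    stopf("rank-deficient design; aliased terms: %s",
          paste(names(covars)[const], collapse = ", "))
  dat <- cbind(data.frame(.time = records$time, .event = records$event), covars)
  nonconv <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron",
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|out of iterations", conditionMessage(w)))
        nonconv <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (nonconv)
    stopf("Cox model did not converge within 100 iterations")
  .check_design(fit)
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), coef = sm[, "coef"], hr = exp(sm[, "coef"]),
             hr_low = exp(sm[, "coef"] - 1.96 * sm[, "se(coef)"]),
             hr_high = exp(sm[, "coef"] + 1.96 * sm[, "se(coef)"]),
             se = sm[, "se(coef)"], p = sm[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

.rank_auc <- function(score, label) {
  # empirical AUC of score for label 1 vs 0, ties counted half
  r <- rank(score, ties.method = "average")
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Landmark AUC with percentile bootstrap CI
#'
#' Subjects with an event at or before the horizon are cases; subjects
#' followed beyond the horizon (event-free at the horizon) are controls;
#' subjects censored before the horizon are excluded (simple landmark
#' classification, no censoring weights). AUC is the empirical rank AUC of
#' the score for case-vs-control; the CI is a percentile bootstrap over the
#' included subjects.
#'
#' @param scores Risk score per subject (higher = higher risk).
#' @param records A [clinical_records()] table in the same subject order.
#' @param horizon Landmark time, in the records' time unit (e.g. 1 or 3
#'   years).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @return List with `auc`, `ci_low`, `ci_high`, `n_case`, `n_control`.
#' @export
landmark_auc <- function(scores, records, horizon, n_boot = 10000L, seed = 1L) {
  stopifnot(length(scores) == nrow(records))
  case <- records$event == 1L & records$time <= horizon
  control <- records$time > horizon
  keep <- case | control
  if (sum(case) == 0L || sum(control) == 0L)
    stopf("landmark filtering left %d cases and %d controls", sum(case), sum(control))
  s <- scores[keep]
  lab <- as.integer(case[keep])
  auc <- .rank_auc(s, lab)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    ix <- sample.int(length(s), replace = TRUE)
    if (length(unique(lab[ix])) < 2L) return(NA_real_)
    .rank_auc(s[ix], lab[ix])
  }, 0))
  boot <- boot[!is.na(boot)]
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)
  list(auc = auc, ci_low = ci[1L], ci_high = ci[2L],
       n_case = sum(case), n_control = sum(control))
}
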