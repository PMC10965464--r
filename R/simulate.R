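#' Synthetic data with known ground truth
#'
#' Generators for every input the pipeline consumes: expression matrices with
#' a planted DR-signature shift (up for the positive set, down for the
#' negative set, in a randomly chosen "active" half of the samples),
#' copy-number profiles with known binned scores, and survival records whose
#' hazard is proportional-hazards-linked to a score. All generators are pure
#' functions of their configuration and seed.
#'
#' @name synthetic-data
NULL

#' Simulation configuration for expression data
#'
#' @param n_genes Total genes (default 2000); must cover the embedded
#'   signature genes.
#' @param n_samples Number of samples (or cells).
#' @param frac_signature Fraction of each signature set embedded in the
#'   matrix (default 1).
#' @param effect_size Mean log2-shift applied to positive-set genes in active
#'   samples and, negated, to negative-set genes (default 1).
#' @param noise_model `"lognormal"` (TPM-like, default) or
#'   `"negative-binomial"` (counts).
#' @param baseline_sd Standard deviation of the per-gene baseline log2 means
#'   (default 1, giving realistic shared gene-level structure across
#'   samples). Set to 0 for a fully exchangeable null matrix in which genes
#'   and samples are iid — the design needed when per-sample statistics must
#'   be independent across samples, as in permutation-calibration studies.
#' @param dropout_rate Fraction of entries zeroed (single-cell mode);
#'   default 0.
#' @param censoring_rate Target censoring fraction for survival generation.
#' @param true_loghr True log hazard ratio per standardised score unit.
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_samples = 100L, frac_signature = 1,
                       effect_size = 1, noise_model = c("lognormal", "negative-binomial"),
                       dropout_rate = 0, censoring_rate = 0.3,
                       true_loghr = -0.69, baseline_sd = 1, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_genes >= 1, n_samples >= 1,
            frac_signature >= 0, frac_signature <= 1,
            effect_size >= 0, dropout_rate >= 0, dropout_rate < 1,
            censoring_rate >= 0, censoring_rate < 1, baseline_sd >= 0)
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 frac_signature = frac_signature, effect_size = effect_size,
                 noise_model = noise_model, dropout_rate = dropout_rate,
                 censoring_rate = censoring_rate, true_loghr = true_loghr,
                 baseline_sd = baseline_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an expression matrix with a planted DR-signature shift
#'
#' Baseline log2 means are drawn per gene from N(3, `baseline_sd`);
#' per-entry noise is N(0, 1) on the log2 scale. A random half of the samples is "active":
#' their positive-set genes are shifted up and negative-set genes shifted
#' down by `effect_size` log2 units. Lognormal mode reports `2^log2value`
#' as TPM; negative-binomial mode draws counts with that mean (size 5).
#' Dropout zeroes entries with probability `dropout_rate`.
#'
#' @param cfg A [sim_config()].
#' @param signature A [signature_pair()]; defaults to the packaged DR
#'   signature.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (`data.frame` with `sample_id` and logical `active`).
#' @export
simulate_expression <- function(cfg = sim_config(), signature = load_dr_signature()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(signature, "signature_pair"))
  n_pos <- round(cfg$frac_signature * length(signature$positive$genes))
  n_neg <- round(cfg$frac_signature * length(signature$negative$genes))
  pos <- signature$positive$genes[seq_len(n_pos)]
  neg <- signature$negative$genes[seq_len(n_neg)]
  n_sig <- n_pos + n_neg
  if (cfg$n_genes < n_sig)
    stopf("n_genes = %d cannot hold %d embedded signature genes", cfg$n_genes, n_sig)
  genes <- c(pos, neg,
             if (cfg$n_genes > n_sig) sprintf("BG%05d", seq_len(cfg$n_genes - n_sig)))
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))

  with_seed(cfg$seed, {
    active <- logical(cfg$n_samples)
    active[sample.int(cfg$n_samples, floor(cfg$n_samples / 2))] <- TRUE
    mu <- stats::rnorm(cfg$n_genes, mean = 3, sd = cfg$baseline_sd)
    logx <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, sd = 1),
                   nrow = cfg$n_genes) + mu
    if (cfg$effect_size > 0 && any(active)) {
      shift <- numeric(cfg$n_genes)
      shift[seq_len(n_pos)] <- cfg$effect_size
      shift[n_pos + seq_len(n_neg)] <- -cfg$effect_size
      logx[, active] <- logx[, active] + shift
    }
    vals <- 2^logx
    unit <- "TPM"
    if (cfg$noise_model == "negative-binomial") {
      vals <- matrix(stats::rnbinom(length(vals), mu = vals, size = 5),
                     nrow = nrow(vals))
      unit <- "counts"
    }
    if (cfg$dropout_rate > 0) {
      drop <- matrix(stats::runif(length(vals)) < cfg$dropout_rate, nrow = nrow(vals))
      vals[drop] <- 0
    }
    dimnames(vals) <- list(genes, samples)
    list(matrix = expression_matrix(vals, unit = unit),
         truth = data.frame(sample_id = samples, active = active,
                            stringsAsFactors = FALSE))
  })
}

.sim_bins <- rbind(  # interior value range for each planted bin
  `-2` = c(-1.6, -1.05), `-1` = c(-0.95, -0.30), `0` = c(-0.20, 0.20),
  `1` = c(0.30, 0.95), `2` = c(1.05, 1.60))

.draw_bin_value <- function(bin) {
  rng <- .sim_bins[as.character(bin), ]
  stats::runif(1L, rng[1L], rng[2L])
}

#' Simulate copy-number profiles with known scores
#'
#' Arms follow the human autosomal layout (chromosomes 1-22; 13, 14, 15, 21
#' and 22 contribute only a q arm). Each chromosome plants a
#' whole-chromosome event (both arms set to the same value at a non-neutral
#' bin) with probability `event_rate * 0.3`; otherwise each arm
#' independently plants an arm event with probability `event_rate` (bins
#' drawn from {-2, -1, 1, 2}). Focal regions plant events at rate
#' `event_rate`. All values are drawn strictly inside their bin, so the
#' truth table is exact by construction and [cnv_score_table()] must
#' reproduce it.
#'
#' @param n_samples Number of profiles.
#' @param event_rate Per-arm/per-region event probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param n_focal Number of focal regions per sample (default 10).
#' @return List with `profiles` (list of [cnv_profile()]) and `truth`
#'   (`data.frame` of the planted component scores).
#' @export
simulate_cnv <- function(n_samples, event_rate, seed = 1L, n_focal = 10L) {
  stopifnot(event_rate >= 0, event_rate <= 1, n_samples >= 1)
  acro <- c(13, 15, 14, 21, 22)
  arms <- unlist(lapply(1:22, function(ch)
    paste0(ch, if (ch %in% acro) "q" else c("p", "q"))))
  focal_ids <- sprintf("FOCAL%02d", seq_len(n_focal))
  event_bins <- c(-2L, -1L, 1L, 2L)

  with_seed(seed, {
    profiles <- vector("list", n_samples)
    truth <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      arm_vals <- stats::setNames(numeric(length(arms)), arms)
      arm_bins <- stats::setNames(integer(length(arms)), arms)
      chrom_sc <- 0L
      for (ch in 1:22) {
        ch_arms <- paste0(ch, if (ch %in% acro) "q" else c("p", "q"))
        if (length(ch_arms) == 2L && stats::runif(1L) < event_rate * 0.3) {
          b <- sample(event_bins, 1L)
          v <- .draw_bin_value(b)
          arm_vals[ch_arms] <- v
          arm_bins[ch_arms] <- b
          chrom_sc <- chrom_sc + b
        } else {
          for (a in ch_arms) {
            b <- if (stats::runif(1L) < event_rate) sample(event_bins, 1L) else 0L
            arm_vals[[a]] <- .draw_bin_value(b)
            arm_bins[[a]] <- b
          }
        }
      }
      focal_bins <- vapply(seq_len(n_focal), function(k)
        if (stats::runif(1L) < event_rate) sample(event_bins, 1L) else 0L, 0L)
      focal_vals <- vapply(focal_bins, .draw_bin_value, 0)
      names(focal_vals) <- focal_ids
      sid <- sprintf("CN%04d", i)
      profiles[[i]] <- cnv_profile(sid, arm_vals, focal_log2 = focal_vals)
      truth[[i]] <- data.frame(
        sample_id = sid, arm_score = sum(arm_bins),
        focal_score = sum(focal_bins), chromosome_score = chrom_sc,
        overall_score = sum(arm_bins) + sum(focal_bins) + chrom_sc,
        stringsAsFactors = FALSE)
    }
    list(profiles = profiles, truth = do.call(rbind, truth))
  })
}

#' Simulate survival records linked to a score
#'
#' Event times are exponential with hazard `h0 * exp(true_loghr * z)` where
#' `z` is the standardised score and `h0 = 0.1`. Censoring times are
#' exponential with rate `h0 * c / (1 - c)` for target censoring fraction
#' `c` (exact at `true_loghr = 0`, approximate otherwise). Age, sex, race
#' and cancer type are drawn from fixed categorical distributions.
#'
#' @param scores Numeric score per subject (e.g. DR scores).
#' @param true_loghr Log hazard ratio per standardised score unit.
#' @param censoring_rate Target censoring fraction in `[0, 1)`.
#' @param seed RNG seed.
#' @return A [clinical_records()] table with a `z` column (the standardised
#'   score used in the hazard).
#' @export
simulate_survival <- function(scores, true_loghr = -0.69, censoring_rate = 0.3,
                              seed = 1L) {
  stopifnot(censoring_rate >= 0, censoring_rate < 1)
  n <- length(scores)
  z <- if (stats::sd(scores) > 0) as.numeric(scale(scores)) else rep(0, n)
  h0 <- 0.1
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = h0 * exp(true_loghr * z))
    if (censoring_rate > 0) {
      t_cens <- stats::rexp(n, rate = h0 * censoring_rate / (1 - censoring_rate))
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    rec <- clinical_records(
      sample_id = sprintf("S%04d", seq_len(n)), time = time, event = event,
      age = round(stats::rnorm(n, 60, 10)),
      sex = sample(c("female", "male"), n, replace = TRUE),
      race = sample(c("asian", "black", "white"), n, replace = TRUE,
                    prob = c(0.1, 0.2, 0.7)),
      cancer_type = sample(c("BRCA", "KIRC", "LIHC", "LUAD"), n, replace = TRUE))
    rec$z <- z
    rec
  })
}
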