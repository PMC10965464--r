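# shared fixture builders; everything is generated in code at test time

# small named expression matrix with deterministic values
tiny_expr <- function(n_genes = 30, n_samples = 4, seed = 11, unit = "TPM",
                      genes = sprintf("G%03d", seq_len(n_genes))) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_genes * n_samples, 2, 1), nrow = n_genes,
              dimnames = list(genes, sprintf("S%02d", seq_len(n_samples))))
  expression_matrix(m, unit = unit)
}

# brute-force ssGSEA enrichment score: materialises both CDFs position by
# position with an explicit double loop, independent of the cumsum path
oracle_es <- function(expr, set_genes, tau) {
  r <- rank(expr, ties.method = "average")
  ids <- names(expr)
  ord <- order(-r, ids, method = "radix")
  n <- length(expr)
  m <- length(set_genes)
  es <- 0
  for (i in seq_len(n)) {
    w_in <- 0; w_tot <- 0; n_out <- 0
    for (j in seq_len(n)) {
      g <- ids[ord[j]]
      if (g %in% set_genes) {
        w_tot <- w_tot + r[ord[j]]^tau
        if (j <= i) w_in <- w_in + r[ord[j]]^tau
      } else if (j <= i) n_out <- n_out + 1
    }
    es <- es + w_in / w_tot - n_out / (n - m)
  }
  unname(es)
}

# product-limit survival estimate at each event time, by hand
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  s <- 1
  out <- NULL
  for (t in unique(time[event == 1])) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}
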