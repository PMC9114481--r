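# Independent oracles used to cross-check package computations.

# Brute-force maximally selected log-rank scan: log-rank scores from the
# Nelson-Aalen estimator as computed by survival::survfit (ctype = 1),
# explicit loops over candidates and samples. Independent of the vectorized
# implementation in optimal_cutpoint().
oracle_cutpoint <- function(values, time, event, min_prop = 0.1) {
  n <- length(values)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, ctype = 1)
  ch <- stats::stepfun(fit$time, c(0, fit$cumhaz))
  a <- event - ch(time)
  a_bar <- mean(a)
  v <- sort(unique(values))
  cands <- (v[-length(v)] + v[-1]) / 2
  best <- NULL
  for (cp in cands) {
    low <- values <= cp
    n1 <- sum(low)
    if (n1 < ceiling(min_prop * n) || (n - n1) < ceiling(min_prop * n)) next
    s <- 0
    for (i in seq_len(n)) if (low[i]) s <- s + a[i]
    e <- n1 * a_bar
    vr <- n1 * (n - n1) / (n * (n - 1)) * sum((a - a_bar)^2)
    st <- if (vr <= 0) 0 else abs(s - e) / sqrt(vr)
    better <- is.null(best) || st > best$stat + 1e-12 ||
      (abs(st - best$stat) <= 1e-12 && abs(n1 - n / 2) < abs(best$n1 - n / 2))
    if (better) best <- list(cutpoint = cp, stat = st, n1 = n1, low = low)
  }
  best
}

# Recount a consensus matrix from stored per-iteration draws and labels.
oracle_consensus <- function(n, draws, labels) {
  co_clustered <- matrix(0, n, n)
  co_sampled <- matrix(0, n, n)
  for (it in seq_along(draws)) {
    idx <- draws[[it]]
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    cl <- labels[[it]]
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (cl[i] == cl[j])
        co_clustered[idx[i], idx[j]] <- co_clustered[idx[i], idx[j]] + 1
    }
  }
  cons <- ifelse(co_sampled > 0, co_clustered / co_sampled, 0)
  diag(cons) <- 1
  cons
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small default cohort used across tests
tiny_config <- function(...) {
  synthetic_config(n_samples = 40, n_lncrna = 60, n_pcg = 30,
                   probes_per_cell_type = 20, n_assoc = 5, seed = 42, ...)
}

lnc_promoter_methylation <- function(sim, flank = 2000) {
  retained <- filter_probes(sim$annotation$probes)
  genes <- sim$annotation$genes
  promoters <- promoter_of(genes[genes$biotype == "lncRNA", ], flank = flank)
  mapping <- map_probes_to_promoters(retained, promoters)
  suppressWarnings(summarize_promoter(sim$beta, mapping))
}
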