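#' Two-group log-rank test
#'
#' Standard log-rank comparison of survival between two groups: at each
#' distinct event time, observed events per group are compared with their
#' hypergeometric expectation; the summed discrepancy gives a chi-square
#' statistic with 1 df (computed via [survival::survdiff()]).
#'
#' @param groups vector of two group labels, one per sample.
#' @param time,event survival times and event indicators (1 = event).
#' @return list: `statistic` (chi-square), `p` (two-sided).
#' @export
logrank_test <- function(groups, time, event) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("need exactly two non-empty groups")
  if (sum(event) < 1) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

# log-rank scores a_i = delta_i - Lambda(t_i) (Nelson-Aalen cumulative
# hazard at each sample's follow-up time); the score-sum over a candidate
# low group, standardized under the permutation hypothesis, is the
# maximally selected rank statistic.
logrank_scores <- function(time, event) {
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  cumhaz <- cumsum(d / n_risk)
  event - cumhaz[match(time, ut)]
}

#' Optimal survival cutpoint (maximally selected log-rank statistic)
#'
#' Scans every threshold between consecutive distinct values that leaves at
#' least `min_prop` of the samples on each side, computes the standardized
#' two-group log-rank statistic for the induced split, and returns the
#' maximizing cutpoint — the surv_cutpoint convention for dichotomizing a
#' continuous marker. Ties in the maximum are broken toward the more
#' balanced split.
#'
#' @param values per-sample marker (e.g. a lncRNA's promoter methylation).
#' @param time,event survival times and event indicators.
#' @param min_prop minimum fraction of samples per group (default 0.1).
#' @return list of class `cutpoint_result`: `cutpoint` (midpoint between
#'   the flanking distinct values), `max_stat` (standardized statistic),
#'   `groups` (named `"low"`/`"high"` per sample), and the scan table
#'   `candidates` (`cutpoint`, `stat`, `n_low`).
#' @export
optimal_cutpoint <- function(values, time, event, min_prop = 0.1) {
  n <- length(values)
  stopifnot(length(time) == n, length(event) == n)
  if (length(unique(values)) < 2) stop("need >= 2 distinct values")
  if (sum(event) < 1) stop("need at least one event")
  a <- logrank_scores(time, event)
  a_bar <- mean(a)
  ss <- sum((a - a_bar)^2)
  v <- sort(unique(values))
  min_n <- ceiling(min_prop * n)
  cand <- (v[-length(v)] + v[-1]) / 2
  n_low <- vapply(cand, function(cp) sum(values <= cp), integer(1))
  ok <- n_low >= min_n & (n - n_low) >= min_n
  if (!any(ok)) stop("no cutpoint satisfies min_prop = ", min_prop)
  cand <- cand[ok]; n_low <- n_low[ok]
  stat <- vapply(seq_along(cand), function(i) {
    low <- values <= cand[i]
    s <- sum(a[low])
    e <- n_low[i] * a_bar
    vr <- n_low[i] * (n - n_low[i]) / (n * (n - 1)) * ss
    if (vr <= 0) 0 else abs(s - e) / sqrt(vr)
  }, numeric(1))
  # complementary splits yield the same standardized statistic up to
  # floating point, so ties are resolved at tolerance: prefer the more
  # balanced split, then the smallest cutpoint
  tied <- which(stat >= max(stat) - 1e-12)
  tied <- tied[order(abs(n_low[tied] - n / 2), cand[tied])]
  best <- tied[1]
  groups <- stats::setNames(ifelse(values <= cand[best], "low", "high"),
                            names(values))
  structure(list(cutpoint = cand[best], max_stat = max(stat),
                 groups = groups,
                 candidates = data.frame(cutpoint = cand, stat = stat,
                                         n_low = n_low)),
            class = "cutpoint_result")
}

#' Nested Cox models and likelihood-ratio increments
#'
#' Fits a Cox proportional-hazards model (Efron tie handling) for each tier
#' of a strictly nested covariate sequence — conventionally
#' clinical (age, sex), then + WHO diagnostic category, then + methylation
#' subtype — and tests each increment by the likelihood-ratio chi-square
#' with df equal to the number of added coefficients. Quantifies the
#' prognostic value the methylation subtypes add beyond routine clinical
#' covariates.
#'
#' @param surv data frame with `time`, `event` and every covariate named in
#'   `tiers`; character covariates are treated as factors.
#' @param tiers list of covariate-name vectors, each a strict superset of
#'   the previous (default the three-tier clinical/WHO/cluster sequence).
#' @return data frame, one row per tier: `tier` (covariates), `loglik`,
#'   `n_coef`, `delta_lr` (2 * loglik increment; `NA` for the first tier),
#'   `df`, `p` (chi-square upper tail).
#' @export
nested_cox_lr <- function(surv,
                          tiers = list(c("age", "sex"),
                                       c("age", "sex", "who_category"),
                                       c("age", "sex", "who_category",
                                         "lncrna_cluster"))) {
  stopifnot(all(c("time", "event") %in% names(surv)))
  for (i in seq_along(tiers)[-1])
    if (!all(tiers[[i - 1]] %in% tiers[[i]]))
      stop("tiers must be strictly nested")
  for (v in unique(unlist(tiers)))
    if (is.character(surv[[v]]) || length(unique(surv[[v]])) <= 5)
      surv[[v]] <- as.factor(surv[[v]])
  fits <- lapply(tiers, function(covs) {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covs, collapse = " + ")))
    survival::coxph(f, data = surv, ties = "efron")
  })
  loglik <- vapply(fits, function(f) f$loglik[2], numeric(1))
  n_coef <- vapply(fits, function(f) sum(!is.na(stats::coef(f))), integer(1))
  delta_lr <- c(NA, 2 * diff(loglik))
  df <- c(NA, diff(n_coef))
  p <- ifelse(is.na(df), NA,
              stats::pchisq(delta_lr, df = pmax(df, 1), lower.tail = FALSE))
  p[!is.na(df) & df == 0] <- NA
  data.frame(tier = vapply(tiers, paste, "", collapse = "+"),
             loglik = loglik, n_coef = n_coef, delta_lr = delta_lr,
             df = df, p = p, stringsAsFactors = FALSE)
}

#' Kaplan-Meier curve coordinates per group
#'
#' Step-function coordinates of the Kaplan-Meier estimator, exportable for
#' plotting.
#'
#' @param groups group label per sample.
#' @param time,event survival data.
#' @return data frame: `group`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_coordinates <- function(groups, time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ groups)
  strata <- rep(names(fit$strata), fit$strata)
  data.frame(group = sub("^groups=", "", strata), time = fit$time,
             surv = fit$surv, n_risk = fit$n.risk, n_event = fit$n.event,
             stringsAsFactors = FALSE)
}
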