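#' Select the most variable probes
#'
#' Ranks probes by standard deviation over non-missing samples and keeps the
#' top fraction (the conventional feature selection before methylation-based
#' subtyping). Boundary ties are broken by probe-id lexicographic order so
#' the selection is deterministic.
#'
#' @param beta samples x probes matrix.
#' @param top_fraction fraction of probes to retain, in `(0, 1]`
#'   (default 0.05, i.e. the top 5%).
#' @return character vector of retained probe ids, with attribute
#'   `sd_cutoff` (the smallest retained SD).
#' @export
select_variable_probes <- function(beta, top_fraction = 0.05) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  if (nrow(beta) < 2) stop("need at least 2 samples")
  sds <- apply(beta, 2, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  if (all(sds == 0)) warning("all probes have zero variance")
  n_keep <- ceiling(top_fraction * length(sds))
  ord <- order(-sds, names(sds))
  keep <- names(sds)[ord[seq_len(n_keep)]]
  attr(keep, "sd_cutoff") <- min(sds[keep])
  keep
}

#' Resampled consensus clustering with PAC model selection
#'
#' For each candidate `k`, repeatedly subsamples `resample * n` samples
#' without replacement, clusters them with k-means under the Pearson
#' correlation geometry (rows are z-scored, so Euclidean k-means is
#' equivalent to clustering on `1 - r`), and accumulates how often each
#' sample pair lands in the same cluster relative to how often it was
#' co-sampled. The final assignment at each `k` cuts an average-linkage
#' dendrogram of `1 - consensus`; the number of clusters is chosen by
#' minimizing the proportion of ambiguous clustering (PAC), the fraction of
#' consensus entries falling strictly inside `pac_window`.
#'
#' @param data samples x features numeric matrix.
#' @param k_range integer vector of candidate cluster counts (default 2:10).
#' @param iterations resampling iterations per `k` (default 50).
#' @param resample subsampling fraction (default 0.8).
#' @param seed integer seed; the same subsamples are reused across `k`.
#' @param pac_window consensus interval whose occupancy defines PAC
#'   (default `c(0.1, 0.9)`).
#' @param keep_draws store per-iteration subsample indices and cluster
#'   labels (for auditing the consensus counts).
#' @return object of class `consensus_result`: list with `k_range`,
#'   `consensus` (list of samples x samples matrices), `assignments`
#'   (samples x k matrix of labels), `pac` (named vector), `chosen_k`,
#'   `assignment` (labels at `chosen_k`), and optionally `draws`.
#' @export
consensus_cluster <- function(data, k_range = 2:10, iterations = 50,
                              resample = 0.8, seed = 1,
                              pac_window = c(0.1, 0.9), keep_draws = FALSE) {
  n <- nrow(data)
  if (resample <= 0 || resample > 1) stop("resample must lie in (0, 1]")
  m <- floor(resample * n)
  k_range <- sort(unique(as.integer(k_range)))
  bad_k <- k_range[k_range > m]
  if (length(bad_k)) {
    warning("skipping k > resampled size: ", paste(bad_k, collapse = ", "))
    k_range <- k_range[k_range <= m]
  }
  if (length(k_range) == 0) stop("no feasible k in k_range")
  if (max(k_range) > n) stop("k exceeds the number of samples")
  if (is.null(rownames(data))) rownames(data) <- paste0("S", seq_len(n))

  # Pearson geometry: z-score each sample's feature vector
  z <- t(scale(t(data)))
  z[is.na(z)] <- 0

  set.seed(seed)
  draws <- lapply(seq_len(iterations), function(i) sort(sample(n, m)))
  co_sampled <- matrix(0, n, n)
  for (idx in draws)
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1

  consensus <- list(); assignments <- matrix(NA_integer_, n, length(k_range),
                                             dimnames = list(rownames(data),
                                                             k_range))
  labels_all <- list()
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    co_clustered <- matrix(0, n, n)
    labels_k <- list()
    for (it in seq_len(iterations)) {
      idx <- draws[[it]]
      cl <- stats::kmeans(z[idx, , drop = FALSE], centers = k,
                          nstart = 5, iter.max = 30)$cluster
      for (g in seq_len(k)) {
        members <- idx[cl == g]
        co_clustered[members, members] <- co_clustered[members, members] + 1
      }
      if (keep_draws) labels_k[[it]] <- cl
    }
    cons <- ifelse(co_sampled > 0, co_clustered / co_sampled, 0)
    diag(cons) <- 1
    dimnames(cons) <- list(rownames(data), rownames(data))
    consensus[[as.character(k)]] <- cons
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    assignments[, ki] <- stats::cutree(hc, k = k)
    if (keep_draws) labels_all[[as.character(k)]] <- labels_k
  }

  pac <- vapply(consensus, function(cons) {
    v <- cons[upper.tri(cons)]
    mean(v > pac_window[1] & v < pac_window[2])
  }, numeric(1))
  # ties at the minimum go to the largest k: coarse merges of a finer
  # stable partition are themselves stable, and the finest unambiguous
  # partition is the one sought
  chosen_k <- max(k_range[pac <= min(pac) + 1e-12])

  out <- list(k_range = k_range, consensus = consensus,
              assignments = assignments, pac = pac, chosen_k = chosen_k,
              assignment = assignments[, as.character(chosen_k)])
  if (keep_draws) out$draws <- list(idx = draws, labels = labels_all)
  class(out) <- "consensus_result"
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over k =", paste(range(x$k_range), collapse = ".."),
      "\nPAC:", paste(sprintf("k=%s %.3f", names(x$pac), x$pac),
                      collapse = ", "),
      "\nchosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' Sample-sample Pearson correlation of promoter methylation
#'
#' @param pm samples x genes matrix.
#' @return samples x samples Pearson correlation matrix (pairwise-complete
#'   on missing values, diagonal 1). Zero-variance samples yield `NA`
#'   correlations with a warning.
#' @export
sample_correlation <- function(pm) {
  if (ncol(pm) < 2) stop("need at least 2 genes")
  sds <- apply(pm, 1, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds)))
    warning("zero-variance sample(s): ",
            paste(rownames(pm)[sds == 0 | is.na(sds)], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(pm), use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}
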