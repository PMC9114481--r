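#' Reference-based cell-type deconvolution of a methylation profile
#'
#' Estimates the cell-type composition of a bulk beta-value profile from a
#' reference signature matrix. The default solver is non-negative least
#' squares on raw beta values; `nu_svr` fits a linear nu-support-vector
#' regression on z-scored profile and signature (the CIBERSORT convention),
#' trying `nu` in {0.25, 0.5, 0.75} and keeping the fit with the smallest
#' reconstruction RMSE, with negative coefficients clipped to zero.
#' Coefficients are renormalized to sum to 1 (clip first, then normalize).
#' No quantile normalization is applied.
#'
#' @param profile named per-probe beta vector, or a samples x probes matrix
#'   (rows deconvolved independently).
#' @param signature probes x cell-types reference matrix
#'   (see [generate_signature()]).
#' @param method `"nnls"` (default) or `"nu_svr"`.
#' @param min_overlap minimum fraction of signature probes that must be
#'   present in the profile (default 0.8); missing signature probes are
#'   dropped pairwise.
#' @return For a vector profile, a list of class `cell_fractions`:
#'   `fractions` (named, non-negative, sum 1, or all `NA` with
#'   `degenerate = TRUE` when every coefficient is zero), `rmse` and `corr`
#'   of the reconstruction on the fitting scale, `method`. For a matrix,
#'   a data frame with one row per sample (fraction columns plus `rmse`,
#'   `corr`).
#' @export
deconvolve <- function(profile, signature, method = c("nnls", "nu_svr"),
                       min_overlap = 0.8) {
  method <- match.arg(method)
  if (is.matrix(profile)) {
    rows <- lapply(seq_len(nrow(profile)), function(i)
      deconvolve(profile[i, ], signature, method, min_overlap))
    out <- data.frame(do.call(rbind, lapply(rows, function(r) r$fractions)),
                      rmse = vapply(rows, `[[`, 0, "rmse"),
                      corr = vapply(rows, `[[`, 0, "corr"),
                      check.names = FALSE)
    rownames(out) <- rownames(profile)
    return(out)
  }
  shared <- intersect(rownames(signature), names(profile))
  shared <- shared[!is.na(profile[shared])]
  coverage <- length(shared) / nrow(signature)
  if (coverage < min_overlap)
    stop(sprintf("only %.0f%% of signature probes present (need >= %.0f%%)",
                 100 * coverage, 100 * min_overlap))
  s <- signature[shared, , drop = FALSE]
  y <- profile[shared]

  if (method == "nnls") {
    coef <- pracma::lsqnonneg(s, y)$x
    fitted <- drop(s %*% coef)
    obs <- y
  } else {
    # global (not per-column) standardization: per-column scaling would
    # rescale each cell type's coefficient by its column SD
    zs <- (s - mean(s)) / stats::sd(as.vector(s))
    zy <- (y - mean(y)) / stats::sd(y)
    best <- NULL
    for (nu in c(0.25, 0.5, 0.75)) {
      fit <- e1071::svm(x = zs, y = zy, type = "nu-regression",
                        kernel = "linear", nu = nu, scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV)
      w <- pmax(w, 0)
      fz <- drop(zs %*% w)
      rmse <- sqrt(mean((zy - fz)^2))
      if (is.null(best) || rmse < best$rmse)
        best <- list(coef = w, fitted = fz, rmse = rmse)
    }
    coef <- best$coef
    fitted <- best$fitted
    obs <- zy
  }
  names(coef) <- colnames(signature)
  total <- sum(coef)
  if (total <= 0) {
    return(structure(list(fractions = stats::setNames(
      rep(NA_real_, ncol(signature)), colnames(signature)),
      rmse = NA_real_, corr = NA_real_, degenerate = TRUE,
      method = method), class = "cell_fractions"))
  }
  structure(list(fractions = coef / total,
                 rmse = sqrt(mean((obs - fitted)^2)),
                 corr = suppressWarnings(stats::cor(obs, fitted)),
                 degenerate = FALSE, method = method),
            class = "cell_fractions")
}

#' Permutation significance of a deconvolution fit
#'
#' The empirical null redistributes the profile's beta values across probes
#' (the signature fixed) and re-runs the deconvolution; the p-value is the
#' add-one estimator `(1 + #(null corr >= observed corr)) / (n_perm + 1)`,
#' so its smallest attainable value is `1 / (n_perm + 1)`.
#'
#' @inheritParams deconvolve
#' @param n_perm number of permutations (default 100; must be >= 10).
#' @param seed integer seed.
#' @return list: `p`, `observed_corr`, `null_corr` (length `n_perm`).
#' @export
permutation_p <- function(profile, signature, n_perm = 100, seed = 1,
                          method = "nnls", min_overlap = 0.8) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  obs <- deconvolve(profile, signature, method, min_overlap)
  if (isTRUE(obs$degenerate)) stop("observed deconvolution is degenerate")
  set.seed(seed)
  null_corr <- vapply(seq_len(n_perm), function(i) {
    perm <- stats::setNames(sample(profile), names(profile))
    d <- deconvolve(perm, signature, method, min_overlap)
    if (isTRUE(d$degenerate) || is.na(d$corr)) -Inf else d$corr
  }, numeric(1))
  list(p = (1 + sum(null_corr >= obs$corr)) / (n_perm + 1),
       observed_corr = obs$corr, null_corr = null_corr)
}

#' Mean-methylation signature scores
#'
#' Scores each sample against named CpG sets (immune checkpoints, cytolytic
#' activity, HLA, interferon response, TILs, treatment-response panels, ...)
#' as the mean beta over the set's probes present in the matrix.
#'
#' @param beta samples x probes matrix.
#' @param cpg_sets named list of probe-id vectors.
#' @return samples x signatures matrix of mean betas; a set with no probe in
#'   the matrix yields `NA` with a warning.
#' @export
signature_score <- function(beta, cpg_sets) {
  stopifnot(is.list(cpg_sets), !is.null(names(cpg_sets)))
  scores <- vapply(names(cpg_sets), function(nm) {
    probes <- intersect(cpg_sets[[nm]], colnames(beta))
    if (length(probes) == 0) {
      warning("signature set '", nm, "' has no probes in the matrix")
      return(rep(NA_real_, nrow(beta)))
    }
    rowMeans(beta[, probes, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(beta)))
  matrix(scores, nrow = nrow(beta),
         dimnames = list(rownames(beta), names(cpg_sets)))
}

#' Cell fractions by cluster with one-way ANOVA
#'
#' Summarizes deconvolved fractions per subtype and tests, per cell type,
#' whether mean infiltration differs across subtypes (one-way ANOVA).
#' Clusters with fewer than 2 samples are excluded with a warning.
#'
#' @param fractions samples x cell-types matrix (or the data frame returned
#'   by [deconvolve()] on a matrix — fraction columns are used).
#' @param clusters named vector sample -> cluster.
#' @return list: `means` (clusters x cell-types), `anova` (data frame with
#'   `cell_type`, `F`, `p`).
#' @export
fractions_by_cluster <- function(fractions, clusters) {
  if (is.data.frame(fractions))
    fractions <- as.matrix(fractions[, setdiff(names(fractions),
                                               c("rmse", "corr", "perm_p"))])
  cl <- clusters[rownames(fractions)]
  sizes <- table(cl)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding cluster(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(cl %in% small)
    fractions <- fractions[keep, , drop = FALSE]
    cl <- cl[keep]
  }
  if (length(unique(cl)) < 2) stop("need >= 2 clusters with >= 2 samples")
  cl <- factor(cl)
  means <- t(vapply(levels(cl), function(g)
    colMeans(fractions[cl == g, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(fractions))))
  anova <- do.call(rbind, lapply(colnames(fractions), function(ct) {
    y <- fractions[, ct]
    if (stats::var(y, na.rm = TRUE) == 0)
      return(data.frame(cell_type = ct, F = 0, p = 1))
    a <- stats::anova(stats::aov(y ~ cl))
    data.frame(cell_type = ct, F = a$`F value`[1], p = a$`Pr(>F)`[1])
  }))
  rownames(anova) <- NULL
  list(means = means, anova = anova)
}
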