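#' Generate a synthetic cell-type reference signature matrix
#'
#' Each cell type is given a block of `probes_per_cell_type` discriminating
#' probes: beta near 0.9 in that type and near 0.1 in every other (small
#' uniform jitter breaks exact collinearity). The construction guarantees
#' full column rank and low pairwise column correlation, mimicking a
#' methylation deconvolution reference such as an immune/stromal CpG panel.
#'
#' @param config a [synthetic_config()].
#' @return probes x cell-types numeric matrix with probe-id rownames and
#'   cell-type colnames; attributes `condition_number` (2-norm kappa).
#' @export
generate_signature <- function(config) {
  validate_synthetic_config(config)
  if (config$n_cell_types < 2) stop("need at least 2 cell types")
  set.seed(derive_seed(config$seed, "signature"))
  k <- config$n_cell_types
  ppc <- config$probes_per_cell_type
  p <- k * ppc
  if (p < k) stop("fewer signature probes than cell types: rank deficient")
  sig <- matrix(0.1, nrow = p, ncol = k,
                dimnames = list(sprintf("sig%05d", seq_len(p)),
                                cell_type_names(k)))
  for (j in seq_len(k)) sig[(j - 1) * ppc + seq_len(ppc), j] <- 0.9
  sig <- clip01(sig + matrix(stats::runif(p * k, -0.05, 0.05), p, k))
  if (qr(sig)$rank < k) stop("signature matrix is rank deficient")
  attr(sig, "condition_number") <- kappa(sig, exact = TRUE)
  sig
}

#' Simulate a beta-value matrix with planted truth
#'
#' Builds the full synthetic cohort: a samples x probes matrix of array beta
#' values plus the planted ground truth every downstream stage is tested
#' against.
#'
#' Promoter probes draw `Beta(mu * phi, (1 - mu) * phi)` noise around a
#' per-gene target `mu`: 0.85 for planted hyper-methylated lncRNAs, 0.15
#' for hypo, 0.5 for inter. Inter lncRNAs not used for association planting
#' are cluster-informative: their probes receive a cluster-specific shift of
#' `+/- cluster_shift` (a non-constant sign pattern across clusters, so the
#' planted category is never overturned). Association-planted lncRNAs get a
#' per-sample `mu` that is a monotone (Gaussian-copula) function of one
#' cell-type fraction, calibrated so the Spearman correlation is
#' approximately `assoc_rho`. Signature probes are the mixture of the
#' reference profiles, `mixture %*% t(signature)`, under the same Beta noise.
#' `beta_precision = Inf` switches noise off entirely.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort`:
#'   \describe{
#'     \item{beta}{samples x probes matrix in `[0, 1]`.}
#'     \item{truth}{list with `cluster_of_sample`, `category_of_lncrna`,
#'       `mixture_of_sample` (rows sum to 1), `planted_assoc`
#'       (`gene_id`, `cell_type`, `rho`), `cluster_informative`,
#'       `survival_params`, `linkage`.}
#'     \item{annotation}{output of [generate_annotation()].}
#'     \item{signature}{output of [generate_signature()].}
#'   }
#' @export
simulate_beta <- function(config) {
  validate_synthetic_config(config)
  anno <- generate_annotation(config)
  sig <- generate_signature(config)
  set.seed(derive_seed(config$seed, "beta"))

  n <- config$n_samples
  phi <- config$beta_precision
  sample_ids <- sprintf("S%04d", seq_len(n))
  cluster <- sample(rep(seq_len(config$n_clusters), length.out = n))
  names(cluster) <- sample_ids

  lnc <- anno$genes$gene_id[anno$genes$biotype == "lncRNA"]
  n_lnc <- length(lnc)
  n_hyper <- round(config$frac_hyper * n_lnc)
  n_hypo <- round(config$frac_hypo * n_lnc)
  category <- sample(rep(c("hyper", "hypo", "inter"),
                         c(n_hyper, n_hypo, n_lnc - n_hyper - n_hypo)))
  names(category) <- lnc

  inter <- lnc[category == "inter"]
  n_assoc <- config$n_assoc
  if (n_assoc > length(inter)) {
    warning("n_assoc reduced to the number of inter-methylated lncRNAs (",
            length(inter), ")")
    n_assoc <- length(inter)
  }
  assoc_genes <- if (n_assoc > 0) sample(inter, n_assoc) else character(0)
  informative <- setdiff(inter, assoc_genes)

  # mixtures: symmetric Dirichlet rows
  g <- matrix(stats::rgamma(n * config$n_cell_types,
                            shape = config$dirichlet_alpha), nrow = n)
  mixture <- g / rowSums(g)
  dimnames(mixture) <- list(sample_ids, colnames(sig))

  planted_assoc <- if (n_assoc > 0) {
    data.frame(gene_id = assoc_genes,
               cell_type = sample(colnames(sig), n_assoc, replace = TRUE),
               rho = config$assoc_rho *
                 rep_len(c(1, -1), n_assoc)[sample(n_assoc)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), cell_type = character(0),
               rho = numeric(0))
  }

  # non-constant cluster sign patterns for informative genes
  signs <- NULL
  if (length(informative) > 0 && config$n_clusters >= 2 &&
      config$cluster_shift > 0) {
    signs <- matrix(sample(c(-1, 1), length(informative) * config$n_clusters,
                           replace = TRUE),
                    nrow = length(informative),
                    dimnames = list(informative, NULL))
    flat <- abs(rowSums(signs)) == config$n_clusters
    while (any(flat)) {
      j <- sample(config$n_clusters, 1)
      signs[flat, j] <- -signs[flat, j]
      flat <- abs(rowSums(signs)) == config$n_clusters
    }
  }

  # per-gene, per-sample target mu for promoter probes
  genes <- anno$genes
  base_mu <- c(hyper = 0.85, hypo = 0.15, inter = 0.5)
  mu_gene <- matrix(0.5, nrow = n, ncol = nrow(genes),
                    dimnames = list(sample_ids, genes$gene_id))
  is_lnc <- genes$biotype == "lncRNA"
  mu_gene[, is_lnc] <- rep(base_mu[category[genes$gene_id[is_lnc]]],
                           each = n)
  if (!is.null(signs))
    mu_gene[, informative] <- 0.5 +
      config$cluster_shift * t(signs[, cluster, drop = FALSE])
  if (n_assoc > 0) {
    rho_latent <- 2 * sin(pi * abs(config$assoc_rho) / 6)
    for (i in seq_len(n_assoc)) {
      f <- mixture[, planted_assoc$cell_type[i]]
      zf <- stats::qnorm((rank(f, ties.method = "average") - 0.5) / n)
      zg <- sign(planted_assoc$rho[i]) * rho_latent * zf +
        sqrt(1 - rho_latent^2) * stats::rnorm(n)
      mu_gene[, planted_assoc$gene_id[i]] <- 0.3 + 0.4 * stats::pnorm(zg)
    }
  }

  mu_probe <- mu_gene[, anno$probes$gene_id, drop = FALSE]
  colnames(mu_probe) <- anno$probes$probe_id
  mu_sig <- clip01(mixture %*% t(sig))
  mu <- cbind(mu_probe, mu_sig)
  beta <- if (is.infinite(phi)) mu else {
    mu_c <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
    matrix(stats::rbeta(length(mu_c), mu_c * phi, (1 - mu_c) * phi),
           nrow = n, dimnames = dimnames(mu))
  }

  lambda0 <- 0.1
  hazard <- rep(lambda0, config$n_clusters)
  hazard[config$n_clusters] <- lambda0 * config$hazard_ratio
  truth <- list(cluster_of_sample = cluster,
                category_of_lncrna = category,
                mixture_of_sample = mixture,
                planted_assoc = planted_assoc,
                cluster_informative = informative,
                survival_params = data.frame(cluster = seq_along(hazard),
                                             hazard = hazard),
                linkage = anno$linkage)
  structure(list(beta = beta, truth = truth, annotation = anno,
                 signature = sig, config = config),
            class = "synthetic_cohort")
}

#' Simulate survival outcomes from planted clusters
#'
#' Event times are exponential with cluster-specific hazard: baseline 0.1
#' per time unit, multiplied by `hazard_ratio` in the last planted cluster.
#' Censoring times are independent uniform on `(0, tau)` with `tau` solved
#' numerically so the expected censored fraction matches `censor_rate`.
#' Age and sex are simulated independent of outcome, as is a 3-level WHO
#' diagnostic category, so nested Cox models have a calibrated null.
#'
#' @param truth the `truth` element of a [simulate_beta()] cohort.
#' @param config the matching [synthetic_config()].
#' @return data frame: `sample_id`, `time`, `event` (0/1), `age`, `sex`
#'   (0/1), `who_category`, `lncrna_cluster` (the planted cluster).
#' @export
simulate_survival <- function(truth, config) {
  validate_synthetic_config(config)
  if (is.null(truth$cluster_of_sample)) stop("truth lacks cluster assignment")
  set.seed(derive_seed(config$seed, "survival"))
  cluster <- truth$cluster_of_sample
  n <- length(cluster)
  hz <- truth$survival_params$hazard[cluster]
  t_event <- stats::rexp(n, rate = hz)
  if (config$censor_rate > 0) {
    w <- tabulate(cluster, nbins = nrow(truth$survival_params)) / n
    pc <- function(tau) {
      sum(w * (1 - exp(-truth$survival_params$hazard * tau)) /
            (truth$survival_params$hazard * tau)) - config$censor_rate
    }
    tau <- stats::uniroot(pc, c(1e-8, 1e8), tol = 1e-10)$root
    t_cens <- stats::runif(n, 0, tau)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  data.frame(sample_id = names(cluster), time = time, event = event,
             age = pmax(0.1, stats::rnorm(n, mean = 8, sd = 4)),
             sex = stats::rbinom(n, 1, 0.5),
             who_category = sample(paste0("WHO", 1:3), n, replace = TRUE),
             lncrna_cluster = unname(cluster),
             stringsAsFactors = FALSE)
}
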