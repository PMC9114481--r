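test_that("deconvolution recovers exact and pure mixtures", {
  sig <- generate_signature(tiny_config())
  y <- drop(sig %*% c(0.3, 0.7, rep(0, 8)))
  names(y) <- rownames(sig)
  d <- deconvolve(y, sig)
  expect_equal(unname(d$fractions), c(0.3, 0.7, rep(0, 8)), tolerance = 1e-6)
  expect_lt(d$rmse, 1e-10)

  pure <- setNames(sig[, "CD8"], rownames(sig))
  dp <- deconvolve(pure, sig)
  expect_equal(unname(dp$fractions[["CD8"]]), 1, tolerance = 1e-6)
})

test_that("noisy Dirichlet mixtures are recovered within tolerance", {
  set.seed(31)
  sig <- generate_signature(tiny_config())
  n <- 30
  w <- matrix(rgamma(n * 10, 1), n)
  w <- w / rowSums(w)
  prof <- w %*% t(sig) + matrix(rnorm(n * nrow(sig), 0, 0.02), n)
  colnames(prof) <- rownames(sig)
  est <- deconvolve(prof, sig)
  est_mat <- as.matrix(est[, colnames(sig)])
  rmse <- sqrt(colMeans((est_mat - w)^2))
  expect_true(all(rmse < 0.05))
  expect_true(all(abs(rowSums(est_mat) - 1) < 1e-9))
})

test_that("nnls and nu-SVR agree on noiseless mixtures", {
  set.seed(8)
  sig <- generate_signature(tiny_config())
  w <- rgamma(10, 1); w <- w / sum(w)
  y <- setNames(drop(sig %*% w), rownames(sig))
  d1 <- deconvolve(y, sig, method = "nnls")
  d2 <- deconvolve(y, sig, method = "nu_svr")
  expect_equal(d1$fractions, d2$fractions, tolerance = 1e-3)
})

test_that("insufficient probe overlap raises a coverage error", {
  sig <- generate_signature(tiny_config())
  y <- setNames(drop(sig %*% rep(0.1, 10)), rownames(sig))
  short <- y[seq_len(floor(0.5 * length(y)))]
  expect_error(deconvolve(short, sig), "signature probes present")
  # 80% coverage passes
  ok <- y[seq_len(ceiling(0.8 * length(y)))]
  expect_s3_class(deconvolve(ok, sig), "cell_fractions")
})

test_that("permutation p attains its add-one bound on true mixtures", {
  set.seed(12)
  sig <- generate_signature(tiny_config())
  w <- rgamma(10, 1); w <- w / sum(w)
  y <- setNames(pmin(pmax(drop(sig %*% w) + rnorm(nrow(sig), 0, 0.01), 0), 1),
                rownames(sig))
  pp <- permutation_p(y, sig, n_perm = 100, seed = 4)
  expect_equal(pp$p, 1 / 101, tolerance = 1e-12)
  expect_gte(pp$p, 1 / 101)
  expect_error(permutation_p(y, sig, n_perm = 5), "n_perm")
})

test_that("random profiles are rarely significant under permutation", {
  sig <- generate_signature(synthetic_config(n_samples = 40, n_lncrna = 60,
                                             n_pcg = 30, n_assoc = 5,
                                             probes_per_cell_type = 10,
                                             seed = 42))
  set.seed(17)
  ps <- vapply(1:60, function(i) {
    y <- setNames(runif(nrow(sig)), rownames(sig))
    permutation_p(y, sig, n_perm = 50, seed = i)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.85)
})

test_that("signature scores are set means with missing-set warnings", {
  beta <- matrix(c(0.2, 0.4, 0.6, 0.8, 0.1, 0.3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("p1", "p2", "p3")))
  sc <- signature_score(beta, list(one = "p1", three = c("p1", "p2", "p3")))
  expect_equal(sc[, "one"], c(s1 = 0.2, s2 = 0.8))
  expect_equal(sc["s1", "three"], 0.4)
  expect_warning(s2 <- signature_score(beta, list(gone = "px")), "no probes")
  expect_true(all(is.na(s2)))
})

test_that("fraction ANOVA: nulls at F=0, planted shifts detected, F = t^2", {
  cl <- setNames(rep(c(1, 2), each = 25), paste0("s", 1:50))
  same <- matrix(0.1, 50, 3,
                 dimnames = list(names(cl), c("CD8", "CD14", "Treg")))
  fb <- fractions_by_cluster(same, cl)
  expect_equal(fb$anova$F, rep(0, 3))
  expect_equal(fb$anova$p, rep(1, 3))

  set.seed(23)
  fr <- matrix(rnorm(150, 0.2, 0.05), 50, 3,
               dimnames = list(names(cl), c("CD8", "CD14", "Treg")))
  fr[cl == 2, "CD8"] <- fr[cl == 2, "CD8"] + 0.3
  fb2 <- fractions_by_cluster(fr, cl)
  expect_lt(fb2$anova$p[fb2$anova$cell_type == "CD8"], 1e-6)
  expect_equal(fb2$means["2", "CD8"] - fb2$means["1", "CD8"], 0.3,
               tolerance = 0.05)

  # two-group ANOVA F equals the squared pooled-variance t statistic
  tt <- t.test(fr[cl == 1, "CD14"], fr[cl == 2, "CD14"], var.equal = TRUE)
  expect_equal(fb2$anova$F[fb2$anova$cell_type == "CD14"],
               unname(tt$statistic)^2, tolerance = 1e-9)

  expect_warning(
    fractions_by_cluster(fr, setNames(c(rep(1, 25), rep(2, 24), 3),
                                      names(cl))),
    "excluding")
})
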