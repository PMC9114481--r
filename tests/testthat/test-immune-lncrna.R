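test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # never below raw p; monotone over the sorted order
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_equal(bh_adjust(p, "bonferroni"), pmin(p * 50, 1))
})

test_that("Spearman associations are rank-invariant and threshold-conjunctive", {
  n <- 30
  set.seed(3)
  meth <- runif(n)
  pm <- cbind(gene1 = meth)
  rownames(pm) <- paste0("s", 1:n)
  # fraction strictly increasing in methylation through a monotone map
  fr <- cbind(CD8 = exp(3 * meth))
  rownames(fr) <- rownames(pm)
  cl <- setNames(rep(1, n), rownames(pm))
  rec <- spearman_assoc(pm, fr, cl)
  expect_equal(rec$rho, 1)
  expect_true(rec$called)

  # invariance to strictly monotone transforms of either variable
  pm3 <- cbind(gene1 = meth^3); rownames(pm3) <- rownames(pm)
  rec2 <- spearman_assoc(pm3, fr, cl)
  rec3 <- spearman_assoc(pm, cbind(CD8 = log(fr[, 1])), cl)
  expect_equal(rec2$rho, rec$rho)
  expect_equal(rec3$rho, rec$rho)

  # |rho| <= threshold is never called no matter the p-value
  set.seed(5)
  big_pm <- matrix(runif(5000), 1000, 5,
                   dimnames = list(paste0("s", 1:1000), paste0("g", 1:5)))
  big_fr <- cbind(CD8 = 0.25 * scale(big_pm[, 1])[, 1] + rnorm(1000))
  rownames(big_fr) <- rownames(big_pm)
  recs <- spearman_assoc(big_pm, big_fr,
                         setNames(rep(1, 1000), rownames(big_pm)))
  expect_true(all(!recs$called[abs(recs$rho) <= 0.3]))

  # constant methylation yields NA rho, never called
  pm_c <- cbind(gene1 = rep(0.5, n)); rownames(pm_c) <- rownames(pm)
  rec_c <- spearman_assoc(pm_c, fr, cl)
  expect_true(is.na(rec_c$rho))
  expect_false(rec_c$called)

  # undersized clusters are skipped with a warning
  expect_warning(
    spearman_assoc(pm, fr, setNames(c(rep(1, 25), 2:6), rownames(pm))),
    "skipping")
})

test_that("planted correlations are detected with high sensitivity", {
  cfg <- synthetic_config(n_samples = 100, n_clusters = 1, n_lncrna = 60,
                          n_pcg = 10, n_assoc = 10, assoc_rho = 0.5,
                          seed = 77)
  sim <- simulate_beta(cfg)
  pm <- lnc_promoter_methylation(sim)
  rec <- spearman_assoc(pm, sim$truth$mixture_of_sample,
                        sim$truth$cluster_of_sample)
  pl <- sim$truth$planted_assoc
  hit <- mapply(function(g, ct) {
    r <- rec[rec$gene_id == g & rec$cell_type == ct, ]
    nrow(r) == 1 && r$called
  }, pl$gene_id, pl$cell_type)
  expect_gte(mean(hit), 0.8)
  # planted sign is recovered
  obs_rho <- mapply(function(g, ct)
    rec$rho[rec$gene_id == g & rec$cell_type == ct], pl$gene_id, pl$cell_type)
  expect_true(all(sign(obs_rho) == sign(pl$rho)))
})

test_that("category enrichment reproduces exact hypergeometric values", {
  # 2x2 table [[10,0],[0,10]]: two-sided p = 2 / C(20,10)
  cats <- data.frame(gene_id = paste0("g", 1:20),
                     label = rep(c("hypo", "inter"), each = 10))
  enr <- category_enrichment(paste0("g", 1:10), cats)
  expect_equal(enr$p[enr$category == "hypo"], 2 / choose(20, 10),
               tolerance = 1e-12)

  # balanced table: odds ratio 1, p = 1
  cats2 <- data.frame(gene_id = paste0("g", 1:20),
                      label = rep(c("hypo", "inter"), 10))
  enr2 <- category_enrichment(paste0("g", c(1:5, 16:20)), cats2)
  expect_equal(enr2$p, c(1, 1))

  # degenerate margin flagged, p = 1
  cats3 <- data.frame(gene_id = paste0("g", 1:10),
                      label = rep("hypo", 10))
  enr3 <- category_enrichment(paste0("g", 1:3), cats3)
  expect_true(enr3$degenerate)
  expect_equal(enr3$p, 1)

  expect_error(category_enrichment(paste0("g", 1:20), cats), "uncalled")
})

test_that("null enrichment p-values are approximately uniform", {
  set.seed(9)
  ps <- replicate(400, {
    cats <- data.frame(gene_id = paste0("g", 1:40),
                       label = sample(rep(c("hyper", "inter"), each = 20)))
    called <- sample(cats$gene_id, 15)
    category_enrichment(called, cats)$p[1]
  })
  # Fisher p is discrete and conservative: no excess below nominal levels
  expect_lte(mean(ps < 0.05), 0.07)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("pathway linkage respects the 10-kb window and symmetry", {
  lnc <- data.frame(gene_id = "L1", chrom = "chr1", strand = "+",
                    start = 1000, end = 5000)
  mk_pcg <- function(s, e) data.frame(gene_id = "P1", chrom = "chr1",
                                      strand = "+", start = s, end = e)
  pw <- data.frame(gene_id = "P1", pathway = c("A", "B"))

  # gap 7000: linked
  l1 <- link_pathways(lnc, mk_pcg(12000, 14000), pw)
  expect_equal(nrow(l1), 1)
  expect_equal(l1$distance, 7000)
  expect_setequal(l1$pathways[[1]], c("A", "B"))

  # gap 10001: not linked (strict window)
  expect_equal(nrow(link_pathways(lnc, mk_pcg(15001, 16000), pw)), 0)
  # gap exactly 10000: linked
  expect_equal(nrow(link_pathways(lnc, mk_pcg(15000, 16000), pw)), 1)

  # overlap: distance 0
  l0 <- link_pathways(lnc, mk_pcg(4000, 9000), pw)
  expect_equal(l0$distance, 0)

  # unannotated PCG links with empty pathway set
  l_na <- link_pathways(lnc, mk_pcg(6000, 7000),
                        data.frame(gene_id = "PX", pathway = "C"))
  expect_length(l_na$pathways[[1]], 0)

  expect_warning(link_pathways(lnc, mk_pcg(6000, 7000), NULL), "empty")

  # distance symmetry: swapping roles yields the same pair and distance
  rev <- link_pathways(mk_pcg(12000, 14000),
                       within(lnc, gene_id <- "L1"), pw)
  expect_equal(rev$distance, l1$distance)
})

test_that("pathway counting unions pathways over linked genes", {
  links <- data.frame(lncrna_id = c("L1", "L1", "L2"),
                      pcg_id = c("P1", "P2", "P3"),
                      distance = c(0, 500, 100))
  links$pathways <- I(list(c("A", "B"), c("B", "C"), character(0)))
  cnt <- count_pathways(links, c("L1", "L2", "L3"))
  expect_equal(cnt$n_pathways, c(3, 0, 0))
})

test_that("one-vs-rest differential methylation calls planted shifts", {
  set.seed(13)
  cl <- setNames(rep(c(1, 2), each = 20), paste0("s", 1:40))
  pm <- cbind(strong = c(rnorm(20, 0.9, 0.02), rnorm(20, 0.2, 0.02)),
              null = rnorm(40, 0.5, 0.02),
              small = c(rnorm(20, 0.55, 0.001), rnorm(20, 0.5, 0.001)),
              flat = rep(0.4, 40))
  rownames(pm) <- names(cl)
  dm <- diff_methylation(pm, cl)
  d1 <- dm[dm$cluster == 1, ]
  expect_equal(d1$delta[d1$gene_id == "strong"], 0.7, tolerance = 0.05)
  expect_true(d1$called[d1$gene_id == "strong"])
  expect_false(d1$called[d1$gene_id == "null"])
  # tiny delta with astronomical significance is still not called
  expect_lt(d1$p[d1$gene_id == "small"], 1e-10)
  expect_false(d1$called[d1$gene_id == "small"])
  # identical constant groups: p = 1, delta = 0
  expect_equal(d1$p[d1$gene_id == "flat"], 1)
  expect_equal(d1$delta[d1$gene_id == "flat"], 0)

  # vectorized Welch t matches stats::t.test gene by gene
  for (g in c("strong", "null", "small")) {
    tt <- t.test(pm[cl == 1, g], pm[cl == 2, g])
    expect_equal(d1$p[d1$gene_id == g], tt$p.value, tolerance = 1e-12)
  }
  expect_error(diff_methylation(pm, setNames(c(1, rep(2, 39)), names(cl))),
               "< 2 samples")
})
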