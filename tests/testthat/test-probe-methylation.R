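make_manifest <- function(n, ...) {
  m <- data.frame(probe_id = sprintf("cg%03d", seq_len(n)), chrom = "chr1",
                  pos = seq_len(n) * 100, chrXY = FALSE, snp_overlap = FALSE,
                  non_unique = FALSE, not_on_epic = FALSE,
                  stringsAsFactors = FALSE)
  flags <- list(...)
  for (f in names(flags)) m[[f]][flags[[f]]] <- TRUE
  m
}

test_that("probe filtering removes flagged probes and reports per flag", {
  expect_equal(nrow(filter_probes(make_manifest(10))), 10)

  m <- filter_probes(make_manifest(10, chrXY = 1:3, snp_overlap = 4:5))
  expect_equal(nrow(m), 5)
  expect_equal(m$probe_id, sprintf("cg%03d", 6:10))
  rep <- attr(m, "filter_report")
  expect_equal(unname(rep[c("chrXY", "snp_overlap", "total_removed")]),
               c(3, 2, 5))

  # a doubly flagged probe is removed once, counted under both flags
  m2 <- filter_probes(make_manifest(10, chrXY = 1, snp_overlap = 1))
  expect_equal(nrow(m2), 9)
  rep2 <- attr(m2, "filter_report")
  expect_equal(unname(rep2[c("chrXY", "snp_overlap", "total_removed")]),
               c(1, 1, 1))

  expect_warning(filter_probes(make_manifest(2, chrXY = 1:2)), "all probes")
})

test_that("probe-promoter mapping uses half-open containment, multi-assigns", {
  probes <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                       pos = c(9000, 12000, 10500))
  promoters <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                          start = c(8000, 10000), end = c(12000, 14000))
  m <- map_probes_to_promoters(probes, promoters)
  expect_setequal(m$gA, c("p1", "p3"))        # 12000 excluded (half-open)
  expect_setequal(m$gB, c("p2", "p3"))        # p3 in both overlapping promoters

  bad <- data.frame(probe_id = "p1", chrom = "1", pos = 9000)
  expect_error(map_probes_to_promoters(bad, promoters), "chromosome")
})

test_that("promoter summarization averages non-missing probes", {
  beta <- matrix(c(0.2, 0.4, 0.1,
                   NA, 0.4, 0.5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("p1", "p2", "p3")))
  mp <- list(gA = c("p1", "p2"), gB = "p3")
  pm <- summarize_promoter(beta, mp)
  expect_equal(pm["s1", "gA"], 0.3)
  expect_equal(pm["s2", "gA"], 0.4)    # missing probe excluded
  expect_equal(pm[, "gB"], c(s1 = 0.1, s2 = 0.5))  # single-probe gene

  expect_warning(summarize_promoter(beta, c(mp, list(gC = "absent"))),
                 "dropped")

  # commutes with sample subsetting
  sub <- summarize_promoter(beta["s2", , drop = FALSE], mp)
  expect_equal(sub, pm["s2", , drop = FALSE], ignore_attr = TRUE)
})

test_that("categorization applies strict thresholds over non-missing samples", {
  pm <- cbind(hyper_g = rep(0.9, 10), hypo_g = rep(0.1, 10),
              edge_g = c(rep(0.9, 8), rep(0.1, 2)),
              na_g = NA_real_)
  rownames(pm) <- paste0("s", 1:10)
  cats <- suppressWarnings(categorize(pm))
  expect_equal(cats$label[cats$gene_id == "hyper_g"], "hyper")
  expect_equal(cats$label[cats$gene_id == "hypo_g"], "hypo")
  # exactly 80% is not "more than 80%"
  expect_equal(cats$label[cats$gene_id == "edge_g"], "inter")
  expect_true(is.na(cats$label[cats$gene_id == "na_g"]))

  # a beta of exactly 0.7 does not count as > 0.7
  pm2 <- cbind(g = rep(0.7, 10)); rownames(pm2) <- paste0("s", 1:10)
  expect_equal(categorize(pm2)$label, "inter")

  # missing-aware denominator: 9 of 9 non-missing above threshold
  pm3 <- cbind(g = c(rep(0.9, 9), NA)); rownames(pm3) <- paste0("s", 1:10)
  expect_equal(categorize(pm3)$label, "hyper")

  # grouped categorization labels each sample subset separately
  pm4 <- cbind(g = c(rep(0.9, 10), rep(0.1, 10)))
  rownames(pm4) <- paste0("s", 1:20)
  by_grp <- categorize(pm4, groups = rep(c("typeA", "typeB"), each = 10))
  expect_setequal(by_grp$label, c("hyper", "hypo"))
})

test_that("hyper and hypo are mutually exclusive on random matrices", {
  set.seed(11)
  for (i in 1:5) {
    pm <- matrix(runif(200), nrow = 10,
                 dimnames = list(NULL, paste0("g", 1:20)))
    cats <- categorize(pm)
    expect_false(any(cats$frac_above > 0.8 & cats$frac_below > 0.8))
    expect_true(all(cats$label %in% c("hyper", "hypo", "inter")))
  }
})

test_that("planted categories are recovered from noisy synthetic data", {
  sim <- simulate_beta(tiny_config())
  pm <- lnc_promoter_methylation(sim)
  cats <- categorize(pm)
  truth <- sim$truth$category_of_lncrna[cats$gene_id]
  expect_identical(cats$label, unname(truth))
})
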