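test_that("log-rank test matches the hand-computed hypergeometric table", {
  # group a: events at 1,2,3; group b: events at 4,5,6
  # per-time O-E and variance give chisq = (3 - 1.15)^2 / 0.6775 = 1369/271
  lr <- logrank_test(rep(c("a", "b"), each = 3), time = 1:6,
                     event = rep(1, 6))
  expect_equal(lr$statistic, 1369 / 271, tolerance = 1e-10)
  expect_equal(lr$p, pchisq(1369 / 271, 1, lower.tail = FALSE))

  # identical event-time multisets: observed = expected, statistic 0
  lr0 <- logrank_test(rep(c("a", "b"), 3), time = rep(1:3, each = 2),
                      event = rep(1, 6))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # invariant to strictly increasing time transforms
  set.seed(19)
  tm <- rexp(40); ev <- rbinom(40, 1, 0.7); gr <- rep(c("a", "b"), 20)
  expect_equal(logrank_test(gr, tm, ev)$statistic,
               logrank_test(gr, exp(tm), ev)$statistic, tolerance = 1e-12)
  expect_error(logrank_test(rep("a", 6), 1:6, rep(1, 6)), "two")
})

test_that("optimal cutpoint separates planted survival blocks", {
  # low-marker samples die early, high-marker late
  values <- rep(c(0.1, 0.9), each = 10)
  time <- c(1:10 / 10, 10 + 1:10)
  event <- rep(1, 20)
  cp <- optimal_cutpoint(values, time, event)
  expect_gt(cp$cutpoint, 0.1)
  expect_lt(cp$cutpoint, 0.9)
  expect_equal(unname(cp$groups), rep(c("low", "high"), each = 10))

  # infeasible minimum group size
  expect_error(optimal_cutpoint(runif(9), rexp(9), rep(1, 9), min_prop = 0.5),
               "min_prop")
  expect_error(optimal_cutpoint(rep(0.5, 10), rexp(10), rep(1, 10)),
               "distinct")
})

test_that("cutpoint scan equals the brute-force oracle on random instances", {
  set.seed(37)
  for (i in 1:25) {
    n <- sample(10:30, 1)
    values <- round(runif(n), 2)
    if (length(unique(values)) < 2) next
    time <- rexp(n, 0.2)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1L
    got <- tryCatch(optimal_cutpoint(values, time, event),
                    error = function(e) NULL)
    want <- oracle_cutpoint(values, time, event)
    if (is.null(got)) { expect_null(want); next }
    expect_equal(got$max_stat, want$stat, tolerance = 1e-9)
    expect_identical(unname(got$groups == "low"), want$low)
  }
})

test_that("statistics are invariant to rescaling all times", {
  set.seed(41)
  n <- 60
  values <- runif(n); time <- rexp(n); event <- rbinom(n, 1, 0.8)
  cp1 <- optimal_cutpoint(values, time, event)
  cp2 <- optimal_cutpoint(values, time * 1000, event)
  expect_equal(cp1$cutpoint, cp2$cutpoint)
  expect_equal(cp1$max_stat, cp2$max_stat, tolerance = 1e-12)

  surv <- data.frame(time = time, event = event, age = rnorm(n, 8, 3),
                     sex = rbinom(n, 1, 0.5),
                     who_category = sample(c("w1", "w2"), n, TRUE),
                     lncrna_cluster = sample(1:2, n, TRUE))
  lr1 <- nested_cox_lr(surv)
  surv2 <- surv; surv2$time <- surv2$time * 365
  lr2 <- nested_cox_lr(surv2)
  expect_equal(lr1$delta_lr, lr2$delta_lr, tolerance = 1e-8)
})

test_that("nested Cox tiers: monotone loglik, zero gain for duplicates", {
  set.seed(43)
  n <- 120
  cl <- sample(1:2, n, TRUE)
  surv <- data.frame(time = rexp(n, 0.1 * c(1, 3)[cl]),
                     event = rbinom(n, 1, 0.85),
                     age = rnorm(n, 8, 3), sex = rbinom(n, 1, 0.5),
                     who_category = sample(c("w1", "w2", "w3"), n, TRUE),
                     lncrna_cluster = cl)
  lr <- nested_cox_lr(surv)
  expect_equal(nrow(lr), 3)
  expect_true(all(diff(lr$loglik) >= -1e-6))
  expect_true(all(lr$delta_lr[-1] >= -1e-6))
  # the planted cluster effect is detected
  expect_lt(lr$p[3], 0.01)

  # adding a covariate identical to one already present gains nothing
  surv$age_copy <- surv$age
  lr_dup <- nested_cox_lr(surv, tiers = list(c("age", "sex"),
                                             c("age", "sex", "age_copy")))
  expect_equal(lr_dup$delta_lr[2], 0, tolerance = 1e-6)
  expect_true(is.na(lr_dup$p[2]))   # zero added coefficients

  expect_error(nested_cox_lr(surv, tiers = list(c("age", "sex"), "age")),
               "nested")
})

test_that("KM coordinates start at 1 and are non-increasing per group", {
  set.seed(47)
  km <- km_coordinates(rep(c("hi", "lo"), 25), rexp(50), rbinom(50, 1, 0.8))
  for (g in c("hi", "lo")) {
    s <- km$surv[km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
  }
})
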