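# Quadrant biomarker: thresholds, quadrant map, proportion CIs, Fisher
# exact test, ROC AUC, DCB and the Gehan-Breslow-Wilcoxon survival test.

test_that("healthy-quantile thresholds use order-statistic interpolation", {
  expect_equal(derive_group_threshold(1:100, q = 0.8), 80.2, tolerance = 1e-9)
  expect_equal(derive_group_threshold(rep(7, 10)), 7)
  expect_equal(derive_group_threshold(c(3, 1, 4, 1, 5, 9), q = 1), 9)
  expect_error(derive_group_threshold(c(1, 2, 3)), "at least 5")
})

test_that("the quadrant map follows the published definitions and tie rule", {
  thr <- biomarker_thresholds("NSCLC")
  expect_equal(thr$dn_tem, 36.0)
  expect_equal(thr$dp_temra, 17.2)
  qa <- assign_quadrant(c(30, 40, 40, 30, 36), c(10, 10, 20, 20, 17.2), thr)
  expect_identical(qa$quadrant, c("Q4", "Q1", "Q2", "Q3", "Q2"))
  sclc <- biomarker_thresholds("SCLC")
  expect_equal(c(sclc$dn_tem, sclc$dp_temra), c(42, 11))
  # the quadrant map is total on [0,100]^2
  grid <- expand.grid(dn = seq(0, 100, by = 10), dp = seq(0, 100, by = 10))
  qall <- assign_quadrant(grid$dn, grid$dp, thr)
  expect_false(anyNA(qall$quadrant))
  expect_true(all(qall$quadrant %in% c("Q1", "Q2", "Q3", "Q4")))
})

test_that("missing frequencies exclude the donor with a warning", {
  thr <- biomarker_thresholds("NSCLC")
  expect_warning(qa <- assign_quadrant(c(30, NA), c(10, 10), thr,
                                       donor_id = c("a", "b")), "missing")
  expect_identical(qa$donor_id, "a")
})

test_that("Wald and Wilson intervals reproduce closed-form bounds", {
  w <- response_rate_ci(5, 15, "wald")
  z <- qnorm(0.975); p <- 5 / 15
  expect_equal(w$lower, 100 * (p - z * sqrt(p * (1 - p) / 15)), tolerance = 1e-10)
  expect_equal(w$upper, 100 * (p + z * sqrt(p * (1 - p) / 15)), tolerance = 1e-10)
  # edge behaviour: Wald may leave [0, 100]; Wilson cannot
  expect_equal(response_rate_ci(0, 10, "wald")$lower, 0)
  expect_gt(response_rate_ci(11, 12, "wald")$upper, 100)
  expect_equal(response_rate_ci(0, 10, "wilson")$lower, 0, tolerance = 1e-12)
  expect_lte(response_rate_ci(10, 10, "wilson")$upper, 100)
  # both intervals contain the point estimate
  for (s in c(0, 3, 9)) {
    for (m in c("wald", "wilson")) {
      ci <- response_rate_ci(s, 9, m)
      expect_lte(ci$lower, ci$estimate)
      expect_gte(ci$upper, ci$estimate)
    }
  }
  expect_error(response_rate_ci(5, 0), "at least 1")
})

test_that("interval width shrinks with n", {
  w1 <- response_rate_ci(30, 100, "wilson")
  w2 <- response_rate_ci(3000, 10000, "wilson")
  expect_lt(w2$upper - w2$lower, w1$upper - w1$lower)
})

test_that("Fisher exact p matches hand-checkable tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  p <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "degenerate")
  expect_identical(p0, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Fisher exact p equals the enumeration oracle on random tables", {
  set.seed(12)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher_oracle(tab), tolerance = 1e-8)
  }
})

test_that("midrank AUC matches the exhaustive pairwise oracle with ties", {
  set.seed(13)
  for (i in 1:25) {
    scores <- sample(1:6, 12, replace = TRUE)  # heavy ties
    labels <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (!any(labels) || all(labels)) next
    a <- roc_auc(scores, labels, direction = "lower")
    expect_equal(a$auc, auc_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is 1 for perfect separation and ~0.5 for noise", {
  a <- roc_auc(c(1, 2, 3, 10, 11, 12), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
               direction = "lower")
  expect_equal(a$auc, 1)
  set.seed(14)
  a2 <- roc_auc(rnorm(4000), rbinom(4000, 1, 0.5) == 1, direction = "lower")
  expect_lt(abs(a2$auc - 0.5), 0.05)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("midrank AUC agrees with an independent ROC implementation", {
  set.seed(19)
  scores <- c(rnorm(40, 30, 8), rnorm(25, 42, 8))
  labels <- rep(c(TRUE, FALSE), c(40, 25))
  a <- roc_auc(scores, labels, direction = "lower")
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        direction = ">", quiet = TRUE)))
  expect_equal(a$auc, ref, tolerance = 1e-12)
})

test_that("DCB derivation follows the 6-month definition", {
  expect_identical(derive_dcb(c("PR", "SD", "PD", "CR", NA)),
                   c(TRUE, TRUE, FALSE, TRUE, NA))
})

test_that("Gehan-Breslow-Wilcoxon is null on identical groups, large when separated", {
  set.seed(15)
  t0 <- rexp(60, 0.01)
  r <- km_gehan_breslow_wilcoxon(c(t0, t0), rep(TRUE, 120),
                                 rep(c("a", "b"), each = 60))
  expect_lt(r$statistic, 1e-9)
  expect_gt(r$p_value, 0.99)
  # one group all events at t=1, other all censored at t=10
  r2 <- km_gehan_breslow_wilcoxon(rep(c(1, 10), each = 10),
                                  rep(c(TRUE, FALSE), each = 10),
                                  rep(c("a", "b"), each = 10),
                                  permutations = 2000, seed = 1)
  expect_gt(r2$statistic, 15)
  expect_lt(r2$p_value, 1e-4)
  expect_lt(r2$p_permutation, 0.01)
})

test_that("without censoring the Gehan statistic reduces to the Wilcoxon rank test", {
  set.seed(18)
  for (i in 1:5) {
    times <- c(rexp(20, 0.02), rexp(25, 0.035))
    grp <- rep(c("a", "b"), c(20, 25))
    r <- km_gehan_breslow_wilcoxon(times, rep(TRUE, 45), grp)
    kw <- unname(kruskal.test(times, factor(grp))$statistic)
    # identical up to finite-sample variance factors
    expect_lt(abs(r$statistic - kw) / max(kw, 1), 0.05)
  }
})

test_that("KM estimate on uncensored data is the empirical survival function", {
  times <- c(1, 2, 3, 4, 5)
  r <- km_gehan_breslow_wilcoxon(c(times, times), rep(TRUE, 10),
                                 rep(c("a", "b"), each = 5))
  fit <- r$fit
  surv_a <- summary(fit)$surv[summary(fit)$strata == "group=a"]
  expect_equal(surv_a, (5 - seq_len(5)) / 5, tolerance = 1e-12)
})

test_that("evaluate_biomarker recovers configured quadrant rates", {
  set.seed(16)
  n_q <- 300
  prof <- data.frame(
    donor_id = sprintf("P%04d", 1:(2 * n_q)),
    group = "patient",
    dn_tem_pct = rep(c(20, 50), each = n_q),  # Q4 then Q1
    dp_temra_pct = 10)
  out <- attach_outcomes(prof, biomarker_thresholds("NSCLC"),
                         default_response_model(), seed = 17)
  expect_warning(b <- evaluate_biomarker(prof, out), "0 donors")
  r4 <- b$rates[b$rates$quadrant == "Q4" & b$rates$endpoint == "PR", ]
  r1 <- b$rates[b$rates$quadrant == "Q1" & b$rates$endpoint == "PR", ]
  # configured rates 0.45 (Q4) and 0.18 (Q1) inside their 95% CIs
  expect_gt(45, r4$lower_wald); expect_lt(45, r4$upper_wald)
  expect_gt(18, r1$lower_wald); expect_lt(18, r1$upper_wald)
  expect_lt(b$fisher$PR$p_value, 0.001)
  expect_gt(b$auc$auc, 0.5)
})

test_that("a single-donor quadrant yields a degenerate but defined CI", {
  prof <- data.frame(donor_id = c("a", "b"), group = "patient",
                     dn_tem_pct = c(20, 50), dp_temra_pct = c(10, 10))
  out <- data.frame(donor_id = c("a", "b"), best_response = c("PR", "PD"),
                    response_at_6m = c("PR", "PD"))
  expect_warning(b <- evaluate_biomarker(prof, out), "0 donors")
  r <- b$rates[b$rates$quadrant == "Q4" & b$rates$endpoint == "PR", ]
  expect_identical(r$n, 1L)
  expect_equal(r$rate, 100)
})
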