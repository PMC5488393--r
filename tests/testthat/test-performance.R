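test_that("evaluate_rule reproduces published confusion-count arithmetic", {
  # sensitivity rows of the performance table
  coh <- classify_cohort(counts_cohort(tp = 207, fn = 6, fp = 0, tn = 10))
  s <- evaluate_rule(coh, coh$disease, rule = c("NMN", "MN"))
  expect_equal(round(s$sensitivity, 1), 97.2)
  expect_equal(unname(s$counts[c("tp", "fn")]), c(207, 6))

  coh <- classify_cohort(counts_cohort(tp = 19, fn = 19, fp = 0, tn = 10))
  s <- evaluate_rule(coh, coh$disease, rule = c("NMN", "MN", "MTY"))
  expect_equal(round(s$sensitivity, 1), 50.0)

  # specificity from 1628/1712
  coh <- classify_cohort(counts_cohort(tp = 5, fn = 0, fp = 84, tn = 1628))
  s <- evaluate_rule(coh, coh$disease, rule = c("NMN", "MN", "MTY"))
  expect_equal(round(s$specificity, 1), 95.1)
  expect_equal(unname(s$counts[c("tn", "fp")]), c(1628, 84))

  # degenerate: everyone diseased and positive
  coh <- classify_cohort(counts_cohort(tp = 10, fn = 0, fp = 0, tn = 0))
  expect_error(evaluate_rule(coh, coh$disease), "specificity undefined")
  coh <- classify_cohort(counts_cohort(tp = 0, fn = 0, fp = 1, tn = 9))
  expect_error(evaluate_rule(coh, coh$disease), "sensitivity undefined")
})

test_that("adding methoxytyramine never lowers sensitivity nor raises specificity", {
  cfg <- sim_config(seed = 33)
  coh <- rbind(simulate_ppgl(cfg), simulate_screening_negatives(cfg))
  cl <- classify_cohort(coh)
  dis <- cl$group == "ppgl"
  two <- evaluate_rule(cl, dis, c("NMN", "MN"))
  three <- evaluate_rule(cl, dis, c("NMN", "MN", "MTY"))
  expect_gte(three$sensitivity, two$sensitivity)
  expect_lte(three$specificity, two$specificity)
})

test_that("exact McNemar comparison matches the closed-form binomial", {
  same <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(compare_paired_proportions(same, same)$p_value, 1)
  # one-sided discordance (13, 0): p = 2 * 0.5^13
  a <- rep(TRUE, 20)
  b <- c(rep(FALSE, 13), rep(TRUE, 7))
  res <- compare_paired_proportions(a, b)
  expect_equal(res$n_discordant_a, 13)
  expect_equal(res$n_discordant_b, 0)
  expect_equal(res$p_value, 2 * 0.5^13, tolerance = 1e-12)
  # symmetric single discordants
  res <- compare_paired_proportions(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  expect_equal(res$p_value, 1)
  expect_error(compare_paired_proportions(c(TRUE), c(TRUE, FALSE)),
               "identical subject list")
})

test_that("rank AUC matches brute-force pairwise concordance", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc(rep(2, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    sc <- sample(1:20, n, replace = TRUE)  # force ties
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lb) || all(lb)) next
    expect_equal(auc(sc, lb), auc_bruteforce(sc, lb))
  }
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  sc <- rnorm(100)
  lb <- rbinom(100, 1, 0.4)
  a0 <- auc(sc, lb)
  expect_equal(auc(exp(sc), lb), a0)
  expect_equal(auc(rank(sc), lb), a0)
  expect_equal(auc(plogis(3 * sc - 1), lb), a0)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(8)
  sc <- c(rnorm(60, 1), rnorm(90))
  lb <- c(rep(TRUE, 60), rep(FALSE, 90))
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c(FALSE, TRUE),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc(sc, lb), ref, tolerance = 1e-12)
})

test_that("panel score behaves per logistic-model structure", {
  coh <- tiny_cohort()
  # zero weights -> 0.5 everywhere
  expect_equal(panel_score(coh, list(intercept = 0)), rep(0.5, nrow(coh)))
  # positive weight: raising the concentration raises the score
  s1 <- panel_score(data.frame(age = 50, nmn = 0.5, mn = 0.1, mty = 0.05),
                    list(intercept = 0, nmn = 1))
  s2 <- panel_score(data.frame(age = 50, nmn = 1.5, mn = 0.1, mty = 0.05),
                    list(intercept = 0, nmn = 1))
  expect_gt(s2, s1)
})

test_that("fitted score separates a separable synthetic cohort", {
  cfg <- sim_config(seed = 21,
                    ppgl_mixture = c(NONE = 0, NMN_ONLY = 0, MN_ONLY = 0,
                                     MTY_ONLY = 0, NMN_MN = 0, NMN_MTY = 0,
                                     MN_MTY = 0, TRIPLET = 1),
                    ppgl_fold = list(nmn = c(meanlog = log(20), sdlog = 0.2),
                                     mn = c(meanlog = log(20), sdlog = 0.2),
                                     mty = c(meanlog = log(20), sdlog = 0.2)))
  coh <- rbind(simulate_ppgl(cfg, n = 60), simulate_reference(cfg, n = 200))
  dis <- coh$group == "ppgl"
  fit <- suppressWarnings(fit_panel_score(coh, dis))
  expect_gt(min(fit$scores[dis]), max(fit$scores[!dis]))
  expect_equal(auc(fit$scores, dis), 1)
})

test_that("paired AUC comparison is antisymmetric and null-consistent", {
  set.seed(9)
  sc_a <- c(rnorm(50, 1.2), rnorm(80))
  sc_b <- sc_a + rnorm(130, 0, 1.5)
  lb <- c(rep(TRUE, 50), rep(FALSE, 80))
  r_same <- compare_auc(sc_a, sc_a, lb)
  expect_equal(r_same$delta_auc, 0)
  expect_equal(r_same$p_value, 1)
  r_ab <- compare_auc(sc_a, sc_b, lb)
  r_ba <- compare_auc(sc_b, sc_a, lb)
  expect_equal(r_ab$delta_auc, -r_ba$delta_auc)
  expect_equal(r_ab$p_value, r_ba$p_value)
  expect_error(compare_auc(sc_a, sc_b[-1], lb), "equal-length")
})
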