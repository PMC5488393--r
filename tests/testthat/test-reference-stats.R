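test_that("stratified summary follows order-statistic conventions", {
  one <- tibble::tibble(age = 35, sex = "F", bp_status = "normotensive",
                        nmn = 0.3, mn = 0.15, mty = 0.03)
  s <- stratified_summary(one)
  all_row <- s[s$stratum == "All subjects", ]
  expect_equal(all_row$nmn_median, 0.3)
  expect_equal(all_row$nmn_min, 0.3)
  expect_equal(all_row$nmn_max, 0.3)
  # even-n convention: midpoint of the two central order statistics
  two <- rbind(one, transform(one, nmn = 0.5))
  s2 <- stratified_summary(two)
  expect_equal(s2$nmn_median[s2$stratum == "All subjects"], 0.4)
  # empty stratum reported as n = 0 with absent statistics
  expect_equal(s$n[s$stratum == "Men"], 0)
  expect_true(is.na(s$nmn_median[s$stratum == "Men"]))
})

test_that("strata partition the cohort consistently", {
  coh <- simulate_reference(sim_config(seed = 4))
  s <- stratified_summary(coh)
  n_all <- s$n[s$stratum == "All subjects"]
  expect_equal(sum(s$n[s$stratum %in% c("Women", "Men")]), n_all)
  bands <- c("18-29 years", "30-39 years", "40-49 years", "50-59 years",
             ">60 years")
  expect_equal(sum(s$n[s$stratum %in% bands]), n_all)
  expect_equal(sum(s$n[s$stratum %in% c("Normotensive", "Hypertensive")]),
               n_all)
  # per-metabolite min <= median <= max wherever the stratum is non-empty
  for (m in c("nmn", "mn", "mty")) {
    ok <- s$n > 0
    expect_true(all(s[[paste0(m, "_min")]][ok] <=
                    s[[paste0(m, "_median")]][ok]))
    expect_true(all(s[[paste0(m, "_median")]][ok] <=
                    s[[paste0(m, "_max")]][ok]))
  }
})

test_that("simulated reference medians sit in the published bands", {
  s <- stratified_summary(simulate_reference(sim_config(seed = 10)))
  nmn_med <- s$nmn_median[s$stratum == "All subjects"]
  expect_gt(nmn_med, 0.30)
  expect_lt(nmn_med, 0.38)
})

test_that("a known multiplicative effect is recovered exactly without noise", {
  # deterministic cohort: pure 12% hypertensive effect, additive age trend
  age <- rep(20:69, each = 2)
  bp <- rep(c("normotensive", "hypertensive"), 50)
  coh <- tibble::tibble(
    age = age, sex = rep(c("F", "M"), each = 50), bp_status = bp,
    nmn = exp(-1 + 0.01 * age + log(1.12) * (bp == "hypertensive")),
    mn = 0.15, mty = 0.03
  )
  # a zero-residual fit: warnings about the perfect fit are expected
  res <- suppressWarnings(
    adjusted_group_difference(coh, "nmn", group = "bp_status",
                              covariates = c("age", "sex")))
  expect_equal(res$percent_difference, 12, tolerance = 1e-6)
  expect_equal(res$group, "hypertensive vs normotensive")
})

test_that("built-in simulator effects are recovered within their CIs", {
  cfg <- sim_config(seed = 19)
  coh <- simulate_reference(cfg, n = 4000)
  hyp <- adjusted_group_difference(coh, "nmn", group = "bp_status",
                                   covariates = c("age", "sex"))
  expect_true(hyp$conf_int[1] < 12 && 12 < hyp$conf_int[2])
  expect_lt(hyp$p_value, 0.001)
  man <- adjusted_group_difference(coh, "mn", group = "sex",
                                   covariates = c("age"))
  expect_true(man$conf_int[1] < 30 && 30 < man$conf_int[2])
  expect_equal(man$group, "M vs F")
  expect_error(
    adjusted_group_difference(transform(coh, sex = "F"), "mn", group = "sex"),
    "two levels")
})

test_that("null simulation recovers a near-zero adjusted difference", {
  cfg <- sim_config(seed = 23, nmn_hyper_mult = 1)
  coh <- simulate_reference(cfg, n = 4000)
  res <- adjusted_group_difference(coh, "nmn", group = "bp_status")
  expect_lt(abs(res$percent_difference), 5)
  expect_true(res$conf_int[1] < 0 && 0 < res$conf_int[2])
})

test_that("age correlation lands in the published band and at its limits", {
  coh <- simulate_reference(sim_config(seed = 3), n = 2000)
  r_nmn <- age_correlation(coh, "nmn")
  expect_gt(r_nmn$r, 0.2)
  expect_lt(r_nmn$r, 0.45)
  expect_lt(r_nmn$p_value, 1e-4)
  # age-independent metabolite: r ~ 0
  r_mn <- age_correlation(coh, "mn")
  expect_lt(abs(r_mn$r), 0.1)
  # perfectly monotone deterministic relation: r ~ 1 on log scale
  det <- tibble::tibble(age = 20:70, nmn = exp(0.01 * (20:70)))
  expect_equal(age_correlation(det, "nmn")$r, 1, tolerance = 1e-9)
  expect_error(age_correlation(tibble::tibble(age = 1:5, nmn = rep(1, 5)),
                               "nmn"), "constant")
})
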