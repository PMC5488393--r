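test_that("reference-typical panels classify as negative", {
  res <- classify_cohort(
    data.frame(age = 50, nmn = 0.340, mn = 0.151, mty = 0.028))
  expect_false(res$flag_nmn)
  expect_false(res$flag_mn)
  expect_false(res$flag_mty)
  expect_equal(as.character(res$category), "NONE")
  expect_false(res$any_positive)
})

test_that("values equal to the cutoff are positive (equal to or above)", {
  pol <- cutoff_policy()
  res <- classify_cohort(
    data.frame(age = 50, nmn = uc_normetanephrine(50, pol),
               mn = pol$mn_uc, mty = pol$mty_uc), pol)
  expect_true(res$flag_nmn && res$flag_mn && res$flag_mty)
  expect_equal(as.character(res$category), "TRIPLET")
  expect_equal(c(res$fold_nmn, res$fold_mn, res$fold_mty), c(1, 1, 1))
})

test_that("an isolated normetanephrine elevation is NMN_ONLY", {
  res <- classify_cohort(data.frame(age = 45, nmn = 1.70, mn = 0.10,
                                    mty = 0.05))
  expect_equal(as.character(res$category), "NMN_ONLY")
  expect_gt(res$fold_nmn, 2)       # 1.70 vs UC(45) ~ 0.73
  expect_true(res$strong_positive)
})

test_that("zero panels give NONE with zero folds", {
  res <- classify_cohort(data.frame(age = 30, nmn = 0, mn = 0, mty = 0))
  expect_equal(as.character(res$category), "NONE")
  expect_equal(c(res$fold_nmn, res$fold_mn, res$fold_mty), c(0, 0, 0))
})

test_that("category matches an exhaustive truth table over all flag triples", {
  pol <- cutoff_policy()
  grid <- expand.grid(n = c(FALSE, TRUE), m = c(FALSE, TRUE),
                      t = c(FALSE, TRUE))
  uc_n <- uc_normetanephrine(40, pol)
  coh <- data.frame(
    age = 40,
    nmn = ifelse(grid$n, uc_n * 1.5, uc_n * 0.5),
    mn = ifelse(grid$m, pol$mn_uc * 1.5, pol$mn_uc * 0.5),
    mty = ifelse(grid$t, pol$mty_uc * 1.5, pol$mty_uc * 0.5)
  )
  res <- classify_cohort(coh, pol)
  oracle <- function(n, m, t) {
    k <- sum(n, m, t)
    if (k == 0) return("NONE")
    if (k == 3) return("TRIPLET")
    if (k == 1) return(c("NMN_ONLY", "MN_ONLY", "MTY_ONLY")[which(c(n, m, t))])
    if (n && m) "NMN_MN" else if (n && t) "NMN_MTY" else "MN_MTY"
  }
  expected <- mapply(oracle, grid$n, grid$m, grid$t)
  expect_equal(as.character(res$category), unname(expected))
  expect_equal(res$any_positive, rowSums(grid) >= 1)
  expect_equal(res$multi_positive, rowSums(grid) >= 2)
})

test_that("raising one concentration never removes flags (monotonicity)", {
  set.seed(7)
  pol <- cutoff_policy()
  for (i in 1:30) {
    base <- data.frame(age = runif(1, 10, 90), nmn = rlnorm(1, -1, 0.8),
                       mn = rlnorm(1, -2, 0.8), mty = rlnorm(1, -3.5, 0.8))
    r0 <- classify_cohort(base, pol)
    m <- sample(c("nmn", "mn", "mty"), 1)
    up <- base
    up[[m]] <- up[[m]] * runif(1, 1, 10)
    r1 <- classify_cohort(up, pol)
    f0 <- c(r0$flag_nmn, r0$flag_mn, r0$flag_mty)
    f1 <- c(r1$flag_nmn, r1$flag_mn, r1$flag_mty)
    expect_true(all(f1 >= f0))
  }
})

test_that("missing metabolites yield false flags and an incomplete mark", {
  res <- classify_cohort(data.frame(age = 50, nmn = 2.0, mn = NA_real_,
                                    mty = 0.05))
  expect_true(res$flag_nmn)
  expect_false(res$flag_mn)
  expect_true(is.na(res$fold_mn))
  expect_true(res$incomplete)
  expect_equal(as.character(res$category), "NMN_ONLY")
  # NMN absent: age not needed; all absent: error
  expect_silent(classify_cohort(data.frame(age = NA_real_, nmn = NA_real_,
                                           mn = 0.1, mty = 0.05)))
  expect_error(classify_cohort(data.frame(age = 50, nmn = NA_real_,
                                          mn = NA_real_, mty = NA_real_)),
               "all three")
  expect_error(classify_cohort(data.frame(age = NA_real_, nmn = 1,
                                          mn = 0.1, mty = 0.05)),
               "age is required")
})

test_that("category proportions count correctly and sum to one", {
  cats <- c("NMN_ONLY", "MN_ONLY", "MTY_ONLY", "NONE")
  pr <- category_proportions(cats)
  expect_equal(sum(pr), 1)
  expect_equal(unname(pr[c("NMN_ONLY", "MN_ONLY", "MTY_ONLY", "NONE")]),
               rep(0.25, 4))
  expect_equal(unname(category_proportions("TRIPLET")[["TRIPLET"]]), 1)
  expect_error(category_proportions(character(0)), "empty")
  # partition property on a random cohort
  set.seed(11)
  coh <- data.frame(age = runif(200, 18, 80), nmn = rlnorm(200, -1, 0.6),
                    mn = rlnorm(200, -2, 0.6), mty = rlnorm(200, -3.5, 0.6))
  res <- classify_cohort(coh)
  expect_equal(sum(table(res$category)), nrow(coh))
  expect_equal(sum(category_proportions(res)), 1)
})
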