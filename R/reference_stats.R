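# Reference population descriptive and adjusted statistics ----------------

# decade bins, right-open so continuous ages partition cleanly
REFERENCE_AGE_BANDS <- list(
  "18-29 years" = c(18, 30), "30-39 years" = c(30, 40),
  "40-49 years" = c(40, 50), "50-59 years" = c(50, 60),
  ">60 years" = c(60, Inf)
)

#' Stratified medians and ranges of the reference population
#'
#' Summarises methoxytyramine, normetanephrine and metanephrine as median
#' (minimum-maximum) for the fixed strata used when describing a reference
#' population: all subjects, women/men, decade age bands (18-29, 30-39,
#' 40-49, 50-59, >60 years; right-open bins, so fractional ages partition
#' cleanly) and normotensive/hypertensive. An empty stratum is
#' reported with n = 0 and missing statistics. Even-sized strata use the
#' midpoint median convention.
#'
#' @param cohort Data frame with `age`, `sex` (`"F"`/`"M"`), `bp_status`
#'   (`"normotensive"`/`"hypertensive"`/other) and concentrations `nmn`,
#'   `mn`, `mty` in nmol/L.
#' @return A tibble with one row per stratum: `stratum`, `n`, and for each
#'   metabolite `_median`, `_min`, `_max` columns.
#' @export
stratified_summary <- function(cohort) {
  need <- c("age", "sex", "bp_status", "nmn", "mn", "mty")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  strata <- c(
    list("All subjects" = rep(TRUE, nrow(cohort)),
         "Women" = cohort$sex == "F",
         "Men" = cohort$sex == "M"),
    lapply(REFERENCE_AGE_BANDS, function(b) {
      cohort$age >= b[1] & cohort$age < b[2]
    }),
    list("Normotensive" = cohort$bp_status == "normotensive",
         "Hypertensive" = cohort$bp_status == "hypertensive")
  )
  rows <- lapply(names(strata), function(nm) {
    idx <- which(strata[[nm]])
    row <- list(stratum = nm, n = length(idx))
    for (m in c("mty", "nmn", "mn")) {
      v <- cohort[[m]][idx]
      v <- v[!is.na(v)]
      row[[paste0(m, "_median")]] <- if (length(v)) stats::median(v) else NA_real_
      row[[paste0(m, "_min")]] <- if (length(v)) min(v) else NA_real_
      row[[paste0(m, "_max")]] <- if (length(v)) max(v) else NA_real_
    }
    tibble::as_tibble(row)
  })
  do.call(rbind, rows)
}

#' Covariate-adjusted group difference in a metabolite concentration
#'
#' Fits a linear model to log-transformed concentrations with the grouping
#' factor and additive covariate terms, and reports the group effect as a
#' percent difference, `100 * (exp(coef) - 1)`, together with its
#' confidence interval and p-value. This is the adjusted-comparison form in
#' which effects such as "12% higher normetanephrine in hypertensives,
#' adjusted for age and gender" are quoted.
#'
#' @param cohort Data frame with the metabolite column plus the grouping
#'   and covariate columns.
#' @param metabolite One of `"nmn"`, `"mn"`, `"mty"`.
#' @param group Name of a two-level factor column (`"sex"` or
#'   `"bp_status"`); the effect is reported for the second level relative
#'   to the first (levels sorted, so `M` vs `F` and `normotensive` vs
#'   `hypertensive` — the latter is re-ordered so hypertensive is the
#'   exposed level).
#' @param covariates Character vector of adjustment columns (default
#'   `c("age", "sex")`; the grouping variable is dropped from it
#'   automatically).
#' @return A list with `percent_difference`, `conf_int` (95%, percent
#'   scale), `p_value`, `group`, `metabolite` and the underlying `model`.
#' @export
adjusted_group_difference <- function(cohort, metabolite = "nmn",
                                      group = "bp_status",
                                      covariates = c("age", "sex")) {
  metabolite <- tolower(metabolite)
  stopifnot(metabolite %in% c("nmn", "mn", "mty"))
  covariates <- setdiff(covariates, group)
  g <- cohort[[group]]
  if (is.null(g)) stop("no column '", group, "' in cohort", call. = FALSE)
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2) {
    stop("grouping factor must have exactly two levels, found ",
         length(lev), call. = FALSE)
  }
  # report hypertensive vs normotensive, M vs F
  if (setequal(lev, c("hypertensive", "normotensive"))) {
    lev <- c("normotensive", "hypertensive")
  }
  dat <- data.frame(
    y = log(cohort[[metabolite]]),
    g = factor(as.character(g), levels = lev)
  )
  for (cv in covariates) dat[[cv]] <- cohort[[cv]]
  if (any(!is.finite(dat$y))) {
    stop("log transform requires strictly positive concentrations",
         call. = FALSE)
  }
  model <- stats::lm(y ~ ., data = dat)
  co <- stats::summary.lm(model)$coefficients
  term <- paste0("g", lev[2])
  est <- co[term, "Estimate"]
  ci <- stats::confint(model)[term, ]
  list(
    percent_difference = 100 * (exp(est) - 1),
    conf_int = 100 * (exp(ci) - 1),
    p_value = co[term, "Pr(>|t|)"],
    group = paste(lev[2], "vs", lev[1]),
    metabolite = metabolite, model = model
  )
}

#' Age correlation of a metabolite concentration
#'
#' Pearson correlation of log-transformed concentration with age. The log
#' scale matches the scale on which the concentrations are analysed
#' throughout the package.
#'
#' @inheritParams adjusted_group_difference
#' @return A list with `r`, `p_value`, `n`.
#' @export
age_correlation <- function(cohort, metabolite = "nmn") {
  metabolite <- tolower(metabolite)
  stopifnot(metabolite %in% c("nmn", "mn", "mty"))
  v <- cohort[[metabolite]]
  ok <- !is.na(v) & !is.na(cohort$age) & v > 0
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(log(v[ok])) == 0 || stats::sd(cohort$age[ok]) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(log(v[ok]), cohort$age[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
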