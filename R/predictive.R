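# Likelihood ratios and posttest probability -------------------------------

#' Positive and negative likelihood ratios
#'
#' `lr_positive()` is sensitivity divided by the false-positive rate
#' (1 - specificity); it multiplies pretest odds into posttest odds. A
#' positive sensitivity with a zero false-positive rate yields `Inf` (a
#' pathognomonic result); both zero is undefined. `lr_negative()` is
#' (1 - sensitivity) / specificity.
#'
#' @param sensitivity,fp_rate,specificity Fractions in \[0, 1\].
#' @return A likelihood ratio (possibly `Inf`).
#' @examples
#' lr_positive(0.493, 0.0018) # ~274
#' @export
lr_positive <- function(sensitivity, fp_rate) {
  check_fraction(sensitivity, "sensitivity")
  check_fraction(fp_rate, "fp_rate")
  if (any(sensitivity == 0 & fp_rate == 0)) {
    stop("likelihood ratio undefined when sensitivity and fp_rate are both 0",
         call. = FALSE)
  }
  ifelse(fp_rate == 0, Inf, sensitivity / fp_rate)
}

#' @rdname lr_positive
#' @export
lr_negative <- function(sensitivity, specificity) {
  check_fraction(sensitivity, "sensitivity")
  check_fraction(specificity, "specificity")
  if (any(specificity == 0)) {
    stop("negative likelihood ratio undefined at zero specificity",
         call. = FALSE)
  }
  (1 - sensitivity) / specificity
}

check_fraction <- function(x, what) {
  if (anyNA(x) || any(x < 0 | x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Posttest probability from pretest prevalence and a likelihood ratio
#'
#' Odds-form Bayes: pretest odds are multiplied by the likelihood ratio and
#' converted back to a probability,
#' \deqn{P = \frac{o \cdot LR}{1 + o \cdot LR}, \quad o = \frac{p}{1-p}.}
#' With `lr = 1` the posttest probability equals the pretest prevalence;
#' with `lr = Inf` it is 1.
#'
#' @param pretest Pretest prevalence(s), strictly inside (0, 1).
#' @param lr Positive likelihood ratio(s), `>= 0` (may be `Inf`).
#' @return Posttest probabilities in \[0, 1\].
#' @examples
#' posttest_probability(0.005, lr_positive(0.493, 0.0018)) # ~0.58
#' @export
posttest_probability <- function(pretest, lr) {
  if (anyNA(pretest) || any(pretest <= 0 | pretest >= 1)) {
    stop("pretest prevalence must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (anyNA(lr) || any(lr < 0)) {
    stop("likelihood ratio must be non-negative", call. = FALSE)
  }
  odds <- pretest / (1 - pretest) * lr
  ifelse(is.infinite(odds), 1, odds / (1 + odds))
}

#' Prevalence-to-posttest-probability curve for a rule
#'
#' Evaluates [posttest_probability()] over a grid of pretest prevalences
#' for a rule summarised by its sensitivity and false-positive rate (or a
#' [evaluate_rule()] summary). These are the curves that show how the
#' predictive value of a positive screening result grows with pretest
#' prevalence; rules with higher positive likelihood ratios dominate
#' pointwise ("shift to the left").
#'
#' @param x Either a `diagnostic_summary` or a numeric `c(sensitivity,
#'   fp_rate)` pair of fractions.
#' @param grid Strictly increasing prevalences inside (0, 1).
#' @param rule Optional rule label stored on the curve.
#' @return A tibble with columns `prevalence`, `posttest` and attributes
#'   `sensitivity`, `fp_rate`, `lr`, `rule`.
#' @examples
#' ppv_curve(c(0.493, 0.0018), grid = c(0.005, 0.05))
#' @export
ppv_curve <- function(x, grid = seq(0.005, 0.05, by = 0.001), rule = NULL) {
  if (inherits(x, "diagnostic_summary")) {
    sens <- x$sensitivity / 100
    fp <- 1 - x$specificity / 100
    if (is.null(rule)) rule <- paste(x$rule, collapse = "+")
  } else {
    stopifnot(is.numeric(x), length(x) == 2)
    sens <- x[[1]]; fp <- x[[2]]
  }
  if (length(grid) == 0) stop("empty prevalence grid", call. = FALSE)
  lr <- lr_positive(sens, fp)
  out <- tibble::tibble(prevalence = grid,
                        posttest = posttest_probability(grid, lr))
  attr(out, "sensitivity") <- sens
  attr(out, "fp_rate") <- fp
  attr(out, "lr") <- lr
  attr(out, "rule") <- rule
  out
}

#' Round half away from zero
#'
#' Plain decimal rounding with ties going up (57.5 -> 58), the convention
#' used when quoting percentages; R's own `round()` rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
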