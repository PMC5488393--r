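# Cohort-level diagnostic performance -------------------------------------

#' Sensitivity and specificity of a metabolite rule on a labeled cohort
#'
#' A subject is rule-positive if any metabolite in `rule` is flagged. True
#' positives are rule-positive diseased subjects; true negatives are
#' rule-negative non-diseased subjects. Sensitivity and specificity are
#' returned as percentages (unrounded; the print method rounds to one
#' decimal).
#'
#' @param classified Output of [classify_cohort()].
#' @param disease Logical vector (or name of a logical column in
#'   `classified`) marking diseased subjects.
#' @param rule Character subset of `c("NMN", "MN", "MTY")`.
#' @return An object of class `diagnostic_summary`: a list with `rule`,
#'   `counts` (tp, fp, tn, fn), `sensitivity` and `specificity` (percent).
#' @examples
#' coh <- simulate_ppgl(sim_config(seed = 1))
#' ctl <- simulate_screening_negatives(sim_config(seed = 2))
#' both <- classify_cohort(rbind(coh, ctl))
#' evaluate_rule(both, both$group == "ppgl", rule = c("NMN", "MN"))
#' @export
evaluate_rule <- function(classified, disease, rule = c("NMN", "MN")) {
  rule <- toupper(rule)
  if (!length(rule) || !all(rule %in% c("NMN", "MN", "MTY"))) {
    stop("rule must be a non-empty subset of NMN, MN, MTY", call. = FALSE)
  }
  if (is.character(disease) && length(disease) == 1) {
    disease <- classified[[disease]]
  }
  disease <- as.logical(disease)
  if (length(disease) != nrow(classified) || anyNA(disease)) {
    stop("disease must be a complete logical vector matching the cohort",
         call. = FALSE)
  }
  pos <- rule_positive(classified, rule)
  counts <- c(
    tp = sum(pos & disease), fp = sum(pos & !disease),
    tn = sum(!pos & !disease), fn = sum(!pos & disease)
  )
  if (counts["tp"] + counts["fn"] == 0) {
    stop("no diseased subjects: sensitivity undefined", call. = FALSE)
  }
  if (counts["tn"] + counts["fp"] == 0) {
    stop("no non-diseased subjects: specificity undefined", call. = FALSE)
  }
  structure(
    list(
      rule = rule, counts = counts,
      sensitivity = 100 * counts[["tp"]] / (counts[["tp"]] + counts[["fn"]]),
      specificity = 100 * counts[["tn"]] / (counts[["tn"]] + counts[["fp"]])
    ),
    class = "diagnostic_summary"
  )
}

rule_positive <- function(classified, rule) {
  cols <- paste0("flag_", tolower(rule))
  miss <- setdiff(cols, names(classified))
  if (length(miss)) {
    stop("cohort lacks flag columns (run classify_cohort() first): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rowSums(as.matrix(classified[, cols, drop = FALSE])) >= 1
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("Rule: %s\n", paste(x$rule, collapse = "+")))
  cat(sprintf("  sensitivity %.1f%% (%d/%d)   specificity %.1f%% (%d/%d)\n",
              round_half_up(x$sensitivity, 1),
              x$counts[["tp"]], x$counts[["tp"]] + x$counts[["fn"]],
              round_half_up(x$specificity, 1),
              x$counts[["tn"]], x$counts[["tn"]] + x$counts[["fp"]]))
  invisible(x)
}

#' Exact McNemar comparison of two paired classification rules
#'
#' Compares positivity of two rules evaluated on the identical subject
#' list using the exact binomial (McNemar) test on discordant pairs: under
#' the null, a discordant pair is equally likely in either direction.
#'
#' @param pos_a,pos_b Logical positivity vectors for the same subjects.
#' @return A list with `n_discordant_a` (positive under a only),
#'   `n_discordant_b`, `statistic` (the smaller discordant count) and
#'   `p_value` (two-sided exact; 1 when there are no discordant pairs).
#' @examples
#' compare_paired_proportions(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
compare_paired_proportions <- function(pos_a, pos_b) {
  if (length(pos_a) != length(pos_b)) {
    stop("rule results must cover the identical subject list", call. = FALSE)
  }
  pos_a <- as.logical(pos_a); pos_b <- as.logical(pos_b)
  if (anyNA(pos_a) || anyNA(pos_b)) {
    stop("positivity vectors must be complete", call. = FALSE)
  }
  n10 <- sum(pos_a & !pos_b)
  n01 <- sum(!pos_a & pos_b)
  nd <- n10 + n01
  p <- if (nd == 0) 1 else stats::binom.test(n10, nd, p = 0.5)$p.value
  list(n_discordant_a = n10, n_discordant_b = n01,
       statistic = min(n10, n01), p_value = p)
}

# Multivariable score and ROC ----------------------------------------------

#' Logistic panel score from fixed coefficients
#'
#' Computes the multivariable score
#' `plogis(intercept + sum_m w_m * log(value_m / UC_m(age)))`, i.e. a
#' logistic transform of a linear predictor on log cutoff-normalised
#' concentrations. Normalising by the age-specific cutoff makes the score
#' age-consistent. Non-positive or missing concentrations are floored at
#' `floor` before the log.
#'
#' @param cohort Data frame with `nmn`, `mn`, `mty`, `age`.
#' @param coefficients Named list/vector with `intercept` and weights
#'   `nmn`, `mn`, `mty` (absent weights default to 0).
#' @param policy A [cutoff_policy()].
#' @param floor Positive floor applied before the log transform.
#' @return Numeric scores in (0, 1).
#' @export
panel_score <- function(cohort, coefficients, policy = cutoff_policy(),
                        floor = 1e-3) {
  cf <- as.list(coefficients)
  w <- function(nm) if (is.null(cf[[nm]])) 0 else cf[[nm]]
  x <- score_covariates(cohort, policy, floor)
  stats::plogis(w("intercept") +
    w("nmn") * x$nmn + w("mn") * x$mn + w("mty") * x$mty)
}

score_covariates <- function(cohort, policy, floor) {
  stopifnot(all(c("nmn", "mn", "mty", "age") %in% names(cohort)))
  flooring <- function(v) pmax(ifelse(is.na(v), floor, v), floor)
  list(
    nmn = log(flooring(cohort$nmn) / uc_normetanephrine(cohort$age, policy)),
    mn = log(flooring(cohort$mn) / policy$mn_uc),
    mty = log(flooring(cohort$mty) / policy$mty_uc)
  )
}

#' Fit a multivariable logistic panel score
#'
#' Maximum-likelihood logistic regression of disease status on
#' log cutoff-normalised concentrations of the chosen metabolites. Zero or
#' missing concentrations are floored at half the smallest positive
#' observed value of that metabolite before the log transform.
#'
#' @param cohort Data frame with `nmn`, `mn`, `mty`, `age`.
#' @param disease Logical vector of disease labels.
#' @param metabolites Metabolites to include as covariates.
#' @param policy A [cutoff_policy()].
#' @return A list of class `panel_score_fit` with `model` (the [stats::glm]
#'   fit), `scores` (fitted probabilities), `floor`, `metabolites`.
#' @export
fit_panel_score <- function(cohort, disease,
                            metabolites = c("NMN", "MN", "MTY"),
                            policy = cutoff_policy()) {
  metabolites <- toupper(metabolites)
  stopifnot(all(metabolites %in% c("NMN", "MN", "MTY")))
  disease <- as.logical(disease)
  pos_vals <- unlist(cohort[, tolower(metabolites)])
  pos_vals <- pos_vals[!is.na(pos_vals) & pos_vals > 0]
  floor <- if (length(pos_vals)) min(pos_vals) / 2 else 1e-3
  x <- score_covariates(cohort, policy, floor)
  dat <- data.frame(disease = disease)
  for (m in tolower(metabolites)) dat[[m]] <- x[[m]]
  model <- stats::glm(disease ~ ., data = dat, family = stats::binomial())
  structure(list(model = model, scores = unname(stats::fitted(model)),
                 floor = floor, metabolites = metabolites, policy = policy),
            class = "panel_score_fit")
}

#' @export
predict.panel_score_fit <- function(object, newdata, ...) {
  x <- score_covariates(newdata, object$policy, object$floor)
  dat <- as.data.frame(x[tolower(object$metabolites)])
  unname(stats::predict(object$model, newdata = dat, type = "response"))
}

#' Rank-based (Mann-Whitney) area under the ROC curve
#'
#' AUC computed from ranks: the probability that a random diseased
#' subject's score exceeds a random non-diseased subject's, with ties
#' contributing 1/2. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores Numeric scores (higher = more disease-like).
#' @param labels Logical (or 0/1) disease labels; both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(1, 2, 3, 4), c(0, 1, 0, 1)) # 0.75
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be complete and of equal length",
         call. = FALSE)
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' True- and false-positive rates at every observed score threshold
#' (positivity defined as score greater than or equal to the threshold).
#'
#' @inheritParams auc
#' @return A tibble with columns `threshold`, `tpr`, `fpr`, ordered from
#'   the most permissive to the strictest threshold.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- c(-Inf, sort(unique(scores)), Inf)
  tpr <- vapply(th, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!labels] >= t), numeric(1))
  tibble::tibble(threshold = th, tpr = tpr, fpr = fpr)
}

#' Paired comparison of two AUCs (DeLong)
#'
#' Compares the AUCs of two score vectors computed on the identical
#' subjects using DeLong's covariance estimator for paired ROC curves.
#' Identical score vectors short-circuit to a zero difference with p = 1.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Disease labels common to both.
#' @return A list with `auc_a`, `auc_b`, `delta_auc` (a minus b), `z` and
#'   `p_value`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("paired AUC comparison needs equal-length inputs", call. = FALSE)
  }
  labels <- as.logical(labels)
  auc_a <- auc(scores_a, labels)
  auc_b <- auc(scores_b, labels)
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    return(list(auc_a = auc_a, auc_b = auc_b, delta_auc = 0, z = 0,
                p_value = 1))
  }
  roc_a <- pROC::roc(labels, scores_a, levels = c(FALSE, TRUE),
                     direction = "<", quiet = TRUE)
  roc_b <- pROC::roc(labels, scores_b, levels = c(FALSE, TRUE),
                     direction = "<", quiet = TRUE)
  tst <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
  list(auc_a = auc_a, auc_b = auc_b, delta_auc = auc_a - auc_b,
       z = unname(tst$statistic), p_value = tst$p.value)
}
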