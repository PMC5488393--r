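# shared fixtures built in code

# a tiny labeled cohort with known flags: concentrations chosen relative to
# the fixed cutoffs (MN 0.45, MTY 0.10) and UC(50) ~ 0.799
tiny_cohort <- function() {
  tibble::tibble(
    subject_id = paste0("s", 1:6),
    age = rep(50, 6),
    sex = rep(c("F", "M"), 3),
    bp_status = rep(c("normotensive", "hypertensive"), 3),
    group = c("ppgl", "ppgl", "ppgl", "no_tumor", "no_tumor", "no_tumor"),
    nmn = c(2.0, 0.3, 0.3, 0.3, 0.9, 0.3),
    mn = c(0.50, 0.50, 0.10, 0.10, 0.10, 0.10),
    mty = c(0.20, 0.05, 0.05, 0.05, 0.05, 0.05)
  )
}

# build a classified cohort realising exact confusion counts for a rule:
# positives get a clearly elevated NMN, negatives a clearly normal panel
counts_cohort <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  tibble::tibble(
    age = rep(40, n),
    nmn = c(rep(2, tp), rep(0.3, fn), rep(2, fp), rep(0.3, tn)),
    mn = 0.1, mty = 0.01,
    disease = c(rep(TRUE, tp + fn), rep(FALSE, fp + tn))
  )
}

# independent pairwise-concordance AUC oracle (brute force)
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  s1 <- scores[labels]; s0 <- scores[!labels]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# direct 2x2 contingency-table posttest probability oracle
posttest_contingency <- function(pretest, sens, fp_rate) {
  pretest * sens / (pretest * sens + (1 - pretest) * fp_rate)
}
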