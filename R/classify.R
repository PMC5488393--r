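# Panel classification ----------------------------------------------------

PANEL_CATEGORIES <- c("NONE", "NMN_ONLY", "MN_ONLY", "MTY_ONLY",
                      "NMN_MN", "NMN_MTY", "MN_MTY", "TRIPLET")

#' Classify metabolite panels against upper cutoffs
#'
#' Flags each metabolite positive when its concentration is *equal to or
#' above* its upper cutoff (age-specific for normetanephrine, fixed for
#' metanephrine and methoxytyramine), derives the mutually exclusive
#' combination category from the three flags, and reports fold-elevations
#' (concentration / cutoff). Comparisons always use unrounded cutoffs.
#'
#' A missing concentration can never be positive: its flag is `FALSE`, its
#' fold is `NA`, and the row is marked `incomplete`. A row with all three
#' concentrations missing is an error.
#'
#' @param cohort A data frame with numeric columns `nmn`, `mn`, `mty`
#'   (nmol/L; `NA` allowed) and `age` (years; required wherever `nmn` is
#'   present).
#' @param policy A [cutoff_policy()].
#' @return The input as a tibble with appended columns `flag_nmn`,
#'   `flag_mn`, `flag_mty` (logical), `category` (factor over the 8
#'   combination categories), `fold_nmn`, `fold_mn`, `fold_mty`,
#'   `any_positive`, `multi_positive` (two or more flags),
#'   `strong_positive` (any fold strictly greater than 2) and `incomplete`.
#' @examples
#' classify_cohort(data.frame(age = 50, nmn = 0.34, mn = 0.151, mty = 0.028))
#' @export
classify_cohort <- function(cohort, policy = cutoff_policy()) {
  cohort <- tibble::as_tibble(cohort)
  need <- c("nmn", "mn", "mty", "age")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  all_missing <- is.na(cohort$nmn) & is.na(cohort$mn) & is.na(cohort$mty)
  if (any(all_missing)) {
    stop("all three concentrations missing for row(s) ",
         paste(utils::head(which(all_missing), 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(cohort$nmn) & is.na(cohort$age))) {
    stop("age is required wherever normetanephrine is present",
         call. = FALSE)
  }
  conc <- as.matrix(cohort[, c("nmn", "mn", "mty")])
  if (any(conc < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }

  age_eval <- ifelse(is.na(cohort$age), 0, cohort$age)  # unused when nmn NA
  uc <- cbind(
    nmn = uc_normetanephrine(age_eval, policy),
    mn = policy$mn_uc,
    mty = policy$mty_uc
  )
  fold <- conc / uc
  flag <- !is.na(fold) & fold >= 1

  cohort$flag_nmn <- unname(flag[, "nmn"])
  cohort$flag_mn <- unname(flag[, "mn"])
  cohort$flag_mty <- unname(flag[, "mty"])
  cohort$category <- panel_category(flag[, "nmn"], flag[, "mn"], flag[, "mty"])
  cohort$fold_nmn <- unname(fold[, "nmn"])
  cohort$fold_mn <- unname(fold[, "mn"])
  cohort$fold_mty <- unname(fold[, "mty"])
  nflag <- rowSums(flag)
  cohort$any_positive <- nflag >= 1
  cohort$multi_positive <- nflag >= 2
  cohort$strong_positive <- rowSums(fold > 2, na.rm = TRUE) >= 1
  cohort$incomplete <- rowSums(is.na(conc)) > 0
  cohort
}

#' Combination category from per-metabolite flags
#'
#' Maps the three positivity flags to the mutually exclusive category
#' labels `NONE`, `NMN_ONLY`, `MN_ONLY`, `MTY_ONLY`, `NMN_MN`, `NMN_MTY`,
#' `MN_MTY`, `TRIPLET`.
#'
#' @param nmn,mn,mty Logical vectors of positivity flags.
#' @return A factor with the 8 category levels.
#' @export
panel_category <- function(nmn, mn, mty) {
  lab <- character(length(nmn))
  lab[!nmn & !mn & !mty] <- "NONE"
  lab[nmn & !mn & !mty] <- "NMN_ONLY"
  lab[!nmn & mn & !mty] <- "MN_ONLY"
  lab[!nmn & !mn & mty] <- "MTY_ONLY"
  lab[nmn & mn & !mty] <- "NMN_MN"
  lab[nmn & !mn & mty] <- "NMN_MTY"
  lab[!nmn & mn & mty] <- "MN_MTY"
  lab[nmn & mn & mty] <- "TRIPLET"
  factor(lab, levels = PANEL_CATEGORIES)
}

#' Fractions of subjects in each combination category
#'
#' @param x A factor/character vector of categories, or a classified cohort
#'   (output of [classify_cohort()]) whose `category` column is used.
#' @return A named numeric vector over the 8 categories, summing to 1.
#' @examples
#' res <- classify_cohort(data.frame(age = 50, nmn = 2, mn = 1, mty = 1))
#' category_proportions(res)
#' @export
category_proportions <- function(x) {
  if (is.data.frame(x)) {
    if (!"category" %in% names(x)) {
      stop("data frame has no 'category' column; run classify_cohort() first",
           call. = FALSE)
    }
    x <- x$category
  }
  if (length(x) == 0) stop("empty result list", call. = FALSE)
  x <- factor(as.character(x), levels = PANEL_CATEGORIES)
  if (anyNA(x)) stop("unknown category labels in input", call. = FALSE)
  tab <- prop.table(table(x))
  stats::setNames(as.numeric(tab[PANEL_CATEGORIES]), PANEL_CATEGORIES)
}
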