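# Cutoff policy and age-specific upper cutoffs ---------------------------

#' Cutoff policy for the plasma metanephrine triplet panel
#'
#' Bundles every decision threshold used by the package: the cubic age
#' formula for the normetanephrine (NMN) upper cutoff in both unit systems,
#' its cap, the fixed upper cutoffs for metanephrine (MN) and
#' methoxytyramine (MTY), and the molar masses used for pg/mL to nmol/L
#' conversion.
#'
#' The NMN upper cutoff rises as the cube of age,
#' \deqn{UC(a) = c \, a^3 + b,}
#' clamped to `nmn_floor_age` below and capped at `nmn_cap` above. Defaults
#' are the values in routine diagnostic use: in nmol/L the coefficient is
#' 2.074e-6 and the intercept 0.54, with a cap of 1.09 nmol/L reached at 65
#' years; the pg/mL parameterisation (coefficient 3.792e-4, intercept 98.9,
#' cap 200) is carried independently because the two published fits were
#' rounded independently. MN and MTY use fixed cutoffs of 0.45 and
#' 0.10 nmol/L.
#'
#' Molar masses are the free-base values (NMN 183.2, MN 197.2,
#' MTY 167.2 g/mol); with these, pg/mL values divided by molar mass
#' reproduce all published nmol/L cutoffs under two-decimal rounding.
#'
#' @param nmn_cubic_coef Cubic coefficient of the NMN cutoff, nmol/L per
#'   year^3.
#' @param nmn_intercept Intercept of the NMN cutoff, nmol/L.
#' @param nmn_cap Maximum NMN cutoff, nmol/L.
#' @param nmn_cap_age Age (years) at which the cap is quoted; informational,
#'   the cap is applied as a clamp at all ages.
#' @param nmn_floor_age Ages below this are evaluated at this age (years);
#'   the cubic fit is valid from 5 years.
#' @param nmn_cubic_coef_pg,nmn_intercept_pg,nmn_cap_pg The pg/mL
#'   parameterisation of the same curve.
#' @param mn_uc Fixed metanephrine cutoff, nmol/L.
#' @param mty_uc Fixed methoxytyramine cutoff, nmol/L.
#' @param molar_mass Named numeric vector of molar masses (g/mol) with
#'   entries `NMN`, `MN`, `MTY`.
#'
#' @return An object of class `cutoff_policy` (a named list).
#' @seealso [uc_normetanephrine()], [pg_to_nmol()], [cutoff_policy_from_file()]
#' @examples
#' pol <- cutoff_policy()
#' uc_normetanephrine(c(11, 19, 65), pol)
#' @export
cutoff_policy <- function(nmn_cubic_coef = 0.000002074,
                          nmn_intercept = 0.54,
                          nmn_cap = 1.09,
                          nmn_cap_age = 65,
                          nmn_floor_age = 5,
                          nmn_cubic_coef_pg = 0.0003792,
                          nmn_intercept_pg = 98.9,
                          nmn_cap_pg = 200,
                          mn_uc = 0.45,
                          mty_uc = 0.10,
                          molar_mass = c(NMN = 183.2, MN = 197.2, MTY = 167.2)) {
  pol <- list(
    nmn_cubic_coef = nmn_cubic_coef, nmn_intercept = nmn_intercept,
    nmn_cap = nmn_cap, nmn_cap_age = nmn_cap_age,
    nmn_floor_age = nmn_floor_age,
    nmn_cubic_coef_pg = nmn_cubic_coef_pg,
    nmn_intercept_pg = nmn_intercept_pg, nmn_cap_pg = nmn_cap_pg,
    mn_uc = mn_uc, mty_uc = mty_uc, molar_mass = molar_mass
  )
  class(pol) <- "cutoff_policy"
  validate_cutoff_policy(pol)
  pol
}

validate_cutoff_policy <- function(pol) {
  num <- unlist(pol[setdiff(names(pol), "molar_mass")])
  if (!all(is.finite(num)) || any(num <= 0)) {
    stop("all cutoff policy constants must be strictly positive and finite",
         call. = FALSE)
  }
  mm <- pol$molar_mass
  if (!all(c("NMN", "MN", "MTY") %in% names(mm)) || any(mm <= 0)) {
    stop("molar_mass must contain positive entries named NMN, MN, MTY",
         call. = FALSE)
  }
  # the cap must not undercut the formula at the youngest evaluable age
  floor_val <- pol$nmn_cubic_coef * pol$nmn_floor_age^3 + pol$nmn_intercept
  if (pol$nmn_cap < floor_val) {
    stop("nmn_cap is below the formula value at nmn_floor_age", call. = FALSE)
  }
  invisible(pol)
}

#' @export
print.cutoff_policy <- function(x, ...) {
  cat("Cutoff policy (nmol/L):\n")
  cat(sprintf("  NMN: %.6g * age^3 + %.3g, capped at %.3g (ages clamped to >= %g)\n",
              x$nmn_cubic_coef, x$nmn_intercept, x$nmn_cap, x$nmn_floor_age))
  cat(sprintf("  MN : %.3g    MTY: %.3g\n", x$mn_uc, x$mty_uc))
  invisible(x)
}

#' Load a cutoff policy from a YAML configuration file
#'
#' Reads a YAML file whose keys mirror the arguments of [cutoff_policy()];
#' keys that are absent keep their defaults. `molar_mass` may be given as a
#' named mapping.
#'
#' @param path Path to a YAML file.
#' @return A `cutoff_policy` object.
#' @export
cutoff_policy_from_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(cutoff_policy))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("unknown cutoff policy keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$molar_mass)) cfg$molar_mass <- unlist(cfg$molar_mass)
  do.call(cutoff_policy, cfg)
}

#' Age-specific upper cutoff for plasma normetanephrine
#'
#' Evaluates the cubic-in-age upper cutoff, `min(coef * age^3 + intercept,
#' cap)`, with ages below the validity floor (default 5 years) clamped to
#' the floor. The unrounded value is returned; two-decimal rounding is a
#' display convention only and positivity decisions always use the
#' unrounded cutoff.
#'
#' @param age Age(s) in years; must be non-negative.
#' @param policy A [cutoff_policy()].
#' @return Upper cutoff(s) in nmol/L.
#' @examples
#' round(uc_normetanephrine(c(11, 19)), 2) # 0.54, 0.55
#' uc_normetanephrine(80)                  # cap: 1.09
#' @export
uc_normetanephrine <- function(age, policy = cutoff_policy()) {
  check_age(age)
  a <- pmax(age, policy$nmn_floor_age)
  pmin(policy$nmn_cubic_coef * a^3 + policy$nmn_intercept, policy$nmn_cap)
}

#' @rdname uc_normetanephrine
#' @details `uc_normetanephrine_pg()` evaluates the independently published
#'   pg/mL parameterisation of the same curve (the two fits were rounded
#'   independently, so the pg/mL curve divided by molar mass agrees with the
#'   nmol/L curve only to within about 2%).
#' @return For `uc_normetanephrine_pg()`, upper cutoff(s) in pg/mL.
#' @export
uc_normetanephrine_pg <- function(age, policy = cutoff_policy()) {
  check_age(age)
  a <- pmax(age, policy$nmn_floor_age)
  pmin(policy$nmn_cubic_coef_pg * a^3 + policy$nmn_intercept_pg,
       policy$nmn_cap_pg)
}

check_age <- function(age) {
  if (length(age) == 0 || anyNA(age) || any(age < 0)) {
    stop("age must be non-negative and non-missing", call. = FALSE)
  }
  invisible(age)
}

#' Upper cutoff for any panel metabolite
#'
#' Dispatches to the age-specific normetanephrine cutoff or the fixed
#' metanephrine / methoxytyramine cutoffs.
#'
#' @param metabolite One of `"NMN"`, `"MN"`, `"MTY"` (recycled against
#'   `age`).
#' @param age Age in years; required (non-NA) for NMN.
#' @inheritParams uc_normetanephrine
#' @return Upper cutoff(s) in nmol/L.
#' @export
uc_for <- function(metabolite, age = NA_real_, policy = cutoff_policy()) {
  metabolite <- toupper(metabolite)
  if (!all(metabolite %in% c("NMN", "MN", "MTY"))) {
    stop("unknown metabolite; expected NMN, MN or MTY", call. = FALSE)
  }
  n <- max(length(metabolite), length(age))
  metabolite <- rep_len(metabolite, n)
  age <- rep_len(age, n)
  out <- numeric(n)
  is_nmn <- metabolite == "NMN"
  if (any(is_nmn)) {
    if (anyNA(age[is_nmn])) {
      stop("age is required for the normetanephrine cutoff", call. = FALSE)
    }
    out[is_nmn] <- uc_normetanephrine(age[is_nmn], policy)
  }
  out[metabolite == "MN"] <- policy$mn_uc
  out[metabolite == "MTY"] <- policy$mty_uc
  out
}

# Unit conversion ---------------------------------------------------------

#' Convert metabolite concentrations between pg/mL and nmol/L
#'
#' Mass-to-molar conversion by the metabolite's molar mass:
#' `nmol/L = (pg/mL) / (g/mol)`. The round trip
#' `nmol_to_pg(pg_to_nmol(x))` restores `x` to floating-point accuracy.
#'
#' @param value Concentration value(s); non-negative.
#' @param metabolite `"NMN"`, `"MN"` or `"MTY"` (recycled).
#' @param policy A [cutoff_policy()] supplying molar masses.
#' @return Converted concentration(s).
#' @examples
#' round(pg_to_nmol(c(200, 88, 17), c("NMN", "MN", "MTY")), 2)
#' @export
pg_to_nmol <- function(value, metabolite, policy = cutoff_policy()) {
  value / molar_mass_of(metabolite, value, policy)
}

#' @rdname pg_to_nmol
#' @export
nmol_to_pg <- function(value, metabolite, policy = cutoff_policy()) {
  value * molar_mass_of(metabolite, value, policy)
}

molar_mass_of <- function(metabolite, value, policy) {
  metabolite <- toupper(metabolite)
  if (!all(metabolite %in% names(policy$molar_mass))) {
    stop("unknown metabolite; expected one of ",
         paste(names(policy$molar_mass), collapse = ", "), call. = FALSE)
  }
  if (any(value < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  n <- max(length(metabolite), length(value))
  unname(policy$molar_mass[rep_len(metabolite, n)])
}

# Empirical cutoff derivation ---------------------------------------------

#' Derive an upper cutoff from a reference sample
#'
#' Returns the sample maximum or an upper percentile (97.5th or 99.5th) of
#' a reference distribution. The methoxytyramine cutoff of 0.10 nmol/L was
#' set at the reference maximum; percentile-based cutoffs are the common
#' alternative. Percentiles use linear interpolation between order
#' statistics (R's default `quantile()` type 7); this estimator is fixed so
#' derived cutoffs are reproducible.
#'
#' @param values Non-empty numeric vector of non-negative reference
#'   concentrations.
#' @param method `"max"`, `"p97.5"` or `"p99.5"`.
#' @return A single cutoff value.
#' @examples
#' derive_uc(c(0.028, 0.041, 0.100, 0.015), method = "max")
#' @export
derive_uc <- function(values, method = c("max", "p97.5", "p99.5")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("empty reference sample", call. = FALSE)
  if (anyNA(values) || any(values < 0)) {
    stop("reference values must be non-negative and non-missing",
         call. = FALSE)
  }
  switch(method,
    max = max(values),
    p97.5 = unname(stats::quantile(values, 0.975, type = 7)),
    p99.5 = unname(stats::quantile(values, 0.995, type = 7))
  )
}
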