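# Synthetic cohort generator ----------------------------------------------

#' Simulation configuration for synthetic screening cohorts
#'
#' Defines the generative model for four cohorts: a tumor-free reference
#' population (used to set cutoffs), a no-tumor screening population
#' (patients tested because of suspicion, with a heavier upper tail of
#' false positives), and PPGL and HNPGL tumor populations built from a
#' mixture of biochemical phenotypes.
#'
#' Concentrations are log-normal. For normetanephrine the log-scale
#' location rises linearly with age (slope `nmn_age_slope`) and the
#' dispersion at each age is set so that the population 97.5th percentile
#' equals the capped cubic upper cutoff at that age — so by construction
#' about 2.5% of tumor-free subjects sit at or above the age-specific
#' cutoff at every age, while the age correlation of log concentration
#' stays near the observed 0.32. Metanephrine and methoxytyramine have
#' age-free locations with multiplicative male effects (x1.30 and x1.09),
#' and normetanephrine a multiplicative hypertension effect (x1.12).
#'
#' Tumor cohorts draw a combination category (which metabolites are
#' elevated) from `mixture`, then multiply each elevated metabolite's
#' cutoff by a fold-elevation drawn from a log-normal truncated to folds
#' greater than 1; non-elevated metabolites are drawn from the reference
#' law truncated below the cutoff. The default PPGL mixture is the
#' category table observed in 213 tumors (47 NMN only, 9 MN only, 3 MTY
#' only, 56 NMN+MN, 46 NMN+MTY, 49 all three, 3 silent, and no MN+MTY
#' pairs); the default HNPGL mixture is half silent with a minority of NMN
#' and/or MTY secretors and no MN secretors.
#'
#' The screening population applies, independently per metabolite, a small
#' tail-replacement probability (`screening_extra_fp`) that lifts the value
#' just above its cutoff, calibrated so the per-metabolite false-positive
#' rates are about 3.9% (NMN), 0.4% (MN) and 1.1% (MTY); setting these to
#' zero reverts to the reference calibration.
#'
#' All randomness flows from `seed`: each generator uses a fixed
#' per-group offset of the master seed, so the four cohorts of one
#' configuration are mutually independent and individually reproducible.
#'
#' @param seed Integer master seed (`NULL` for the current RNG state).
#' @param n_reference,n_screening,n_ppgl,n_hnpgl Group sizes.
#' @param ... Overrides for any default listed in `sim_config()$...`;
#'   unknown names are an error.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' ref <- simulate_reference(cfg)
#' @export
sim_config <- function(seed = NULL, n_reference = 423, n_screening = 1712,
                       n_ppgl = 213, n_hnpgl = 38, ...) {
  cfg <- list(
    seed = seed,
    n_reference = n_reference, n_screening = n_screening,
    n_ppgl = n_ppgl, n_hnpgl = n_hnpgl,
    # demographics: age ranges and composition per group
    reference_age_range = c(18, 81), reference_p_male = 185 / 423,
    reference_p_hyper = 262 / 423,
    screening_age_range = c(10, 93), screening_p_male = 860 / 1712,
    screening_p_hyper = 0.60,
    ppgl_age_range = c(11, 82), ppgl_p_male = 96 / 213,
    ppgl_p_hyper = 0.65,
    hnpgl_age_range = c(26, 75), hnpgl_p_male = 16 / 38,
    hnpgl_p_hyper = 0.40,
    # tumor-free concentration law (log scale, nmol/L)
    nmn_log_median = -1.16,   # location at age 45, normotensive
    nmn_age_slope = 0.008,    # per year of age
    nmn_hyper_mult = 1.12,
    mn_log_median = log(0.135),  # female location
    mn_sigma = 0.35, mn_male_mult = 1.30,
    mty_log_median = log(0.027), # female location
    mty_sigma = 0.43, mty_male_mult = 1.09,
    # screening-population false-positive tail replacement
    screening_extra_fp = c(nmn = 0.0144, mn = 0.0021, mty = 0.0094),
    screening_fp_tail_sd = 0.35,
    # tumor phenotype mixtures over combination categories
    ppgl_mixture = c(NONE = 3, NMN_ONLY = 47, MN_ONLY = 9, MTY_ONLY = 3,
                     NMN_MN = 56, NMN_MTY = 46, MN_MTY = 0,
                     TRIPLET = 49) / 213,
    hnpgl_mixture = c(NONE = 0.500, NMN_ONLY = 0.184, MN_ONLY = 0,
                      MTY_ONLY = 0.279, NMN_MN = 0, NMN_MTY = 0.037,
                      MN_MTY = 0, TRIPLET = 0),
    # fold-elevation distributions (log scale, truncated to fold > 1)
    ppgl_fold = list(nmn = c(meanlog = log(3), sdlog = 1.1),
                     mn = c(meanlog = log(1.9), sdlog = 1.0),
                     mty = c(meanlog = log(1.9), sdlog = 1.0)),
    hnpgl_fold = list(nmn = c(meanlog = log(1.8), sdlog = 0.8),
                      mn = c(meanlog = log(1.8), sdlog = 0.8),
                      mty = c(meanlog = log(1.8), sdlog = 0.8))
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop("unknown sim_config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  for (nm in c("n_reference", "n_screening", "n_ppgl", "n_hnpgl")) {
    chk(length(cfg[[nm]]) == 1 && cfg[[nm]] >= 0, paste(nm, "must be >= 0"))
  }
  for (mx in c("ppgl_mixture", "hnpgl_mixture")) {
    m <- cfg[[mx]]
    chk(setequal(names(m), PANEL_CATEGORIES), paste(mx, "must cover the 8 categories"))
    chk(all(m >= 0) && abs(sum(m) - 1) < 1e-8, paste(mx, "must be non-negative and sum to 1"))
  }
  chk(all(cfg$screening_extra_fp >= 0 & cfg$screening_extra_fp < 1),
      "screening_extra_fp must be probabilities")
  chk(all(c(cfg$nmn_hyper_mult, cfg$mn_male_mult, cfg$mty_male_mult,
            cfg$mn_sigma, cfg$mty_sigma, cfg$screening_fp_tail_sd) > 0),
      "multipliers and dispersions must be positive")
  for (p in c("reference_p_male", "reference_p_hyper", "screening_p_male",
              "screening_p_hyper", "ppgl_p_male", "ppgl_p_hyper",
              "hnpgl_p_male", "hnpgl_p_hyper")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must lie in [0, 1]"))
  }
  if (length(problems)) {
    stop("invalid simulation config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(cfg)
}

# per-group fixed offsets of the master seed (kept below 2^31)
group_seed <- function(seed, group) {
  offs <- c(reference = 101L, screening = 211L, ppgl = 307L, hnpgl = 401L)
  (as.integer(seed) + offs[[group]] * 10007L) %% .Machine$integer.max
}

with_group_seed <- function(seed, group, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(group_seed(seed, group))
  force(expr)
}

# log-scale location and total dispersion of tumor-free NMN at given ages;
# the total dispersion pins the 97.5th percentile of the mixed
# (normo/hypertensive) population to the capped cubic cutoff at every age
nmn_law <- function(age, cfg, policy) {
  mu <- cfg$nmn_log_median + cfg$nmn_age_slope * (age - 45)
  hm <- log(cfg$nmn_hyper_mult)
  p_h <- cfg$reference_p_hyper
  sig_tot <- (log(uc_normetanephrine(age, policy)) - mu - p_h * hm) /
    stats::qnorm(0.975)
  sig_ind <- sqrt(pmax(sig_tot^2 - p_h * (1 - p_h) * hm^2, 1e-6))
  list(mu = mu, sigma = sig_ind, hyper_shift = hm, hyper_centering = p_h * hm)
}

draw_demographics <- function(n, age_range, p_male, p_hyper, group) {
  tibble::tibble(
    subject_id = sprintf("%s_%05d", group, seq_len(n)),
    age = stats::runif(n, age_range[1], age_range[2]),
    sex = ifelse(stats::runif(n) < p_male, "M", "F"),
    bp_status = ifelse(stats::runif(n) < p_hyper, "hypertensive",
                       "normotensive"),
    group = group
  )
}

# tumor-free concentration draws given demographics
draw_negative_panel <- function(demo, cfg, policy) {
  n <- nrow(demo)
  male <- demo$sex == "M"
  hyper <- demo$bp_status == "hypertensive"
  law <- nmn_law(demo$age, cfg, policy)
  nmn <- exp(law$mu + hyper * law$hyper_shift +
             stats::rnorm(n, 0, law$sigma))
  mn <- exp(cfg$mn_log_median + male * log(cfg$mn_male_mult) +
            stats::rnorm(n, 0, cfg$mn_sigma))
  mty <- exp(cfg$mty_log_median + male * log(cfg$mty_male_mult) +
             stats::rnorm(n, 0, cfg$mty_sigma))
  tibble::as_tibble(cbind(demo, tibble::tibble(nmn = nmn, mn = mn, mty = mty)))
}

#' Simulate the tumor-free reference population
#'
#' Ages are uniform over the configured range (default 18-81), sex and
#' blood-pressure status are Bernoulli with the configured composition,
#' and concentrations follow the log-normal law described in
#' [sim_config()]. By calibration, about 2.5% of subjects lie at or above
#' the age-specific normetanephrine cutoff and roughly 0.2% above the
#' fixed metanephrine and methoxytyramine cutoffs.
#'
#' @param config A [sim_config()].
#' @param n Number of subjects (defaults to `config$n_reference`).
#' @param policy A [cutoff_policy()].
#' @return A tibble with `subject_id`, `age`, `sex`, `bp_status`, `group`
#'   and concentrations `nmn`, `mn`, `mty` in nmol/L.
#' @export
simulate_reference <- function(config = sim_config(), n = config$n_reference,
                               policy = cutoff_policy()) {
  if (n <= 0) stop("empty cohort: n must be positive", call. = FALSE)
  with_group_seed(config$seed, "reference", {
    demo <- draw_demographics(n, config$reference_age_range,
                              config$reference_p_male,
                              config$reference_p_hyper, "reference")
    draw_negative_panel(demo, config, policy)
  })
}

#' Simulate the no-tumor screening population
#'
#' Like [simulate_reference()] but over the screening demographic (ages
#' 10-93 by default) and with an inflated upper tail: independently per
#' metabolite, a subject's value is replaced with probability
#' `screening_extra_fp[m]` by a value just above the cutoff
#' (`UC * exp(|N(0, screening_fp_tail_sd)|)`). Default calibration targets
#' per-metabolite false-positive rates of about 3.9% (NMN), 0.4% (MN) and
#' 1.1% (MTY), with multi-positive results rare because the replacements
#' are independent.
#'
#' @inheritParams simulate_reference
#' @param n Number of subjects (defaults to `config$n_screening`).
#' @export
simulate_screening_negatives <- function(config = sim_config(),
                                         n = config$n_screening,
                                         policy = cutoff_policy()) {
  if (n <= 0) stop("empty cohort: n must be positive", call. = FALSE)
  with_group_seed(config$seed, "screening", {
    demo <- draw_demographics(n, config$screening_age_range,
                              config$screening_p_male,
                              config$screening_p_hyper, "no_tumor")
    coh <- draw_negative_panel(demo, config, policy)
    for (m in c("nmn", "mn", "mty")) {
      hit <- stats::runif(n) < config$screening_extra_fp[[m]]
      if (any(hit)) {
        uc <- uc_for(toupper(m), coh$age[hit], policy)
        coh[[m]][hit] <- uc *
          exp(abs(stats::rnorm(sum(hit), 0, config$screening_fp_tail_sd)))
      }
    }
    coh
  })
}

# log-normal fold truncated to > 1 (log-fold truncated normal above 0)
draw_fold <- function(n, pars) {
  lo <- stats::pnorm(0, pars[["meanlog"]], pars[["sdlog"]])
  exp(stats::qnorm(stats::runif(n, lo, 1), pars[["meanlog"]], pars[["sdlog"]]))
}

# tumor-free draw truncated strictly below the cutoff
draw_below_uc <- function(mu, sigma, uc) {
  hi <- stats::pnorm(log(uc), mu, sigma)
  exp(stats::qnorm(stats::runif(length(mu), 0, hi), mu, sigma))
}

simulate_tumor <- function(config, n, policy, group, mixture, fold_pars,
                           age_range, p_male, p_hyper) {
  if (n <= 0) stop("empty cohort: n must be positive", call. = FALSE)
  with_group_seed(config$seed, group, {
    demo <- draw_demographics(n, age_range, p_male, p_hyper, group)
    cat_draw <- sample(PANEL_CATEGORIES, n, replace = TRUE,
                       prob = mixture[PANEL_CATEGORIES])
    elevated <- cbind(
      nmn = cat_draw %in% c("NMN_ONLY", "NMN_MN", "NMN_MTY", "TRIPLET"),
      mn = cat_draw %in% c("MN_ONLY", "NMN_MN", "MN_MTY", "TRIPLET"),
      mty = cat_draw %in% c("MTY_ONLY", "NMN_MTY", "MN_MTY", "TRIPLET")
    )
    male <- demo$sex == "M"
    hyper <- demo$bp_status == "hypertensive"
    law <- nmn_law(demo$age, config, policy)
    mu <- cbind(
      nmn = law$mu + hyper * law$hyper_shift,
      mn = config$mn_log_median + male * log(config$mn_male_mult),
      mty = config$mty_log_median + male * log(config$mty_male_mult)
    )
    sigma <- cbind(nmn = law$sigma,
                   mn = rep(config$mn_sigma, n),
                   mty = rep(config$mty_sigma, n))
    conc <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("nmn", "mn", "mty")))
    for (m in c("nmn", "mn", "mty")) {
      uc <- uc_for(toupper(m), demo$age, policy)
      el <- elevated[, m]
      if (any(el)) conc[el, m] <- uc[el] * draw_fold(sum(el), fold_pars[[m]])
      if (any(!el)) {
        conc[!el, m] <- draw_below_uc(mu[!el, m], sigma[!el, m], uc[!el])
      }
    }
    tibble::as_tibble(cbind(demo, tibble::as_tibble(conc)))
  })
}

#' Simulate PPGL and HNPGL tumor cohorts
#'
#' Each tumor draws a combination category (which metabolites are
#' elevated) from the configured phenotype mixture; elevated metabolites
#' are set to cutoff times a heavy-tailed fold-elevation (most more than
#' 2-fold, some just above the cutoff), non-elevated metabolites are drawn
#' from the tumor-free law truncated below the cutoff, and silent tumors
#' have fully negative panels. The default HNPGL mixture contains no
#' metanephrine secretors.
#'
#' @inheritParams simulate_reference
#' @param n Number of tumors (defaults to `config$n_ppgl` /
#'   `config$n_hnpgl`).
#' @export
simulate_ppgl <- function(config = sim_config(), n = config$n_ppgl,
                          policy = cutoff_policy()) {
  simulate_tumor(config, n, policy, "ppgl", config$ppgl_mixture,
                 config$ppgl_fold, config$ppgl_age_range,
                 config$ppgl_p_male, config$ppgl_p_hyper)
}

#' @rdname simulate_ppgl
#' @export
simulate_hnpgl <- function(config = sim_config(), n = config$n_hnpgl,
                           policy = cutoff_policy()) {
  simulate_tumor(config, n, policy, "hnpgl", config$hnpgl_mixture,
                 config$hnpgl_fold, config$hnpgl_age_range,
                 config$hnpgl_p_male, config$hnpgl_p_hyper)
}

#' Simulate the full four-group study cohort
#'
#' Binds reference, no-tumor screening, PPGL and HNPGL cohorts generated
#' from one configuration (each group on its own seed stream).
#'
#' @inheritParams simulate_reference
#' @return A tibble with all four groups and a `group` column.
#' @export
simulate_study <- function(config = sim_config(), policy = cutoff_policy()) {
  rbind(
    simulate_reference(config, policy = policy),
    simulate_screening_negatives(config, policy = policy),
    simulate_ppgl(config, policy = policy),
    simulate_hnpgl(config, policy = policy)
  )
}
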