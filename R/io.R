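# Cohort CSV input/output --------------------------------------------------

COHORT_UNITS <- c("nmol_per_L", "pg_per_mL")

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8, header-required cohort file with
#' columns (case-insensitive) `subject_id`, `age`, `sex`, `bp_status`,
#' `group`, `nmn`, `mn`, `mty`, and optionally `units`. Concentrations in
#' pg/mL are converted to the canonical internal unit, nmol/L, using the
#' policy's molar masses. Validation is total: every problem found (missing
#' columns, unknown units, duplicate ids, negative values, out-of-range
#' ages) is collected and reported in a single structured error; no rows
#' are silently dropped.
#'
#' @param path Path to a CSV file.
#' @param units `"nmol_per_L"` or `"pg_per_mL"`; overrides (and must not
#'   contradict) any `units` column in the file. If neither is given,
#'   nmol/L is assumed.
#' @param policy A [cutoff_policy()] for unit conversion.
#' @return A tibble in nmol/L with a `units` attribute of `"nmol_per_L"`.
#' @export
read_cohort <- function(path, units = NULL, policy = cutoff_policy()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("empty data section in ", path, call. = FALSE)
  names(raw) <- tolower(names(raw))

  problems <- character()
  mandatory <- c("subject_id", "age", "nmn", "mn", "mty")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop("schema error: missing mandatory column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (opt in c("sex", "bp_status", "group")) {
    if (!opt %in% names(raw)) raw[[opt]] <- "unknown"
  }

  file_units <- NULL
  if ("units" %in% names(raw)) {
    u <- unique(raw$units)
    if (length(u) != 1) problems <- c(problems, "units declared inconsistently across rows")
    file_units <- u[1]
  }
  units <- units %||% file_units %||% "nmol_per_L"
  if (!units %in% COHORT_UNITS) {
    stop("unknown units '", units, "'; expected one of ",
         paste(COHORT_UNITS, collapse = ", "), call. = FALSE)
  }
  if (!is.null(file_units) && file_units %in% COHORT_UNITS &&
      !identical(units, file_units)) {
    problems <- c(problems, sprintf(
      "requested units '%s' contradict file units '%s'", units, file_units))
  }

  dup <- unique(raw$subject_id[duplicated(raw$subject_id)])
  if (length(dup)) {
    problems <- c(problems, paste("duplicate subject_id:",
                                  paste(utils::head(dup, 5), collapse = ", ")))
  }
  for (m in c("nmn", "mn", "mty")) {
    v <- suppressWarnings(as.numeric(raw[[m]]))
    bad <- which(!is.na(raw[[m]]) & raw[[m]] != "" & is.na(v))
    if (length(bad)) {
      problems <- c(problems, sprintf("non-numeric %s in row(s) %s", m,
                                      paste(utils::head(bad, 5), collapse = ", ")))
    }
    if (any(v < 0, na.rm = TRUE)) {
      problems <- c(problems, sprintf("negative %s concentration(s)", m))
    }
    raw[[m]] <- v
  }
  age <- suppressWarnings(as.numeric(raw$age))
  if (any(is.na(age) | age < 0 | age > 120)) {
    problems <- c(problems, "age must be present and within [0, 120] for all rows")
  }
  raw$age <- age
  if (length(problems)) {
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  if (units == "pg_per_mL") {
    for (m in c("nmn", "mn", "mty")) {
      raw[[m]] <- pg_to_nmol(raw[[m]], toupper(m), policy)
    }
  }
  raw$units <- NULL
  out <- tibble::as_tibble(raw[, c("subject_id", "age", "sex", "bp_status",
                                   "group", "nmn", "mn", "mty")])
  attr(out, "units") <- "nmol_per_L"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to CSV
#'
#' Writes the canonical cohort schema with a `units` column; concentrations
#' can be emitted in pg/mL, converting from the internal nmol/L
#' representation. Reading the file back with [read_cohort()] restores the
#' nmol/L values to near machine precision.
#'
#' @param cohort A cohort tibble (nmol/L).
#' @param path Output path.
#' @param units Output unit system.
#' @param policy A [cutoff_policy()] for unit conversion.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, units = c("nmol_per_L", "pg_per_mL"),
                         policy = cutoff_policy()) {
  units <- match.arg(units)
  out <- as.data.frame(cohort)
  if (units == "pg_per_mL") {
    for (m in c("nmn", "mn", "mty")) {
      out[[m]] <- nmol_to_pg(out[[m]], toupper(m), policy)
    }
  }
  out$units <- units
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an analysis report to CSV or JSON
#'
#' Serialises package result objects with stable field ordering:
#' `diagnostic_summary` objects and lists of them become a JSON report
#' (rule, confusion counts, sensitivity/specificity); curve tibbles (for
#' example from [ppv_curve()]) become CSV with their scalar attributes as
#' JSON metadata when written as JSON. The format is inferred from the
#' file extension unless given.
#'
#' @param x A `diagnostic_summary`, a list of them, or a data frame.
#' @param path Output path (`.json` or `.csv`).
#' @param format `"json"`, `"csv"` or `"auto"`.
#' @param digits Number of significant digits for JSON serialisation
#'   (`NA` keeps full precision).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("auto", "json", "csv"),
                         digits = NA) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    if (!is.data.frame(x)) {
      stop("CSV reports require a data frame; use JSON for summaries",
           call. = FALSE)
    }
    utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    return(invisible(path))
  }
  jsonlite::write_json(report_payload(x), path, auto_unbox = TRUE,
                       digits = digits, pretty = TRUE)
  invisible(path)
}

report_payload <- function(x) {
  if (inherits(x, "diagnostic_summary")) {
    return(list(rule = paste(x$rule, collapse = "+"),
                counts = as.list(x$counts),
                sensitivity = x$sensitivity, specificity = x$specificity))
  }
  if (is.data.frame(x)) {
    meta <- attributes(x)[c("sensitivity", "fp_rate", "lr", "rule")]
    meta <- meta[!vapply(meta, is.null, logical(1))]
    if (length(meta)) return(list(meta = meta, data = x))
    return(x)
  }
  if (is.list(x)) return(lapply(x, report_payload))
  x
}
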