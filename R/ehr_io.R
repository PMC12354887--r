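# Event-table IO, phecode mapping and onset derivation: the shared data
# backbone. Ages are stored in days since birth; one year = 365.25 days
# everywhere, so year/week bins are age-anchored and site-independent.

DAYS_PER_YEAR <- 365.25
CODE_SYSTEMS <- c("ICD9", "ICD10", "CPT4")

#' Convert an age in days to an age-year index
#' @param age_days Non-negative integer vector.
#' @return Integer year index, `floor(age_days / 365.25)`.
#' @export
age_to_year <- function(age_days) as.integer(floor(age_days / DAYS_PER_YEAR))

#' Convert an age in days to an age-week index
#' @param age_days Non-negative integer vector.
#' @param n_weeks Number of week bins; later ages are clipped to the last bin.
#' @return Integer week index in `[0, n_weeks - 1]`.
#' @export
age_to_week <- function(age_days, n_weeks = 4320L) {
  pmin(as.integer(floor(age_days / 7)), n_weeks - 1L)
}

validate_events <- function(events) {
  need <- c("patient_id", "age_days", "code", "code_system")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0L)
    stop("event table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(events) == 0L) return(invisible(events))
  bad <- which(is.na(events$age_days) | events$age_days < 0)
  if (length(bad) > 0L)
    stop("validation error: negative or missing age_days at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(is.na(events$code) | !nzchar(events$code))
  if (length(bad) > 0L)
    stop("validation error: empty code at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  unknown <- setdiff(unique(events$code_system), CODE_SYSTEMS)
  if (length(unknown) > 0L)
    stop("validation error: unknown code_system ",
         paste(unknown, collapse = ", "))
  invisible(events)
}

#' Read a coded event table
#'
#' Reads a CSV with columns `patient_id, age_days, code, code_system`,
#' validates every row (non-negative ages, non-empty codes, known code
#' systems) and returns rows sorted by `(patient_id, age_days, code)`.
#'
#' @param path Path to a CSV file.
#' @return A sorted, validated `data.frame`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ev <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("patient_id", "code", "code_system"),
    integer = "age_days")))
  validate_events(ev)
  ev <- ev[order(ev$patient_id, ev$age_days, ev$code), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write a coded event table
#' @param events Event table.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  data.table::fwrite(events, path)
  invisible(path)
}

#' Read / write a phecode map
#'
#' The map format is a CSV with columns `code, code_system, phecode,
#' disease_class`; each diagnosis code maps to exactly one phecode.
#' @param path CSV path.
#' @return `read_phecode_map`: a `data.frame`.
#' @export
read_phecode_map <- function(path) {
  m <- as.data.frame(data.table::fread(path, colClasses = "character"))
  need <- c("code", "code_system", "phecode", "disease_class")
  if (!all(need %in% names(m))) stop("phecode map missing required columns")
  if (anyDuplicated(m$code) > 0L)
    stop("phecode map assigns some code to more than one phecode")
  m
}

#' @rdname read_phecode_map
#' @param map Phecode map `data.frame`.
#' @export
write_phecode_map <- function(map, path) {
  data.table::fwrite(map, path)
  invisible(path)
}

#' Map diagnosis events to phecode occurrences
#'
#' Applies a code-to-phecode map to an event table. Procedure codes (and any
#' unmapped diagnosis code) are dropped; one output row is produced per
#' mapped diagnosis event, and a single occurrence of any mapped code
#' qualifies the patient for the phenotype.
#'
#' @param events Event table.
#' @param map Phecode map with columns `code`, `phecode` (and optionally
#'   `disease_class`).
#' @return A `data.frame` with columns `patient_id, phecode, age_days`.
#' @export
map_to_phecodes <- function(events, map) {
  if (nrow(map) == 0L) stop("empty phecode map")
  validate_events(events)
  idx <- match(events$code, map$code)
  keep <- !is.na(idx)
  out <- data.frame(
    patient_id = events$patient_id[keep],
    phecode = map$phecode[idx[keep]],
    age_days = events$age_days[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$patient_id, out$phecode, out$age_days), , drop = FALSE]
}

#' Compute per-(patient, phecode) onset ages
#'
#' Onset is the age of the first qualifying occurrence: the minimum
#' `age_days` over the patient's events mapping to the phecode, reported
#' both at day resolution and as the age-year index
#' `floor(age_days / 365.25)`.
#'
#' @param occurrences Output of [map_to_phecodes()].
#' @return A `data.frame` with columns `patient_id, phecode,
#'   onset_age_days, onset_age_years`.
#' @export
compute_onset_table <- function(occurrences) {
  if (nrow(occurrences) == 0L) {
    return(data.frame(patient_id = character(), phecode = character(),
                      onset_age_days = integer(), onset_age_years = integer(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(occurrences)
  on <- dt[, .(onset_age_days = min(age_days)), by = .(patient_id, phecode)]
  on[, onset_age_years := age_to_year(onset_age_days)]
  data.table::setorder(on, patient_id, phecode)
  as.data.frame(on)
}
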