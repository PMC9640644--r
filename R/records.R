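# Diagnosis-record preprocessing: parsing, per-day deduplication, asthma
# labeling, cohort filters, and the patient-by-disease-group count matrix.

#' Construct a diagnosis corpus
#'
#' @param patients data.frame with columns patient_id, sex, birth_year and
#'   optionally asthma (logical) and drug_flag.
#' @param events data.frame with columns patient_id, date (Date or
#'   ISO-8601 character), code, code_system.
#' @return an object of class `diagnosis_corpus`.
#' @export
new_diagnosis_corpus <- function(patients, events) {
  stopifnot(all(c("patient_id", "date", "code", "code_system") %in% names(events)),
            all(c("patient_id") %in% names(patients)))
  if (!inherits(events$date, "Date")) {
    parsed <- as.Date(events$date, format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(events$date))
    if (length(bad)) {
      stop(sprintf("unparseable date '%s' in events row %d",
                   events$date[bad[1]], bad[1]), call. = FALSE)
    }
    events$date <- parsed
  }
  structure(list(patients = patients, events = events),
            class = "diagnosis_corpus")
}

#' Read a diagnosis TSV into a corpus
#'
#' Expects columns patient_id, date (ISO-8601), code, code_system; patient
#' metadata may be supplied separately or is derived (ids only).
#'
#' @param path diagnosis TSV path.
#' @param patients_path optional patient metadata TSV.
#' @return a `diagnosis_corpus`.
#' @export
read_diagnosis_tsv <- function(path, patients_path = NULL) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  pat <- if (!is.null(patients_path)) {
    utils::read.table(patients_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = unique(ev$patient_id), stringsAsFactors = FALSE)
  }
  new_diagnosis_corpus(pat, ev)
}

#' Read a code-to-disease-group mapping TSV
#'
#' @param path TSV with columns code, group_index (1-based), label.
#' @return data.frame of class `code_mapping`.
#' @export
read_code_mapping <- function(path) {
  mp <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  stopifnot(all(c("code", "group_index", "label") %in% names(mp)))
  if (any(mp$group_index < 1L)) stop("group_index must be 1-based", call. = FALSE)
  class(mp) <- c("code_mapping", class(mp))
  mp
}

#' Keep only unique codes per patient per calendar day
#'
#' Repeated billing of the same code on the same day carries no extra
#' clinical information; each (patient, date, code) triple is kept once,
#' first occurrence wins, other order preserved.  Idempotent.
#'
#' @param events event data.frame (patient_id, date, code, ...).
#' @return deduplicated event data.frame.
#' @export
dedup_daily_codes <- function(events) {
  if (nrow(events) == 0L) return(events)
  if (!inherits(events$date, "Date")) {
    parsed <- as.Date(as.character(events$date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad)) {
      stop(sprintf("unparseable date '%s' in events row %d",
                   as.character(events$date)[bad[1]], bad[1]), call. = FALSE)
    }
    events$date <- parsed
  }
  key <- paste(events$patient_id, events$date, events$code, sep = "\r")
  out <- events[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Normalize an ICD code for range comparison: strip the dot and right-pad
# with zeros to a fixed width, so "493", "493.2" and "493.20" order
# consistently against the range bounds.
pad0 <- function(code, width) {
  code <- gsub(".", "", toupper(trimws(code)), fixed = TRUE)
  paste0(code, strrep("0", pmax(0L, width - nchar(code))))
}

#' Is a code an asthma code?
#'
#' Asthma is 493.00-493.99 in ICD-9-CM and J45.0-J45.998 in ICD-10-CM.
#' Membership is decided by normalized code comparison (dot stripped,
#' right-zero-padded), so codes recorded at any precision ("493", "4932",
#' "J45.909") are handled.
#'
#' @param code character vector of diagnosis codes.
#' @param code_system "ICD-9-CM" or "ICD-10-CM" (vector or scalar).
#' @return logical vector.
#' @export
is_asthma_code <- function(code, code_system) {
  code_system <- rep_len(code_system, length(code))
  out <- logical(length(code))
  known <- code_system %in% c("ICD-9-CM", "ICD-10-CM")
  if (any(!known)) {
    stop(sprintf("unknown code_system '%s'", code_system[!known][1]),
         call. = FALSE)
  }
  i9 <- code_system == "ICD-9-CM"
  if (any(i9)) {
    c9 <- pad0(code[i9], 5L)
    out[i9] <- c9 >= "49300" & c9 <= "49399" & substr(c9, 1, 3) == "493"
  }
  i10 <- code_system == "ICD-10-CM"
  if (any(i10)) {
    c10 <- pad0(code[i10], 6L)
    out[i10] <- c10 >= "J45000" & c10 <= "J45998" & substr(c10, 1, 3) == "J45"
  }
  out
}

#' Per-patient asthma indicator from events
#'
#' @param events deduplicated or raw event data.frame.
#' @return named logical vector over the patient ids present in `events`.
#' @export
label_asthma <- function(events) {
  hit <- is_asthma_code(events$code, events$code_system)
  tapply(hit, events$patient_id, any)
}

#' Apply the cohort inclusion filters
#'
#' Retains patients aged within `[min_age, max_age]` at their first record,
#' carrying at least `min_asthma_codes` asthma code events (after per-day
#' deduplication) if they are cases, and, when `require_comorbid`, at least
#' one non-asthma (comorbid) diagnosis.  Controls (no asthma code) are kept
#' subject to the age and comorbidity filters unless `cases_only`.
#' Removal counts per filter are attached as attribute `"filter_log"`.
#'
#' @param corpus a `diagnosis_corpus`.
#' @param min_age,max_age inclusive age bounds (default 15-70).
#' @param min_asthma_codes minimum asthma code events for cases (default 1;
#'   the sensitivity cohort uses 2).
#' @param require_comorbid require at least one non-asthma code.
#' @param require_drug_flag require patients$drug_flag truthy, if the column
#'   exists.
#' @param cases_only drop patients without an asthma code.
#' @return filtered `diagnosis_corpus` with per-patient `asthma` and `age`
#'   columns filled in.
#' @export
apply_cohort_filters <- function(corpus, min_age = 15, max_age = 70,
                                 min_asthma_codes = 1L,
                                 require_comorbid = TRUE,
                                 require_drug_flag = FALSE,
                                 cases_only = FALSE) {
  stopifnot(inherits(corpus, "diagnosis_corpus"))
  ev <- dedup_daily_codes(corpus$events)
  pat <- corpus$patients
  n0 <- nrow(pat)
  log <- c()

  asthma_hits <- is_asthma_code(ev$code, ev$code_system)
  n_asthma <- tapply(asthma_hits, ev$patient_id, sum)
  n_comorbid <- tapply(!asthma_hits, ev$patient_id, sum)
  pat$asthma <- (n_asthma[pat$patient_id] >= min_asthma_codes) %in% TRUE
  pat$n_comorbid_codes <- ifelse(is.na(n_comorbid[pat$patient_id]), 0L,
                                 n_comorbid[pat$patient_id])

  first_date <- tapply(as.numeric(ev$date), ev$patient_id, min)
  first_year <- as.integer(format(as.Date(first_date[pat$patient_id],
                                          origin = "1970-01-01"), "%Y"))
  if (!"birth_year" %in% names(pat)) {
    stop("patient metadata must carry birth_year to compute age", call. = FALSE)
  }
  pat$age <- first_year - pat$birth_year

  keep <- !is.na(pat$age) & pat$age >= min_age & pat$age <= max_age
  log["age"] <- sum(!keep)
  if (require_comorbid) {
    k2 <- pat$n_comorbid_codes >= 1L
    log["comorbid"] <- sum(keep & !k2)
    keep <- keep & k2
  }
  if (cases_only) {
    k3 <- pat$asthma
    log["non_case"] <- sum(keep & !k3)
    keep <- keep & k3
  }
  if (require_drug_flag) {
    if (!"drug_flag" %in% names(pat)) {
      stop("require_drug_flag set but patients have no drug_flag column",
           call. = FALSE)
    }
    k4 <- as.logical(pat$drug_flag) %in% TRUE
    log["drug_flag"] <- sum(keep & !k4)
    keep <- keep & k4
  }
  pat <- pat[keep, , drop = FALSE]
  rownames(pat) <- NULL
  ev <- ev[ev$patient_id %in% pat$patient_id, , drop = FALSE]
  rownames(ev) <- NULL
  out <- new_diagnosis_corpus(pat, ev)
  attr(out, "filter_log") <- c(n_input = n0, log, n_retained = nrow(pat))
  out
}

#' Build the patient-by-disease-group count matrix
#'
#' `W[d, g]` counts the deduplicated diagnosis events of group `g` for
#' patient `d`.  Asthma codes are excluded (asthma is the stratifying label,
#' not part of the comorbidity vocabulary).  Codes absent from the mapping
#' are dropped; the dropped count is attached as attribute
#' `"unmapped_dropped"`.
#'
#' @param corpus a `diagnosis_corpus`.
#' @param mapping a `code_mapping` (code, group_index, label).
#' @return integer matrix (patients x V) with patient ids as rownames and
#'   group labels as colnames.
#' @export
build_count_matrix <- function(corpus, mapping) {
  stopifnot(inherits(corpus, "diagnosis_corpus"))
  V <- max(mapping$group_index)
  ev <- dedup_daily_codes(corpus$events)
  ev <- ev[!is_asthma_code(ev$code, ev$code_system), , drop = FALSE]
  pid <- corpus$patients$patient_id
  W <- matrix(0L, nrow = length(pid), ncol = V,
              dimnames = list(pid, {
                labs <- character(V)
                labs[mapping$group_index] <- mapping$label
                empty <- !nzchar(labs)
                labs[empty] <- sprintf("group_%03d", which(empty))
                labs
              }))
  if (nrow(ev) == 0L) {
    attr(W, "unmapped_dropped") <- 0L
    return(W)
  }
  g <- mapping$group_index[match(ev$code, mapping$code)]
  unmapped <- sum(is.na(g))
  okev <- !is.na(g) & ev$patient_id %in% pid
  if (any(okev)) {
    tab <- table(factor(ev$patient_id[okev], levels = pid),
                 factor(g[okev], levels = seq_len(V)))
    W[] <- W + as.integer(tab)
  }
  attr(W, "unmapped_dropped") <- unmapped
  W
}
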