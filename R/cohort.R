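## Retrospective cohort construction: index date, exacerbation date,
## 365-day case/control labeling, prediction-date selection and
## inclusion/exclusion filtering over long-format EHR tables.

ASTHMA_ICD9_PREFIX <- "493."

is_asthma_code <- function(code) startsWith(code, ASTHMA_ICD9_PREFIX) |
  code == "493"

#' Group long-format events into per-patient visit records
#'
#' All events of one patient sharing a calendar date form one visit (the
#' simplest reproducible grouping for dated bags of codes).  Diagnosis
#' codes are passed through the optional ICD-10 to ICD-9 mapping first and
#' deduplicated within a visit; a diagnosis keeps its strongest
#' primary-diagnosis flag and the encounter types it was seen with.
#'
#' @param patients data.frame with columns \code{patient_id},
#'   \code{age_years}, \code{gender}, \code{race}.
#' @param events data.frame with columns \code{patient_id}, \code{date}
#'   (ISO-8601), \code{code_type} (DX|MED), \code{code}, \code{primary_dx}
#'   (0|1), \code{encounter_type} (ED|INPATIENT|OUTPATIENT).
#' @param icd_map optional data.frame with columns \code{icd10_code},
#'   \code{icd9_code}; applied to DX codes before grouping.
#' @return list of patient records (class \code{tsann_patient}), each with
#'   \code{patient_id}, demographics, \code{valid_time} flag and a
#'   date-ordered list of visits.
#' @export
as_patient_records <- function(patients, events, icd_map = NULL) {
  need_p <- c("patient_id", "age_years", "gender", "race")
  need_e <- c("patient_id", "date", "code_type", "code", "primary_dx",
              "encounter_type")
  if (!all(need_p %in% names(patients))) {
    stop_config("patients table must have columns: ",
                paste(need_p, collapse = ", "))
  }
  if (!all(need_e %in% names(events))) {
    stop_config("events table must have columns: ",
                paste(need_e, collapse = ", "))
  }
  if (!is.null(icd_map)) {
    dx <- events$code_type == "DX"
    events$code[dx] <- map_icd10_to_icd9(events$code[dx], icd_map,
                                         quiet = TRUE)
  }
  dates <- as.Date(events$date, format = "%Y-%m-%d")
  ev_split <- split(seq_len(nrow(events)), events$patient_id)

  records <- vector("list", nrow(patients))
  for (k in seq_len(nrow(patients))) {
    pid <- patients$patient_id[k]
    idx <- ev_split[[pid]]
    valid_time <- length(idx) > 0 && !anyNA(dates[idx])
    visits <- list()
    if (valid_time) {
      by_date <- split(idx, as.integer(dates[idx]))
      visits <- lapply(by_date, function(ii) {
        d <- dates[ii[1]]
        dx_i <- ii[events$code_type[ii] == "DX"]
        med_i <- ii[events$code_type[ii] == "MED"]
        dx_codes <- unique(events$code[dx_i])
        dx_primary <- vapply(dx_codes, function(cd) {
          any(events$primary_dx[dx_i][events$code[dx_i] == cd] == 1L)
        }, logical(1))
        dx_enc <- lapply(dx_codes, function(cd) {
          unique(events$encounter_type[dx_i][events$code[dx_i] == cd])
        })
        list(date = d, dx = dx_codes, dx_primary = unname(dx_primary),
             dx_encounter = dx_enc, meds = unique(events$code[med_i]))
      })
      visits <- visits[order(vapply(visits, function(v) as.integer(v$date),
                                    integer(1)))]
      names(visits) <- NULL
    }
    records[[k]] <- structure(list(
      patient_id = pid,
      age_years = patients$age_years[k],
      gender = patients$gender[k],
      race = patients$race[k],
      valid_time = valid_time,
      visits = visits
    ), class = "tsann_patient")
  }
  records
}

visit_dates <- function(patient) {
  as.Date(vapply(patient$visits, function(v) as.integer(v$date),
                 integer(1)), origin = "1970-01-01")
}

#' Find the asthma index date
#'
#' The earliest visit carrying an asthma diagnosis (ICD-9 493.xx, after any
#' ICD-10 mapping) together with a same-day asthma medication (class SABA,
#' ICS, LABA, LTRA, anticholinergic or ICS/LABA).  Medications missing from
#' the class table are treated as non-asthma drugs.
#'
#' @param patient a \code{tsann_patient} record.
#' @param med_classes medication-class table, see
#'   \code{\link{read_med_classes}}.
#' @return a \code{Date}, or \code{NULL} when no qualifying visit exists.
#' @export
find_index_date <- function(patient, med_classes) {
  for (v in patient$visits) {
    if (!any(is_asthma_code(v$dx))) next
    cls <- med_class_of(v$meds, med_classes)
    if (any(cls %in% asthma_med_classes())) return(v$date)
  }
  NULL
}

#' Find the asthma exacerbation date
#'
#' The earliest visit strictly after the index date where an asthma code is
#' flagged as the primary diagnosis of an ED or inpatient encounter and an
#' oral corticosteroid is given the same day.
#'
#' @inheritParams find_index_date
#' @param index_date the patient's index date.
#' @return a \code{Date}, or \code{NULL}.
#' @export
find_exacerbation_date <- function(patient, index_date, med_classes) {
  for (v in patient$visits) {
    if (v$date <= index_date) next
    hit <- FALSE
    for (j in seq_along(v$dx)) {
      if (is_asthma_code(v$dx[j]) && v$dx_primary[j] &&
          any(v$dx_encounter[[j]] %in% c("ED", "INPATIENT"))) {
        hit <- TRUE
        break
      }
    }
    if (!hit) next
    if (any(med_class_of(v$meds, med_classes) %in% "OCS")) return(v$date)
  }
  NULL
}

#' Case/control labeling over a 365-day horizon
#'
#' A patient is a case iff an exacerbation date exists and lies within 365
#' days (inclusive) of the index date.
#'
#' @param index_date,exacerbation_date dates;
#'   \code{exacerbation_date} may be \code{NULL}.
#' @return \code{"case"} or \code{"control"}.
#' @export
assign_label <- function(index_date, exacerbation_date) {
  if (!is.null(exacerbation_date) &&
      as.numeric(exacerbation_date - index_date) <= 365) "case" else "control"
}

#' Prediction-date selection
#'
#' Training set and testing set B: for cases the visit immediately before
#' the exacerbation date, for controls the penultimate visit within 365
#' days of the index date.  Testing set A: the fifth visit counting the
#' index-date visit as the first (cases whose exacerbation precedes the
#' fifth visit are excluded).
#'
#' @param dates ordered vector of the patient's visit dates.
#' @param index_date,exacerbation_date anchor dates
#'   (\code{exacerbation_date} \code{NULL} for controls).
#' @param label "case" or "control".
#' @param mode one of "training", "testA", "testB".
#' @return a \code{Date}, or \code{NULL} with attribute \code{reason} when
#'   the mode is undefined for this patient.
#' @export
prediction_date <- function(dates, index_date, exacerbation_date, label,
                            mode = c("training", "testA", "testB")) {
  mode <- match.arg(mode)
  fail <- function(reason) structure(as.Date(NA), reason = reason)
  in_horizon <- dates >= index_date &
    as.numeric(dates - index_date) <= 365
  if (mode == "testA") {
    cand <- dates[in_horizon]
    if (length(cand) < 5L) return(fail("visits<5"))
    fifth <- cand[5L]
    if (label == "case" && !is.null(exacerbation_date) &&
        exacerbation_date <= fifth) {
      return(fail("exacerbation_before_fifth_visit"))
    }
    return(fifth)
  }
  if (label == "case") {
    before <- dates[dates < exacerbation_date & dates >= index_date]
    if (!length(before)) return(fail("no_visit_before_exacerbation"))
    return(before[length(before)])
  }
  cand <- dates[in_horizon]
  if (length(cand) < 2L) return(fail("visits<5"))
  cand[length(cand) - 1L]
}

#' Inclusion/exclusion filtering
#'
#' Applies, in order: valid time information; gender male or female; age
#' between 18 and 80 (inclusive); an asthma index date exists; a
#' prediction date is defined for the mode; at least \code{min_visits}
#' visits inside the observed window [index date, prediction date].  Every
#' dropped patient is audited with its first failing rule.
#'
#' @param records list of \code{tsann_patient} from
#'   \code{\link{as_patient_records}}.
#' @param med_classes medication-class table.
#' @param mode prediction-date mode, see \code{\link{prediction_date}}.
#' @param min_visits minimum visits in the observed window (default 5).
#' @return list with \code{cohort} (list of \code{tsann_cohort_sample})
#'   and \code{audit} (data.frame patient_id, retained, reason).
#' @export
apply_inclusion_exclusion <- function(records, med_classes,
                                      mode = "training", min_visits = 5L) {
  cohort <- list()
  pid <- character(length(records))
  retained <- logical(length(records))
  reason <- character(length(records))

  for (k in seq_along(records)) {
    p <- records[[k]]
    pid[k] <- p$patient_id
    drop <- function(r) { retained[k] <<- FALSE; reason[k] <<- r }
    if (!isTRUE(p$valid_time)) { drop("time"); next }
    if (!p$gender %in% c("M", "F")) { drop("gender"); next }
    if (is.na(p$age_years) || p$age_years < 18 || p$age_years > 80) {
      drop("age"); next
    }
    index_date <- find_index_date(p, med_classes)
    if (is.null(index_date)) { drop("no_asthma_index"); next }
    exac <- find_exacerbation_date(p, index_date, med_classes)
    label <- assign_label(index_date, exac)
    dates <- visit_dates(p)
    pd <- prediction_date(dates, index_date, exac, label, mode)
    if (is.na(pd)) { drop(attr(pd, "reason") %||% "prediction_date"); next }
    in_win <- dates >= index_date & dates <= pd
    if (sum(in_win) < min_visits) { drop("visits<5"); next }
    retained[k] <- TRUE
    reason[k] <- ""
    cohort[[length(cohort) + 1L]] <- structure(list(
      patient_id = p$patient_id,
      age_years = p$age_years,
      gender = p$gender,
      race = p$race,
      label = if (label == "case") 1L else 0L,
      index_date = index_date,
      exacerbation_date = exac,
      prediction_date = pd,
      mode = mode,
      window_visits = p$visits[in_win]
    ), class = "tsann_cohort_sample")
  }
  list(cohort = cohort,
       audit = data.frame(patient_id = pid, retained = retained,
                          reason = reason, stringsAsFactors = FALSE))
}

#' Build a labeled cohort from raw tables
#'
#' Convenience wrapper: groups events into patient records, applies the
#' cohort rules and returns the labeled samples plus the exclusion audit.
#'
#' @inheritParams as_patient_records
#' @inheritParams apply_inclusion_exclusion
#' @return list with \code{cohort}, \code{audit} and \code{table} (one row
#'   per retained patient: patient_id, label, index_date, prediction_date,
#'   mode).
#' @export
#' @examples
#' sim <- generate_cohort(sim_config(30, seed = 1))
#' ch <- build_cohort(sim$patients, sim$events, read_med_classes())
#' head(ch$table)
build_cohort <- function(patients, events, med_classes, icd_map = NULL,
                         mode = "training", min_visits = 5L) {
  records <- as_patient_records(patients, events, icd_map)
  res <- apply_inclusion_exclusion(records, med_classes, mode, min_visits)
  res$table <- data.frame(
    patient_id = vapply(res$cohort, `[[`, character(1), "patient_id"),
    label = vapply(res$cohort, `[[`, integer(1), "label"),
    index_date = vapply(res$cohort, function(s) format(s$index_date),
                        character(1)),
    prediction_date = vapply(res$cohort, function(s) format(s$prediction_date),
                             character(1)),
    mode = mode,
    stringsAsFactors = FALSE
  )
  res
}
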