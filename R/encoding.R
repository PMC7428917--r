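## Vocabulary construction and conversion of cohort samples into the
## integer-indexed, day-gap-stamped sequences the models consume.

PAD_INDEX <- 0L
UNK_INDEX <- 1L
TIME_VOCAB <- 365L  # day-gap bins 0..364

#' Map ICD-10 diagnosis codes to ICD-9
#'
#' Codes present in the mapping table are replaced; everything else passes
#' through unchanged.  Unmapped codes that look like ICD-10 (leading letter
#' other than V/E) trigger a warning so real extracts surface gaps in the
#' mapping; ICD-9-style input is silently left alone.
#'
#' @param codes character vector of diagnosis codes.
#' @param icd_map data.frame with columns \code{icd10_code},
#'   \code{icd9_code}.
#' @param quiet suppress the unmapped-code warning.
#' @return character vector of the same length.
#' @export
map_icd10_to_icd9 <- function(codes, icd_map, quiet = FALSE) {
  if (is.null(icd_map)) return(codes)
  if (!all(c("icd10_code", "icd9_code") %in% names(icd_map))) {
    stop_config("icd_map must have columns icd10_code, icd9_code")
  }
  hit <- match(codes, icd_map$icd10_code)
  out <- ifelse(is.na(hit), codes, icd_map$icd9_code[hit])
  if (!quiet) {
    unmapped <- is.na(hit) & grepl("^[A-DF-UW-Z]", codes)
    if (any(unmapped)) {
      warning("unmapped ICD-10-style codes kept as-is: ",
              paste(unique(codes[unmapped]), collapse = ", "))
    }
  }
  out
}

## Demographic tokens attached at the prediction-date visit: age bucketed
## by decade, gender and race as categorical tokens.
demographic_tokens <- function(sample) {
  c(sprintf("AGE_%d", (sample$age_years %/% 10L) * 10L),
    sprintf("GENDER_%s", sample$gender),
    sprintf("RACE_%s", sample$race))
}

## Namespaced code strings for one visit (presence semantics, deduplicated).
visit_code_strings <- function(visit) {
  unique(c(if (length(visit$dx)) paste0("DX:", visit$dx),
           if (length(visit$meds)) paste0("MED:", visit$meds)))
}

#' Build the code vocabulary from a training cohort
#'
#' Index 0 is reserved for padding and 1 for unknown codes; known codes are
#' sorted lexicographically before indexing so the mapping is deterministic.
#' Demographic tokens are part of the vocabulary.  The vocabulary must be
#' built from the training split only; codes seen only at test time map to
#' the unknown index.
#'
#' @param cohort list of \code{tsann_cohort_sample}.
#' @return object of class \code{tsann_vocab}: \code{index} (named integer
#'   vector) and \code{size} (number of known codes + 2).
#' @export
build_vocabulary <- function(cohort) {
  if (!length(cohort)) stop_config("cannot build a vocabulary from an empty cohort")
  codes <- unlist(lapply(cohort, function(s) {
    c(unlist(lapply(s$window_visits, visit_code_strings)),
      demographic_tokens(s))
  }))
  known <- sort(unique(codes))
  structure(list(
    index = stats::setNames(seq_along(known) + 1L, known),
    size = length(known) + 2L
  ), class = "tsann_vocab")
}

code_to_index <- function(codes, vocab) {
  idx <- unname(vocab$index[codes])
  idx[is.na(idx)] <- UNK_INDEX
  as.integer(idx)
}

#' Elapsed day gap between a visit and the prediction date
#'
#' Whole days, clamped into the 365-bin time vocabulary [0, 364].  The
#' minimum time unit is one day and the observed window is bounded by 365
#' days, so the clamp only matters at the boundary.
#'
#' @param visit_date,prediction_date dates with
#'   \code{visit_date <= prediction_date}.
#' @return integer gap in [0, 364].
#' @export
elapsed_gap <- function(visit_date, prediction_date) {
  gap <- as.numeric(as.Date(prediction_date) - as.Date(visit_date))
  if (any(gap < 0)) stop_config("visit after prediction date (window violation)")
  as.integer(pmin(gap, TIME_VOCAB - 1L))
}

#' Encode one cohort sample as an integer visit sequence
#'
#' Visits are ordered oldest first (decreasing gap) and capped at
#' \code{max_visits} keeping the most recent; codes within a visit are
#' deduplicated (presence semantics); demographic tokens are appended to
#' the prediction-date visit only.
#'
#' @param sample a \code{tsann_cohort_sample}.
#' @param vocab a \code{tsann_vocab}.
#' @param max_visits cap on sequence length (default 50).
#' @return object of class \code{tsann_encoded}: \code{patient_id},
#'   \code{label}, and \code{visits}, a list of
#'   \code{list(codes, code_names, gap)}.
#' @export
encode_patient <- function(sample, vocab, max_visits = 50L) {
  vis <- sample$window_visits
  if (!length(vis)) stop_config("empty observed window for patient ",
                                sample$patient_id)
  if (length(vis) > max_visits) {
    vis <- vis[seq.int(length(vis) - max_visits + 1L, length(vis))]
  }
  n <- length(vis)
  visits <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- visit_code_strings(vis[[i]])
    if (i == n) nm <- unique(c(nm, demographic_tokens(sample)))
    visits[[i]] <- list(
      codes = code_to_index(nm, vocab),
      code_names = nm,
      gap = elapsed_gap(vis[[i]]$date, sample$prediction_date)
    )
  }
  structure(list(patient_id = sample$patient_id,
                 label = sample$label,
                 visits = visits),
            class = "tsann_encoded")
}

#' @rdname encode_patient
#' @param cohort list of samples to encode.
#' @export
encode_cohort <- function(cohort, vocab, max_visits = 50L) {
  lapply(cohort, encode_patient, vocab = vocab, max_visits = max_visits)
}

#' Write / read an encoded dataset
#'
#' One record per line: \code{patient_id}, \code{label}, then per-visit
#' groups \code{"gap:idx,idx,..."} separated by \code{";"} — a plain-text
#' format sufficient to re-run training reproducibly.
#'
#' @param encoded list of \code{tsann_encoded}.
#' @param path file path.
#' @export
write_encoded <- function(encoded, path) {
  lines <- vapply(encoded, function(e) {
    groups <- vapply(e$visits, function(v) {
      sprintf("%d:%s", v$gap, paste(v$codes, collapse = ","))
    }, character(1))
    sprintf("%s\t%d\t%s", e$patient_id, e$label,
            paste(groups, collapse = ";"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    visits <- lapply(strsplit(parts[3], ";", fixed = TRUE)[[1]], function(g) {
      gv <- strsplit(g, ":", fixed = TRUE)[[1]]
      list(codes = as.integer(strsplit(gv[2], ",", fixed = TRUE)[[1]]),
           code_names = NULL,
           gap = as.integer(gv[1]))
    })
    structure(list(patient_id = parts[1], label = as.integer(parts[2]),
                   visits = visits), class = "tsann_encoded")
  })
}
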