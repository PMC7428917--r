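#' Medication-class mapping
#'
#' Cohort rules are defined over medication *classes*: the index date
#' requires a same-day asthma controller/reliever (SABA, ICS, LABA, LTRA,
#' anticholinergic or ICS/LABA combination) and the exacerbation date
#' requires a same-day oral corticosteroid (OCS).  The mapping from generic
#' drug name to class is supplied as a two-column table so real extracts can
#' plug in their own formulary.
#'
#' @param path path to a delimited file with columns \code{generic_name} and
#'   \code{class}; when \code{NULL} the small example table shipped with the
#'   package is used.
#' @return data.frame with columns \code{generic_name}, \code{class}.
#' @export
#' @examples
#' head(read_med_classes())
read_med_classes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "med_classes.tsv", package = "tsann")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("generic_name", "class")
  if (!all(need %in% names(tab))) {
    stop_config("medication-class table must have columns: ",
                paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(tab$class), med_class_levels())
  if (length(bad)) {
    stop_config("unknown medication classes: ", paste(bad, collapse = ", "))
  }
  tab
}

med_class_levels <- function() {
  c("SABA", "ICS", "LABA", "LTRA", "ANTICHOLINERGIC", "ICS_LABA", "OCS")
}

## Classes that qualify a same-day prescription as an "asthma medication"
## for index-date detection (everything except oral corticosteroids).
asthma_med_classes <- function() {
  setdiff(med_class_levels(), "OCS")
}

## Look up the class of each medication name; unknown drugs map to NA and
## are treated as non-asthma medications.
med_class_of <- function(meds, med_classes) {
  med_classes$class[match(meds, med_classes$generic_name)]
}
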