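#' Configuration for the synthetic EHR generator
#'
#' The generator emulates the structure of a large retrospective asthma
#' cohort: irregular visit spacing, around 5.78 visits per patient inside
#' the observed window, a case:control imbalance near 1:13, a mixed
#' diagnosis/medication code vocabulary, and (optionally) planted risk
#' factors whose effect on the exacerbation log-odds is restricted to a
#' window of day-gaps before the prediction date.
#'
#' Labels are drawn from a logistic model:
#' \deqn{\mathrm{logit}\,P(\mathrm{case}) = b_0 + \sum_f e_f \,
#'   \mathbf{1}[\mathrm{occurrence\ of\ } f \mathrm{\ falls\ in\ its\
#'   active\ window}]}
#' where \eqn{b_0} is \code{baseline_logit} and \eqn{e_f} the factor's
#' \code{effect_logit}.
#'
#' @param n_patients number of patients (>= 2).
#' @param vocab_dx,vocab_med number of synthetic background diagnosis /
#'   medication codes (>= 1).
#' @param mean_visits mean number of visits per patient in the observed
#'   window; drawn as 5 + Poisson(mean_visits - 5), floor 5, so the >= 5
#'   visit inclusion rule passes by construction.
#' @param target_case_fraction marginal case fraction aimed for when no
#'   planted factors are active; sets the default \code{baseline_logit}.
#' @param planted_factors list of \code{\link{planted_factor}} objects.
#' @param baseline_logit intercept of the label model; defaults to
#'   \code{logit(target_case_fraction)}.
#' @param visit_gap_mean_days mean of the exponential inter-visit gaps.
#' @param seed integer seed; identical configs with identical seeds give
#'   byte-identical outputs.
#' @return object of class \code{tsann_sim_config}.
#' @export
sim_config <- function(n_patients,
                       vocab_dx = 40L,
                       vocab_med = 15L,
                       mean_visits = 5.78,
                       target_case_fraction = 1 / 14,
                       planted_factors = list(),
                       baseline_logit = NULL,
                       visit_gap_mean_days = 45,
                       seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L) {
    stop_config("n_patients must be an integer >= 2")
  }
  if (vocab_dx < 1L || vocab_med < 1L) {
    stop_config("vocabulary counts must be >= 1")
  }
  if (mean_visits <= 0 || visit_gap_mean_days <= 0) {
    stop_config("mean_visits and visit_gap_mean_days must be positive")
  }
  if (target_case_fraction <= 0 || target_case_fraction >= 1) {
    stop_config("target_case_fraction must lie in (0,1)")
  }
  for (f in planted_factors) {
    if (!inherits(f, "tsann_planted_factor")) {
      stop_config("planted_factors must be a list of planted_factor objects")
    }
  }
  structure(list(
    n_patients = n_patients,
    vocab_dx = as.integer(vocab_dx),
    vocab_med = as.integer(vocab_med),
    mean_visits = mean_visits,
    target_case_fraction = target_case_fraction,
    planted_factors = planted_factors,
    baseline_logit = baseline_logit %||% logit(target_case_fraction),
    visit_gap_mean_days = visit_gap_mean_days,
    seed = as.integer(seed)
  ), class = "tsann_sim_config")
}

#' A planted, possibly time-localized risk factor
#'
#' An occurrence of \code{code} is given to a fraction \code{prevalence} of
#' patients, at a day-gap before the prediction date drawn uniformly from
#' \code{placement_window}.  The occurrence adds \code{effect_logit} to the
#' patient's exacerbation log-odds only when its realized gap falls inside
#' \code{active_window}; occurrences outside the active window are emitted
#' in the event table but carry no effect, which is what makes temporal
#' localization learnable (and testable).
#'
#' @param code code identifier (kept distinct from background codes).
#' @param effect_logit finite real added to the log-odds when active.
#' @param active_window closed day-gap interval \code{c(a, b)},
#'   0 <= a <= b <= 365.
#' @param prevalence probability a patient carries an occurrence.
#' @param placement_window day-gap interval occurrences are drawn from.
#' @param code_type "DX" or "MED".
#' @return object of class \code{tsann_planted_factor}.
#' @export
planted_factor <- function(code,
                           effect_logit,
                           active_window = c(0, 365),
                           prevalence = 0.5,
                           placement_window = c(0, 364),
                           code_type = "DX") {
  if (!is.finite(effect_logit)) stop_config("effect_logit must be finite")
  aw <- as.numeric(active_window)
  if (length(aw) != 2 || aw[1] < 0 || aw[1] > aw[2] || aw[2] > 365) {
    stop_config("active_window must satisfy 0 <= a <= b <= 365")
  }
  if (prevalence < 0 || prevalence > 1) {
    stop_config("prevalence must lie in [0,1]")
  }
  structure(list(
    code = as.character(code),
    effect_logit = effect_logit,
    active_window = aw,
    prevalence = prevalence,
    placement_window = as.numeric(placement_window),
    code_type = match.arg(code_type, c("DX", "MED"))
  ), class = "tsann_planted_factor")
}

## Visit days for one patient: day 0 (index) plus accumulated exponential
## gaps, compressed into [0, 360] so an exacerbation/terminal visit always
## fits inside the 365-day window.
sim_visit_days <- function(n, gap_mean) {
  if (n == 1L) return(0L)
  gaps <- pmax(1, round(stats::rexp(n - 1L, rate = 1 / gap_mean)))
  days <- c(0, cumsum(gaps))
  if (days[n] > 350) days <- round(days / days[n] * 350)
  for (i in 2:n) if (days[i] <= days[i - 1]) days[i] <- days[i - 1] + 1
  if (days[n] > 360) {
    days <- round(seq(0, 360, length.out = n))
    days <- days + cumsum(c(0L, as.integer(diff(days) == 0)))
  }
  as.integer(days)
}

#' Generate a synthetic EHR cohort with known ground truth
#'
#' Emits long-format patient and event tables in the package's external
#' schema together with the generating truth (labels, planted-factor
#' occurrences and their day-gaps, realized case fraction).  The last
#' regularly generated visit is the prediction visit by construction: cases
#' get an exacerbation visit (primary asthma diagnosis at an ED/inpatient
#' encounter plus same-day oral corticosteroid) a few days later, controls
#' get an ordinary terminal visit, so the cohort rules of
#' \code{\link{build_cohort}} recover exactly the planted prediction date
#' in training/testB mode.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{tsann_sim} with elements \code{patients}
#'   (data.frame), \code{events} (data.frame), and \code{truth} (list with
#'   \code{labels}, \code{occurrences}, \code{case_fraction}).
#' @export
#' @examples
#' sim <- generate_cohort(sim_config(50, seed = 7))
#' head(sim$events)
#' sim$truth$case_fraction
generate_cohort <- function(config) {
  stopifnot(inherits(config, "tsann_sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  dx_vocab <- sprintf("SYN.DX.%03d", seq_len(config$vocab_dx))
  med_vocab <- c("albuterol", "fluticasone", "salmeterol", "montelukast",
                 "ipratropium", "fluticasone-salmeterol")
  med_vocab <- c(med_vocab,
                 sprintf("synmed%03d", seq_len(config$vocab_med)))
  asthma_meds <- c("albuterol", "fluticasone", "salmeterol", "montelukast")
  races <- c("WHITE", "BLACK", "ASIAN", "OTHER")

  pid <- sprintf("P%05d", seq_len(n))
  age <- sample(18:80, n, replace = TRUE)
  gender <- sample(c("M", "F"), n, replace = TRUE)
  race <- sample(races, n, replace = TRUE)
  start <- as.Date("2008-01-01") + sample(0:1460, n, replace = TRUE)

  ev <- list()       # per-patient event blocks
  occ <- list()
  labels <- integer(n)
  logits <- numeric(n)
  pred_day <- integer(n)

  extra <- if (config$mean_visits > 5) config$mean_visits - 5 else 0
  for (p in seq_len(n)) {
    n_vis <- 5L + stats::rpois(1L, extra)
    days <- sim_visit_days(n_vis, config$visit_gap_mean_days)
    d_pred <- days[n_vis]
    gaps <- d_pred - days

    v_date <- character(0); v_type <- character(0); v_code <- character(0)
    v_prim <- integer(0);   v_enc  <- character(0)
    add_event <- function(day, type, code, prim, enc) {
      v_date <<- c(v_date, format(start[p] + day))
      v_type <<- c(v_type, type); v_code <<- c(v_code, code)
      v_prim <<- c(v_prim, prim); v_enc <<- c(v_enc, enc)
    }

    for (i in seq_len(n_vis)) {
      k <- 1L + stats::rpois(1L, 3L)
      codes <- sample(c(dx_vocab, med_vocab), k, replace = FALSE)
      for (cd in codes) {
        add_event(days[i], if (cd %in% dx_vocab) "DX" else "MED",
                  cd, 0L, "OUTPATIENT")
      }
    }
    ## index visit: asthma diagnosis + same-day asthma medication
    add_event(0L, "DX", "493.90", 0L, "OUTPATIENT")
    add_event(0L, "MED", sample(asthma_meds, 1L), 0L, "OUTPATIENT")

    ## planted factors
    lg <- config$baseline_logit
    for (f in config$planted_factors) {
      if (stats::runif(1) >= f$prevalence) next
      lo <- max(0, min(f$placement_window[1], d_pred))
      hi <- min(f$placement_window[2], d_pred)
      tg <- seq.int(lo, hi)
      target <- tg[sample.int(length(tg), 1L)]
      vi <- which.min(abs(gaps - target))
      g_real <- gaps[vi]
      active <- g_real >= f$active_window[1] && g_real <= f$active_window[2]
      add_event(days[vi], f$code_type, f$code, 0L, "OUTPATIENT")
      occ[[length(occ) + 1L]] <- list(
        patient_id = pid[p], code = f$code,
        date = format(start[p] + days[vi]),
        gap_days = as.integer(g_real), active = as.integer(active),
        effect_logit = f$effect_logit)
      if (active) lg <- lg + f$effect_logit
    }

    y <- stats::rbinom(1L, 1L, sigmoid(lg))
    d_next <- d_pred + sample.int(min(14L, 365L - d_pred), 1L)
    if (y == 1L) {
      add_event(d_next, "DX", "493.92", 1L,
                sample(c("ED", "INPATIENT"), 1L))
      add_event(d_next, "MED", "prednisone", 0L, "ED")
    } else {
      add_event(d_next, "DX", sample(dx_vocab, 1L), 0L, "OUTPATIENT")
    }

    labels[p] <- y
    logits[p] <- lg
    pred_day[p] <- d_pred
    ev[[p]] <- list(date = v_date, code_type = v_type, code = v_code,
                    primary_dx = v_prim, encounter_type = v_enc,
                    n = length(v_code))
  }

  events <- data.frame(
    patient_id = rep(pid, vapply(ev, `[[`, 1L, "n")),
    date = unlist(lapply(ev, `[[`, "date")),
    code_type = unlist(lapply(ev, `[[`, "code_type")),
    code = unlist(lapply(ev, `[[`, "code")),
    primary_dx = unlist(lapply(ev, `[[`, "primary_dx")),
    encounter_type = unlist(lapply(ev, `[[`, "encounter_type")),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$patient_id, events$date,
                         events$code_type, events$code), ]
  rownames(events) <- NULL

  patients <- data.frame(patient_id = pid, age_years = as.integer(age),
                         gender = gender, race = race,
                         stringsAsFactors = FALSE)
  occurrences <- if (length(occ)) {
    do.call(rbind, lapply(occ, as.data.frame, stringsAsFactors = FALSE))
  } else {
    data.frame(patient_id = character(0), code = character(0),
               date = character(0), gap_days = integer(0),
               active = integer(0), effect_logit = numeric(0))
  }
  truth <- list(
    labels = data.frame(patient_id = pid, label = labels, logit = logits,
                        index_date = format(start),
                        prediction_date = format(start + pred_day),
                        stringsAsFactors = FALSE),
    occurrences = occurrences,
    case_fraction = mean(labels)
  )
  structure(list(patients = patients, events = events, truth = truth),
            class = "tsann_sim")
}

#' Write / read the synthetic cohort tables
#'
#' Writes \code{patients.tsv}, \code{events.tsv},
#' \code{ground_truth_labels.tsv} and \code{ground_truth_occurrences.tsv}
#' (tab-delimited, header row) under \code{dir}.  \code{read_ehr_tables}
#' performs the exact inverse; a write/read round trip reproduces the
#' in-memory tables identically.
#'
#' @param sim a \code{tsann_sim} from \code{\link{generate_cohort}}.
#' @param dir output directory (created if absent).
#' @return \code{write_ehr_tables}: the directory, invisibly.
#' @export
write_ehr_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "tsann_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory: ", dir)
  }
  wr <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(sim$patients, "patients.tsv")
  wr(sim$events, "events.tsv")
  wr(sim$truth$labels, "ground_truth_labels.tsv")
  wr(sim$truth$occurrences, "ground_truth_occurrences.tsv")
  invisible(dir)
}

#' @rdname write_ehr_tables
#' @export
read_ehr_tables <- function(dir) {
  rd <- function(f, classes) utils::read.delim(
    file.path(dir, f), colClasses = classes, stringsAsFactors = FALSE)
  patients <- rd("patients.tsv",
                 c("character", "integer", "character", "character"))
  events <- rd("events.tsv", c("character", "character", "character",
                               "character", "integer", "character"))
  truth <- NULL
  if (file.exists(file.path(dir, "ground_truth_labels.tsv"))) {
    labels <- rd("ground_truth_labels.tsv",
                 c("character", "integer", "numeric", "character",
                   "character"))
    occurrences <- rd("ground_truth_occurrences.tsv",
                      c("character", "character", "character", "integer",
                        "integer", "numeric"))
    truth <- list(labels = labels, occurrences = occurrences,
                  case_fraction = mean(labels$label))
  }
  structure(list(patients = patients, events = events, truth = truth),
            class = "tsann_sim")
}
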