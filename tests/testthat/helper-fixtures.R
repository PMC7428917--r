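# Hand-built toy patients and small synthetic cohorts used across tests.

toy_med_classes <- function() {
  data.frame(
    generic_name = c("albuterol", "fluticasone", "prednisone",
                     "montelukast"),
    class = c("SABA", "ICS", "OCS", "LTRA"),
    stringsAsFactors = FALSE
  )
}

# One patient as (patients, events) tables.  `visits` is a list of
# list(day, dx = c(code), primary = 0/1 per dx, enc = encounter type,
# meds = c(names)); days are offsets from `origin`.
toy_tables <- function(visits, id = "T1", age = 40L, gender = "M",
                       race = "WHITE", origin = as.Date("2010-01-01")) {
  rows <- list()
  for (v in visits) {
    date <- format(origin + v$day)
    prim <- v$primary %||% rep(0L, length(v$dx %||% character(0)))
    enc <- v$enc %||% "OUTPATIENT"
    for (j in seq_along(v$dx %||% character(0))) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = id, date = date, code_type = "DX", code = v$dx[j],
        primary_dx = prim[j], encounter_type = enc,
        stringsAsFactors = FALSE)
    }
    for (md in v$meds %||% character(0)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = id, date = date, code_type = "MED", code = md,
        primary_dx = 0L, encounter_type = enc, stringsAsFactors = FALSE)
    }
  }
  list(
    patients = data.frame(patient_id = id, age_years = age,
                          gender = gender, race = race,
                          stringsAsFactors = FALSE),
    events = do.call(rbind, rows)
  )
}

toy_record <- function(visits, ...) {
  tb <- toy_tables(visits, ...)
  as_patient_records(tb$patients, tb$events)[[1]]
}

# A regular asthma patient: index at day 0, visits every 10 days,
# optionally an exacerbation-qualifying visit.
toy_asthma_visits <- function(n_visits = 6L, exac_day = NULL, step = 10L) {
  vs <- list(list(day = 0L, dx = "493.90", meds = "albuterol"))
  for (k in seq_len(n_visits - 1L)) {
    vs[[length(vs) + 1L]] <- list(day = k * step, dx = sprintf("SYM.%d", k))
  }
  if (!is.null(exac_day)) {
    vs[[length(vs) + 1L]] <- list(day = exac_day, dx = "493.92",
                                  primary = 1L, enc = "ED",
                                  meds = "prednisone")
  }
  vs
}

# Small encoded cohort via the full pipeline, for model/training tests.
small_encoded_cohort <- function(n = 40L, seed = 7L, factors = list()) {
  sim <- generate_cohort(sim_config(n, planted_factors = factors,
                                    seed = seed))
  ch <- build_cohort(sim$patients, sim$events, read_med_classes())
  vocab <- build_vocabulary(ch$cohort)
  list(sim = sim, cohort = ch$cohort, vocab = vocab,
       encs = encode_cohort(ch$cohort, vocab))
}
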