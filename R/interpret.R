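## Attention-based interpretation: per-patient contribution heatmaps,
## cohort-level ranked factors with month buckets, temporal scatters.

## Kept (non-padding) visit structure, exactly mirroring the masking the
## encoder applies, so attention weights align with code names.
mask_encoded <- function(enc) {
  keep <- list()
  for (v in enc$visits) {
    sel <- v$codes != PAD_INDEX
    if (!any(sel)) next
    nm <- if (!is.null(v$code_names)) v$code_names[sel] else
      as.character(v$codes[sel])
    keep[[length(keep) + 1L]] <- list(codes = v$codes[sel],
                                      code_names = nm, gap = v$gap)
  }
  keep
}

#' Per-patient contribution matrix
#'
#' The contribution of code j in visit i is the product of the visit-level
#' and code-level attention weights, renormalized to total mass 1 for the
#' patient: \eqn{c_{ij} = \beta_i \alpha_{ij} / \sum \beta \alpha}.
#' Variants without visit attention (TSANN_I and friends) use uniform
#' visit weights, flagged in the result.
#'
#' @param risk a \code{tsann_risk} from \code{\link{predict_risk}}.
#' @param enc the encoded sequence the risk output was computed from.
#' @return object of class \code{tsann_contrib}: \code{matrix} (codes x
#'   visits, entries >= 0 summing to 1), \code{gaps} (day gap per visit
#'   column), \code{p} (risk probability), \code{patient_id},
#'   \code{uniform_beta} flag.
#' @export
patient_contributions <- function(risk, enc) {
  keep <- mask_encoded(enc)
  if (length(keep) != length(risk$alpha)) {
    stop_config("attention weights do not match the encoded sequence")
  }
  beta <- risk$beta %||% rep(1 / length(keep), length(keep))
  codes <- unique(unlist(lapply(keep, `[[`, "code_names")))
  M <- matrix(0, length(codes), length(keep),
              dimnames = list(codes,
                              paste0("visit", seq_along(keep))))
  for (i in seq_along(keep)) {
    a <- risk$alpha[[i]]
    if (length(a) != length(keep[[i]]$code_names)) {
      stop_config("alpha length mismatch at visit ", i)
    }
    M[keep[[i]]$code_names, i] <- M[keep[[i]]$code_names, i] + beta[i] * a
  }
  M <- M / sum(M)
  structure(list(matrix = M,
                 gaps = vapply(keep, `[[`, integer(1), "gap"),
                 p = risk$p,
                 patient_id = risk$patient_id,
                 uniform_beta = is.null(risk$beta)),
            class = "tsann_contrib")
}

#' Write a contribution heatmap
#'
#' Emits a tab-delimited codes-by-visits matrix whose header line carries
#' the risk probability, and optionally a PNG raster of the same matrix
#' (darker = more important).
#'
#' @param contrib a \code{tsann_contrib}.
#' @param path output path for the text matrix.
#' @param image optional path for a PNG rendering.
#' @return \code{path}, invisibly.
#' @export
render_heatmap <- function(contrib, path, image = NULL) {
  M <- contrib$matrix
  if (!length(M)) stop_config("empty contribution matrix")
  con <- file(path, "w")
  writeLines(sprintf("# patient=%s risk_probability=%.6f uniform_beta=%s",
                     contrib$patient_id, contrib$p,
                     contrib$uniform_beta), con)
  writeLines(paste(c("code", sprintf("gap%d", contrib$gaps)),
                   collapse = "\t"), con)
  for (r in seq_len(nrow(M))) {
    writeLines(paste(c(rownames(M)[r], sprintf("%.8f", M[r, ])),
                     collapse = "\t"), con)
  }
  close(con)
  if (!is.null(image)) {
    grDevices::png(image, width = 640, height = 480)
    graphics::image(
      t(M)[, rev(seq_len(nrow(M))), drop = FALSE],
      col = grDevices::gray(seq(1, 0, length.out = 64)), axes = FALSE,
      main = sprintf("patient %s  P(exacerbation)=%.3f",
                     contrib$patient_id, contrib$p))
    grDevices::dev.off()
  }
  invisible(path)
}

#' Cohort-level ranked risk factors
#'
#' Each patient's contribution mass (total 1) is assigned to (code, month
#' bucket) pairs, where bucket N = floor(gap/30) covers occurrences N
#' months before the prediction date; scores are summed over patients and
#' ranked.  Equal per-patient weighting prevents long records from
#' dominating the ranking.
#'
#' @param contribs list of \code{tsann_contrib}.
#' @return data.frame (code, month_bucket, score, support) sorted by
#'   decreasing score; \code{support} counts patients with positive mass
#'   on the factor.
#' @export
cohort_level_factors <- function(contribs) {
  if (!length(contribs)) stop_config("need at least one patient")
  acc <- new.env(parent = emptyenv())
  acc$score <- numeric(0)
  acc$support <- integer(0)
  for (cm in contribs) {
    M <- cm$matrix
    bucket <- cm$gaps %/% 30L
    seen <- character(0)
    for (i in seq_len(ncol(M))) {
      pos <- which(M[, i] > 0)
      if (!length(pos)) next
      keys <- paste0(rownames(M)[pos], "\r", bucket[i])
      for (k in seq_along(keys)) {
        key <- keys[k]
        acc$score[key] <- (if (is.na(acc$score[key])) 0 else
          acc$score[key]) + M[pos[k], i]
      }
      seen <- c(seen, keys)
    }
    for (key in unique(seen)) {
      acc$support[key] <- (if (is.na(acc$support[key])) 0L else
        acc$support[key]) + 1L
    }
  }
  parts <- strsplit(names(acc$score), "\r", fixed = TRUE)
  out <- data.frame(
    code = vapply(parts, `[`, character(1), 1L),
    month_bucket = as.integer(vapply(parts, `[`, character(1), 2L)),
    score = unname(acc$score),
    support = unname(acc$support[names(acc$score)]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$code, out$month_bucket), ]
  rownames(out) <- NULL
  out
}

#' Temporal scatter of one code's contributions
#'
#' One point per (patient, occurrence) of the code, weighted by its
#' contribution; patients are subsampled without replacement to
#' \code{max_patients} (seeded).  The x coordinate is the day gap before
#' the prediction date.
#'
#' @param code code name.
#' @param contribs list of \code{tsann_contrib}.
#' @param max_patients subsampling cap (default 2000).
#' @param seed subsampling seed.
#' @return data.frame (patient_id, gap_days, weight); empty with a
#'   warning when the code occurs nowhere.
#' @export
temporal_scatter <- function(code, contribs, max_patients = 2000L,
                             seed = 1L) {
  has <- vapply(contribs, function(cm) code %in% rownames(cm$matrix),
                logical(1))
  if (!any(has)) {
    warning("code not present in any patient: ", code)
    return(data.frame(patient_id = character(0), gap_days = integer(0),
                      weight = numeric(0)))
  }
  sel <- which(has)
  if (length(sel) > max_patients) {
    sel <- with_seed(seed, sort(sel[sample.int(length(sel), max_patients)]))
  }
  rows <- lapply(contribs[sel], function(cm) {
    w <- cm$matrix[code, ]
    pos <- which(w > 0)
    if (!length(pos)) return(NULL)
    data.frame(patient_id = cm$patient_id,
               gap_days = cm$gaps[pos],
               weight = unname(w[pos]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(patient_id = character(0),
                                      gap_days = integer(0),
                                      weight = numeric(0))
  rownames(out) <- NULL
  out
}

#' Contributions for a whole cohort
#'
#' Convenience wrapper: predicts every sample and derives its
#' contribution matrix.
#'
#' @param model trained \code{tsann_model}.
#' @param encs list of encoded samples.
#' @return list of \code{tsann_contrib}.
#' @export
cohort_contributions <- function(model, encs) {
  lapply(encs, function(e) patient_contributions(predict_risk(model, e), e))
}
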