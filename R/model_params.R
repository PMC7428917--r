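## Model parameterization: variant registry and seeded initialization.

#' Model variants
#'
#' \describe{
#'   \item{TSANN_II}{code-level attention, elapsed-time embedding, LSTM,
#'     visit-level attention, dense + softmax (the full two-level model).}
#'   \item{TSANN_I}{as TSANN_II but the visit-attention layer is removed;
#'     prediction uses the final LSTM state.}
#'   \item{TSANN_I_STEP}{as TSANN_I but the time embedding indexes the
#'     visit's order rank (1, 2, 3, ...) instead of the day gap.}
#'   \item{ALSTM}{per-visit code averaging, LSTM, visit-level attention.}
#'   \item{LSTM}{per-visit code averaging, LSTM, final state.}
#'   \item{MLP}{code embeddings averaged over the whole record, dense +
#'     softmax.}
#'   \item{LR}{logistic regression on code (or code-by-month) frequency
#'     features; see \code{\link{fit_lr}}.}
#' }
#'
#' @param name variant name.
#' @param use_time whether elapsed-time information is used.
#' @return list of class \code{tsann_variant} describing the composition:
#'   \code{code_agg} (attention|mean), \code{recurrent} (flag),
#'   \code{visit_agg} (attention|final|mean), \code{time_mode}
#'   (gap|step|none).
#' @export
variant_spec <- function(name = c("TSANN_II", "TSANN_I", "TSANN_I_STEP",
                                  "ALSTM", "LSTM", "MLP", "LR"),
                         use_time = TRUE) {
  name <- match.arg(name)
  time_mode <- if (!use_time) "none" else if (name == "TSANN_I_STEP") "step" else "gap"
  structure(list(
    name = name,
    use_time = use_time,
    code_agg = if (name %in% c("TSANN_II", "TSANN_I", "TSANN_I_STEP"))
      "attention" else "mean",
    recurrent = name %in% c("TSANN_II", "TSANN_I", "TSANN_I_STEP",
                            "ALSTM", "LSTM"),
    visit_agg = switch(name,
      TSANN_II = "attention", ALSTM = "attention",
      TSANN_I = "final", TSANN_I_STEP = "final", LSTM = "final",
      MLP = "mean", LR = "mean"),
    time_mode = time_mode
  ), class = "tsann_variant")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

unif_init <- function(...) {
  dims <- c(...)
  array(stats::runif(prod(dims), -0.05, 0.05), dim = dims)
}

#' Initialize a model
#'
#' Embeddings start uniform(-0.05, 0.05); dense/LSTM weights use
#' Glorot-style limits; the LSTM forget-gate bias starts at 1 (a standard
#' stability choice); the padding embedding row is frozen at zero so
#' padded positions cannot influence predictions.  Gate activations are
#' always sigmoid; \code{activation} sets the LSTM candidate/cell-output
#' nonlinearity and \code{dense_activation} the pre-softmax dense layer
#' (defaults to \code{activation}).
#'
#' @param vocab_size concept vocabulary size V_c (padding and unknown
#'   included).
#' @param variant a \code{\link{variant_spec}} (or variant name).
#' @param D_c concept embedding dimension.
#' @param m time embedding dimension.
#' @param H LSTM hidden size.
#' @param activation one of "tanh", "relu", "leaky_relu".
#' @param dense_activation dense-layer activation (default: same).
#' @param batch_norm add batch normalization before the softmax head.
#' @param use_time passed to \code{variant_spec} when \code{variant} is a
#'   name.
#' @param seed integer seed for the initialization.
#' @return object of class \code{tsann_model}: \code{params} (named list
#'   of arrays), \code{config}, \code{variant}, \code{bn_stats}.
#' @export
init_model <- function(vocab_size, variant = "TSANN_II", D_c = 16L,
                       m = 8L, H = 16L, activation = "tanh",
                       dense_activation = NULL, batch_norm = FALSE,
                       use_time = TRUE, seed = 1L) {
  if (is.character(variant)) variant <- variant_spec(variant, use_time)
  if (variant$name == "LR") {
    stop_config("the LR baseline is fitted with fit_lr(), not init_model()")
  }
  I <- D_c + m
  rdim <- if (variant$recurrent) H else I
  with_seed(seed, {
    params <- list(E = unif_init(vocab_size, D_c))
    params$E[PAD_INDEX + 1L, ] <- 0
    if (variant$time_mode != "none") {
      params$Temb <- unif_init(TIME_VOCAB, m)
    }
    if (variant$code_agg == "attention") {
      params$att_Wv <- glorot(D_c, D_c)
      params$att_bv <- numeric(D_c)
      params$att_uv <- as.numeric(unif_init(D_c))
    }
    if (variant$recurrent) {
      for (g in c("f", "i", "o", "c")) {
        params[[paste0("lstm_W", g)]] <- glorot(I, H)
        params[[paste0("lstm_U", g)]] <- glorot(H, H)
        params[[paste0("lstm_b", g)]] <- if (g == "f") rep(1, H) else numeric(H)
      }
    }
    if (variant$visit_agg == "attention") {
      params$vat_Wp <- glorot(H, H)
      params$vat_bp <- numeric(H)
      params$vat_up <- as.numeric(unif_init(H))
    }
    params$dense_W <- glorot(rdim, H)
    params$dense_b <- numeric(H)
    if (batch_norm) {
      params$bn_gamma <- rep(1, H)
      params$bn_beta <- numeric(H)
    }
    params$out_W <- glorot(H, 2L)
    params$out_b <- numeric(2L)

    structure(list(
      params = params,
      variant = variant,
      config = list(vocab_size = vocab_size, D_c = D_c, m = m, H = H,
                    rdim = rdim, activation = activation,
                    dense_activation = dense_activation %||% activation,
                    batch_norm = batch_norm),
      bn_stats = if (batch_norm) list(mean = numeric(H), var = rep(1, H))
    ), class = "tsann_model")
  })
}

#' Save / load model parameters as structured text
#'
#' The checkpoint is a plain-text file: a JSON-free shape manifest
#' followed by the flattened parameter values, so checkpoints survive
#' text-only pipelines.
#'
#' @param model a \code{tsann_model}.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- model$config
  writeLines(sprintf(
    "tsann_checkpoint\t%s\t%d\t%d\t%d\t%d\t%s\t%s\t%d",
    model$variant$name, cfg$vocab_size, cfg$D_c, cfg$m, cfg$H,
    cfg$activation, cfg$dense_activation, as.integer(cfg$batch_norm)), con)
  writeLines(sprintf("use_time\t%d", as.integer(model$variant$use_time)), con)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    d <- if (is.matrix(p)) dim(p) else c(length(p), 0L)
    writeLines(sprintf("param\t%s\t%d\t%d", nm, d[1], d[2]), con)
    writeLines(paste(sprintf("%.17g", as.numeric(p)), collapse = " "), con)
  }
  if (!is.null(model$bn_stats)) {
    writeLines(sprintf("bn_stats\t%s", paste(
      sprintf("%.17g", c(model$bn_stats$mean, model$bn_stats$var)),
      collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hd[1] != "tsann_checkpoint") stop_config("not a tsann checkpoint: ", path)
  use_time <- as.integer(strsplit(lines[2], "\t")[[1]][2]) == 1L
  model <- init_model(
    vocab_size = as.integer(hd[3]),
    variant = variant_spec(hd[2], use_time),
    D_c = as.integer(hd[4]), m = as.integer(hd[5]), H = as.integer(hd[6]),
    activation = hd[7], dense_activation = hd[8],
    batch_norm = as.integer(hd[9]) == 1L)
  i <- 3L
  while (i <= length(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (fields[1] == "param") {
      vals <- as.numeric(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]])
      nr <- as.integer(fields[3]); nc <- as.integer(fields[4])
      model$params[[fields[2]]] <- if (nc > 0L) matrix(vals, nr, nc) else vals
      i <- i + 2L
    } else if (fields[1] == "bn_stats") {
      vals <- as.numeric(strsplit(fields[2], " ", fixed = TRUE)[[1]])
      H <- model$config$H
      model$bn_stats <- list(mean = vals[1:H], var = vals[(H + 1):(2 * H)])
      i <- i + 1L
    } else i <- i + 1L
  }
  model
}
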