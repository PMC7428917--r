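#' tsann: time-sensitive attentive neural networks for clinical risk
#' prediction
#'
#' Asthma-exacerbation risk prediction from EHR visit sequences with
#' hierarchical attention and elapsed-time embeddings, plus cohort
#' construction, encoding, training/evaluation, interpretation, and a
#' synthetic EHR generator. See the methods vignette for the model and
#' design rationale.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' Numerically stable softmax
#' @param x numeric vector of scores
#' @return vector of the same length summing to 1
#' @keywords internal
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

## Jacobian-vector product of softmax: given y = softmax(x) and dL/dy,
## returns dL/dx = y * (dy - sum(y * dy)).
softmax_backward <- function(y, dy) {
  y * (dy - sum(y * dy))
}

## Elementwise activations used for the LSTM candidate/cell output and the
## dense layer.  Gates always use the logistic sigmoid.
act_fun <- function(x, type) {
  switch(type,
    tanh       = tanh(x),
    relu       = pmax(x, 0),
    leaky_relu = ifelse(x > 0, x, 0.01 * x),
    stop("unknown activation: ", type)
  )
}

## Derivative of act_fun expressed through the pre-activation x and, for
## tanh, the cached output y = tanh(x).
act_grad <- function(x, y, type) {
  switch(type,
    tanh       = 1 - y^2,
    relu       = as.numeric(x > 0),
    leaky_relu = ifelse(x > 0, 1, 0.01),
    stop("unknown activation: ", type)
  )
}

## Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Deterministic 32-bit sub-seed derived from a master seed and a stream tag.
derive_seed <- function(seed, tag) {
  (as.integer(seed) * 1103L + sum(utf8ToInt(as.character(tag)))) %% 2147483647L
}

stop_config <- function(...) stop(..., call. = FALSE)
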