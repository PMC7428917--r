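## Forward computation.  The network is hierarchical:
##   codes -> concept embeddings -> code-level additive attention -> visit
##   vector v_i -> concatenation with the elapsed-time embedding -> LSTM ->
##   visit-level additive attention (or final state) -> dense (+ optional
##   batch norm) -> 2-way softmax.
## Every stage caches its intermediates for the hand-written backward pass.

#' Code-level attention over one visit
#'
#' Additive attention with a learned context vector:
#' \deqn{u_{ij} = \tanh(W_v C_{ij} + b_v),\quad
#'       \alpha_{ij} = \mathrm{softmax}_j(u_{ij}^\top u_v),\quad
#'       v_i = \sum_j \alpha_{ij} C_{ij}.}
#'
#' @param C matrix (codes x D_c) of concept embeddings; padding rows must
#'   already be removed (at least one real code is required).
#' @param params model parameter list with \code{att_Wv}, \code{att_bv},
#'   \code{att_uv}.
#' @return list with \code{v} (visit vector), \code{alpha} (weights
#'   summing to 1) and a \code{cache} for backprop.
#' @export
code_level_attention <- function(C, params) {
  if (!nrow(C)) stop_config("code-level attention requires at least one code")
  pre <- C %*% params$att_Wv +
    matrix(params$att_bv, nrow(C), ncol(C), byrow = TRUE)
  U <- tanh(pre)
  s <- drop(U %*% params$att_uv)
  alpha <- softmax(s)
  v <- drop(crossprod(C, alpha))
  list(v = v, alpha = alpha, cache = list(C = C, U = U, alpha = alpha))
}

#' Visit-level attention over LSTM hidden states
#'
#' \deqn{u_i = \tanh(W_p h_i + b_p),\quad
#'       \beta_i = \mathrm{softmax}_i(u_i^\top u_p),\quad
#'       r_p = \sum_i \beta_i h_i.}
#'
#' @param Hs matrix (visits x H) of hidden states.
#' @param params parameter list with \code{vat_Wp}, \code{vat_bp},
#'   \code{vat_up}.
#' @return list with \code{r} (summary vector), \code{beta} and
#'   \code{cache}.
#' @export
visit_level_attention <- function(Hs, params) {
  pre <- Hs %*% params$vat_Wp +
    matrix(params$vat_bp, nrow(Hs), ncol(Hs), byrow = TRUE)
  U <- tanh(pre)
  s <- drop(U %*% params$vat_up)
  beta <- softmax(s)
  r <- drop(crossprod(Hs, beta))
  list(r = r, beta = beta, cache = list(Hs = Hs, U = U, beta = beta))
}

#' Attach the elapsed-time embedding to a visit vector
#'
#' Concatenates the time-embedding row for the visit's day gap (variant
#' TSANN_I_STEP uses the visit's order rank instead); when time is
#' disabled an all-zero m-vector is concatenated so shapes are stable
#' across ablations.
#'
#' @param v visit vector (D_c).
#' @param gap day gap in [0, 364].
#' @param rank 1-based visit order rank (oldest first).
#' @param model a \code{tsann_model}.
#' @return list with \code{x} (D_c + m vector) and \code{trow} (the
#'   embedding row used, 0 when none).
#' @export
attach_time_embedding <- function(v, gap, rank, model) {
  m <- model$config$m
  mode <- model$variant$time_mode
  if (mode == "none") return(list(x = c(v, numeric(m)), trow = 0L))
  idx <- if (mode == "step") min(rank, TIME_VOCAB) else gap + 1L
  if (idx < 1L || idx > TIME_VOCAB) {
    stop_config("time index out of range: ", idx)
  }
  list(x = c(v, model$params$Temb[idx, ]), trow = idx)
}

#' One LSTM pass over a sequence of visit vectors
#'
#' Standard gates (sigmoid) with configurable candidate/cell-output
#' activation:
#' \deqn{f_t,i_t,o_t = \sigma(\cdot),\ g_t = \phi(\cdot),\
#'       c_t = f_t c_{t-1} + i_t g_t,\ h_t = o_t \phi(c_t)}
#' starting from a zero state.
#'
#' @param X matrix (T x D_c+m) of visit inputs.
#' @param params parameter list with the \code{lstm_*} blocks.
#' @param activation candidate/cell-output activation.
#' @return list with \code{H} (T x H hidden states) and \code{cache}.
#' @export
lstm_forward <- function(X, params, activation = "tanh") {
  Tn <- nrow(X)
  Hn <- ncol(params$lstm_Uf)
  h <- numeric(Hn); cc <- numeric(Hn)
  Hs <- matrix(0, Tn, Hn)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- X[t, ]
    fp <- drop(x %*% params$lstm_Wf) + drop(h %*% params$lstm_Uf) + params$lstm_bf
    ip <- drop(x %*% params$lstm_Wi) + drop(h %*% params$lstm_Ui) + params$lstm_bi
    op <- drop(x %*% params$lstm_Wo) + drop(h %*% params$lstm_Uo) + params$lstm_bo
    gp <- drop(x %*% params$lstm_Wc) + drop(h %*% params$lstm_Uc) + params$lstm_bc
    f <- sigmoid(fp); i <- sigmoid(ip); o <- sigmoid(op)
    g <- act_fun(gp, activation)
    c_prev <- cc
    cc <- f * c_prev + i * g
    sc <- act_fun(cc, activation)
    h <- o * sc
    Hs[t, ] <- h
    cache[[t]] <- list(x = x, f = f, i = i, o = o, g = g, gp = gp,
                       c_prev = c_prev, c = cc, sc = sc)
  }
  list(H = Hs, cache = cache)
}

## Per-sample encoder: everything up to (but excluding) the dense head.
## Padding indices are masked here: index-0 codes are dropped from every
## visit and visits left with no real codes are dropped from the sequence,
## so padding can never change the prediction.
encoder_forward <- function(model, enc) {
  p <- model$params
  va <- model$variant
  D_c <- model$config$D_c
  keep <- list()
  for (v in enc$visits) {
    codes <- v$codes[v$codes != PAD_INDEX]
    if (length(codes)) keep[[length(keep) + 1L]] <-
        list(codes = codes, gap = v$gap)
  }
  if (!length(keep)) stop_config("sequence contains no real codes")
  Tn <- length(keep)
  X <- matrix(0, Tn, D_c + model$config$m)
  att <- vector("list", Tn)
  trows <- integer(Tn)
  alphas <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    C <- p$E[keep[[t]]$codes + 1L, , drop = FALSE]
    if (va$code_agg == "attention") {
      ca <- code_level_attention(C, p)
      v_t <- ca$v
      att[[t]] <- ca$cache
      alphas[[t]] <- ca$alpha
    } else {
      v_t <- colMeans(C)
      att[[t]] <- list(C = C)
      alphas[[t]] <- rep(1 / nrow(C), nrow(C))
    }
    te <- attach_time_embedding(v_t, keep[[t]]$gap, t, model)
    X[t, ] <- te$x
    trows[t] <- te$trow
  }
  if (va$recurrent) {
    ls <- lstm_forward(X, p, model$config$activation)
    if (va$visit_agg == "attention") {
      vat <- visit_level_attention(ls$H, p)
      r <- vat$r; beta <- vat$beta
    } else {
      vat <- NULL
      r <- ls$H[nrow(ls$H), ]
      beta <- NULL
    }
  } else {
    ls <- NULL; vat <- NULL; beta <- NULL
    r <- colMeans(X)
  }
  list(r = r, beta = beta, alphas = alphas,
       cache = list(keep = keep, att = att, trows = trows, X = X,
                    lstm = ls, vat = vat))
}

## Dense + optional batch norm + softmax head over a batch of summary
## vectors.  train=TRUE uses batch statistics (and can update the running
## stats); train=FALSE uses the stored running statistics.
head_forward <- function(model, R, train = FALSE, update_stats = train,
                         eps = 1e-5) {
  p <- model$params
  B <- nrow(R)
  A <- R %*% p$dense_W + matrix(p$dense_b, B, ncol(p$dense_W), byrow = TRUE)
  bn <- NULL
  if (model$config$batch_norm) {
    if (train) {
      mu <- colMeans(A)
      va <- colMeans(A^2) - mu^2
    } else {
      mu <- model$bn_stats$mean
      va <- model$bn_stats$var
    }
    inv_std <- 1 / sqrt(va + eps)
    xhat <- (A - matrix(mu, B, length(mu), byrow = TRUE)) *
      matrix(inv_std, B, length(mu), byrow = TRUE)
    A2 <- xhat * matrix(p$bn_gamma, B, length(mu), byrow = TRUE) +
      matrix(p$bn_beta, B, length(mu), byrow = TRUE)
    bn <- list(xhat = xhat, inv_std = inv_std, mu = mu, var = va,
               update = update_stats)
  } else {
    A2 <- A
  }
  Z <- act_fun(A2, model$config$dense_activation)
  logits <- Z %*% p$out_W + matrix(p$out_b, B, 2L, byrow = TRUE)
  Pm <- t(apply(logits, 1L, softmax))
  list(P = Pm, cache = list(R = R, A = A, A2 = A2, Z = Z, bn = bn))
}

## Weighted cross-entropy over a batch; class_weights = c(w0, w1).
ce_loss <- function(P, y, class_weights = c(1, 1)) {
  w <- class_weights[y + 1L]
  py <- P[cbind(seq_along(y), y + 1L)]
  mean(-w * log(pmax(py, 1e-12)))
}

#' Predict exacerbation risk
#'
#' Runs the full forward pass for a variant and returns the risk
#' probability together with the attention weights used for
#' interpretation.
#'
#' @param model a \code{tsann_model}.
#' @param enc a \code{tsann_encoded} sequence (or a list of them for
#'   \code{predict_cohort}).
#' @return \code{predict_risk}: object of class \code{tsann_risk}:
#'   \code{p} (probability of exacerbation, in (0,1)), \code{prob}
#'   (2-class vector summing to 1), \code{alpha} (per-visit code weights,
#'   each summing to 1), \code{beta} (visit weights summing to 1, or
#'   \code{NULL} for variants without visit attention).
#' @export
predict_risk <- function(model, enc) {
  ef <- encoder_forward(model, enc)
  hf <- head_forward(model, matrix(ef$r, 1L), train = FALSE)
  structure(list(
    p = hf$P[1L, 2L],
    prob = hf$P[1L, ],
    alpha = ef$alphas,
    beta = ef$beta,
    patient_id = enc$patient_id,
    label = enc$label
  ), class = "tsann_risk")
}

#' @rdname predict_risk
#' @param encs list of encoded sequences.
#' @return \code{predict_cohort}: data.frame with \code{patient_id},
#'   \code{label}, \code{score}.
#' @export
predict_cohort <- function(model, encs) {
  R <- t(vapply(encs, function(e) encoder_forward(model, e)$r,
                numeric(model$config$rdim)))
  hf <- head_forward(model, R, train = FALSE)
  data.frame(
    patient_id = vapply(encs, `[[`, character(1), "patient_id"),
    label = vapply(encs, `[[`, integer(1), "label"),
    score = hf$P[, 2L],
    stringsAsFactors = FALSE
  )
}
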