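## Hand-written backpropagation.  Gradients flow head -> (visit attention
## or final state) -> LSTM (BPTT) -> time embeddings / code attention ->
## concept embeddings.  Gradient correctness is guarded by the
## finite-difference check in gradient_check().

zero_like <- function(params) lapply(params, function(p) {
  if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
})

## Backward through dense (+BN) + softmax head.
## dlogits for weighted CE averaged over the batch: w_i (p_i - y_i) / B.
head_backward <- function(model, hcache, P, y, class_weights = c(1, 1)) {
  p <- model$params
  B <- nrow(P)
  Y <- matrix(0, B, 2L)
  Y[cbind(seq_len(B), y + 1L)] <- 1
  w <- class_weights[y + 1L]
  dlogits <- (P - Y) * (w / B)

  g <- list()
  Z <- hcache$Z
  g$out_W <- crossprod(Z, dlogits)
  g$out_b <- colSums(dlogits)
  dZ <- dlogits %*% t(p$out_W)
  dA2 <- dZ * act_grad(hcache$A2, Z, model$config$dense_activation)
  if (model$config$batch_norm) {
    bn <- hcache$bn
    g$bn_gamma <- colSums(dA2 * bn$xhat)
    g$bn_beta <- colSums(dA2)
    dxhat <- dA2 * matrix(p$bn_gamma, B, ncol(dA2), byrow = TRUE)
    mean_dxhat <- colMeans(dxhat)
    mean_dxhat_xhat <- colMeans(dxhat * bn$xhat)
    dA <- (dxhat -
             matrix(mean_dxhat, B, ncol(dA2), byrow = TRUE) -
             bn$xhat * matrix(mean_dxhat_xhat, B, ncol(dA2), byrow = TRUE)) *
      matrix(bn$inv_std, B, ncol(dA2), byrow = TRUE)
  } else {
    dA <- dA2
  }
  g$dense_W <- crossprod(hcache$R, dA)
  g$dense_b <- colSums(dA)
  dR <- dA %*% t(p$dense_W)
  list(grads = g, dR = dR)
}

## Backward through one sample's encoder; accumulates into `acc` (an
## environment holding gradient arrays) and returns nothing.
encoder_backward <- function(model, ecache, dr, acc) {
  p <- model$params
  va <- model$variant
  D_c <- model$config$D_c
  m <- model$config$m
  keep <- ecache$keep
  Tn <- length(keep)

  dX <- matrix(0, Tn, D_c + m)
  if (va$recurrent) {
    Hs <- ecache$lstm$H
    dH <- matrix(0, Tn, ncol(Hs))
    if (va$visit_agg == "attention") {
      vc <- ecache$vat$cache
      beta <- vc$beta
      dbeta <- drop(Hs %*% dr)
      dH <- dH + beta %o% dr
      ds <- softmax_backward(beta, dbeta)
      dU <- ds %o% p$vat_up
      acc$g$vat_up <- acc$g$vat_up + drop(crossprod(vc$U, ds))
      dpre <- dU * (1 - vc$U^2)
      acc$g$vat_Wp <- acc$g$vat_Wp + crossprod(Hs, dpre)
      acc$g$vat_bp <- acc$g$vat_bp + colSums(dpre)
      dH <- dH + dpre %*% t(p$vat_Wp)
    } else {
      dH[Tn, ] <- dr
    }
    ## BPTT
    act <- model$config$activation
    dh_next <- numeric(ncol(dH))
    dc_next <- numeric(ncol(dH))
    for (t in seq.int(Tn, 1L)) {
      cc <- ecache$lstm$cache[[t]]
      dh <- dH[t, ] + dh_next
      do_ <- dh * cc$sc
      dc <- dc_next + dh * cc$o * act_grad(cc$c, cc$sc, act)
      df <- dc * cc$c_prev
      di <- dc * cc$g
      dg <- dc * cc$i
      dfp <- df * cc$f * (1 - cc$f)
      dip <- di * cc$i * (1 - cc$i)
      dop <- do_ * cc$o * (1 - cc$o)
      dgp <- dg * act_grad(cc$gp, cc$g, act)
      x <- cc$x
      h_prev <- if (t > 1L) ecache$lstm$H[t - 1L, ] else numeric(ncol(dH))
      acc$g$lstm_Wf <- acc$g$lstm_Wf + x %o% dfp
      acc$g$lstm_Wi <- acc$g$lstm_Wi + x %o% dip
      acc$g$lstm_Wo <- acc$g$lstm_Wo + x %o% dop
      acc$g$lstm_Wc <- acc$g$lstm_Wc + x %o% dgp
      acc$g$lstm_Uf <- acc$g$lstm_Uf + h_prev %o% dfp
      acc$g$lstm_Ui <- acc$g$lstm_Ui + h_prev %o% dip
      acc$g$lstm_Uo <- acc$g$lstm_Uo + h_prev %o% dop
      acc$g$lstm_Uc <- acc$g$lstm_Uc + h_prev %o% dgp
      acc$g$lstm_bf <- acc$g$lstm_bf + dfp
      acc$g$lstm_bi <- acc$g$lstm_bi + dip
      acc$g$lstm_bo <- acc$g$lstm_bo + dop
      acc$g$lstm_bc <- acc$g$lstm_bc + dgp
      dX[t, ] <- drop(p$lstm_Wf %*% dfp) + drop(p$lstm_Wi %*% dip) +
        drop(p$lstm_Wo %*% dop) + drop(p$lstm_Wc %*% dgp)
      dh_next <- drop(p$lstm_Uf %*% dfp) + drop(p$lstm_Ui %*% dip) +
        drop(p$lstm_Uo %*% dop) + drop(p$lstm_Uc %*% dgp)
      dc_next <- dc * cc$f
    }
  } else {
    ## MLP: r is the mean of the visit inputs
    dX <- matrix(rep(dr / Tn, each = Tn), Tn)
  }

  for (t in seq_len(Tn)) {
    dx <- dX[t, ]
    dv <- dx[seq_len(D_c)]
    if (va$time_mode != "none") {
      trow <- ecache$trows[t]
      acc$g$Temb[trow, ] <- acc$g$Temb[trow, ] + dx[(D_c + 1L):(D_c + m)]
    }
    at <- ecache$att[[t]]
    C <- at$C
    if (va$code_agg == "attention") {
      alpha <- at$alpha
      dalpha <- drop(C %*% dv)
      dC <- alpha %o% dv
      ds <- softmax_backward(alpha, dalpha)
      dU <- ds %o% p$att_uv
      acc$g$att_uv <- acc$g$att_uv + drop(crossprod(at$U, ds))
      dpre <- dU * (1 - at$U^2)
      acc$g$att_Wv <- acc$g$att_Wv + crossprod(C, dpre)
      acc$g$att_bv <- acc$g$att_bv + colSums(dpre)
      dC <- dC + dpre %*% t(p$att_Wv)
    } else {
      dC <- matrix(rep(dv / nrow(C), each = nrow(C)), nrow(C))
    }
    rows <- keep[[t]]$codes + 1L
    for (j in seq_along(rows)) {
      acc$g$E[rows[j], ] <- acc$g$E[rows[j], ] + dC[j, ]
    }
  }
  invisible(NULL)
}

## Full loss + gradients for a batch of encoded samples.
## Returns loss (including the l2 term), prediction matrix and gradients.
model_loss_grad <- function(model, encs, class_weights = c(1, 1), l2 = 0,
                            train = TRUE) {
  ecaches <- lapply(encs, function(e) encoder_forward(model, e))
  R <- t(vapply(ecaches, `[[`, numeric(model$config$rdim), "r"))
  y <- vapply(encs, `[[`, integer(1), "label")
  hf <- head_forward(model, R, train = train)
  loss <- ce_loss(hf$P, y, class_weights)
  hb <- head_backward(model, hf$cache, hf$P, y, class_weights)

  acc <- new.env(parent = emptyenv())
  acc$g <- zero_like(model$params)
  for (nm in names(hb$grads)) acc$g[[nm]] <- acc$g[[nm]] + hb$grads[[nm]]
  for (i in seq_along(encs)) {
    encoder_backward(model, ecaches[[i]]$cache, hb$dR[i, ], acc)
  }
  if (l2 > 0) {
    for (nm in names(model$params)) {
      loss <- loss + l2 * sum(model$params[[nm]]^2)
      acc$g[[nm]] <- acc$g[[nm]] + 2 * l2 * model$params[[nm]]
    }
  }
  ## the padding embedding row is frozen
  acc$g$E[PAD_INDEX + 1L, ] <- 0
  list(loss = loss, P = hf$P, grads = acc$g, bn = hf$cache$bn)
}

#' Finite-difference gradient check
#'
#' Compares the analytic gradient of the batch loss with central finite
#' differences for every parameter block (a random subset of coordinates
#' per block), on the exact loss the training loop optimizes.
#'
#' @param model a \code{tsann_model}.
#' @param encs list of encoded samples (a small batch).
#' @param n_coords coordinates sampled per parameter block.
#' @param h finite-difference step.
#' @param l2,class_weights loss settings.
#' @return data.frame with per-block maximum absolute and relative error.
#' @export
gradient_check <- function(model, encs, n_coords = 5L, h = 1e-5, l2 = 0.001,
                           class_weights = c(1, 1)) {
  ana <- model_loss_grad(model, encs, class_weights, l2)$grads
  loss_at <- function(m) model_loss_grad(m, encs, class_weights, l2)$loss
  out <- lapply(names(model$params), function(nm) {
    p <- model$params[[nm]]
    k <- length(p)
    ## skip the frozen padding row of E
    coords <- if (nm == "E") {
      valid <- setdiff(seq_len(k), which(row(as.matrix(p)) == PAD_INDEX + 1L))
      sample(valid, min(n_coords, length(valid)))
    } else {
      sample(k, min(n_coords, k))
    }
    errs <- vapply(coords, function(ci) {
      m2 <- model
      m2$params[[nm]][ci] <- p[ci] + h
      lp <- loss_at(m2)
      m2$params[[nm]][ci] <- p[ci] - h
      lm <- loss_at(m2)
      fd <- (lp - lm) / (2 * h)
      an <- ana[[nm]][ci]
      c(abs(fd - an), abs(fd - an) / max(1, abs(fd), abs(an)))
    }, numeric(2))
    data.frame(block = nm, max_abs_err = max(errs[1, ]),
               max_rel_err = max(errs[2, ]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
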