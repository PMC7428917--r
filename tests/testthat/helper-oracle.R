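# Independent straight-line oracles, coded directly from the model
# equations with explicit loops.  They deliberately share no code with the
# package's vectorized implementation.

# Full two-level forward pass: code attention -> time concat -> LSTM ->
# visit attention -> dense -> softmax.  `visits` is a list of
# list(codes = integer indices, gap = day gap); params/config as in
# init_model.  Returns list(p, prob, alpha, beta).
oracle_tsann2_forward <- function(params, visits, D_c, m, H,
                                  activation = "tanh",
                                  visit_attention = TRUE) {
  phi <- function(x) {
    if (activation == "tanh") tanh(x)
    else if (activation == "relu") ifelse(x > 0, x, 0)
    else ifelse(x > 0, x, 0.01 * x)
  }
  Tn <- length(visits)
  X <- matrix(0, Tn, D_c + m)
  alphas <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    codes <- visits[[t]]$codes
    n <- length(codes)
    s <- numeric(n)
    Cm <- matrix(0, n, D_c)
    for (j in seq_len(n)) {
      Cj <- params$E[codes[j] + 1L, ]
      Cm[j, ] <- Cj
      uj <- tanh(sapply(seq_len(D_c), function(k)
        sum(Cj * params$att_Wv[, k]) + params$att_bv[k]))
      s[j] <- sum(uj * params$att_uv)
    }
    e <- exp(s - max(s))
    alpha <- e / sum(e)
    alphas[[t]] <- alpha
    v <- numeric(D_c)
    for (j in seq_len(n)) v <- v + alpha[j] * Cm[j, ]
    X[t, ] <- c(v, params$Temb[visits[[t]]$gap + 1L, ])
  }
  # LSTM, one gate at a time
  h <- numeric(H); cc <- numeric(H)
  Hs <- matrix(0, Tn, H)
  gate <- function(W, U, b, x, h) {
    sapply(seq_len(H), function(k) sum(x * W[, k]) + sum(h * U[, k]) + b[k])
  }
  for (t in seq_len(Tn)) {
    x <- X[t, ]
    f <- 1 / (1 + exp(-gate(params$lstm_Wf, params$lstm_Uf, params$lstm_bf, x, h)))
    i <- 1 / (1 + exp(-gate(params$lstm_Wi, params$lstm_Ui, params$lstm_bi, x, h)))
    o <- 1 / (1 + exp(-gate(params$lstm_Wo, params$lstm_Uo, params$lstm_bo, x, h)))
    g <- phi(gate(params$lstm_Wc, params$lstm_Uc, params$lstm_bc, x, h))
    cc <- f * cc + i * g
    h <- o * phi(cc)
    Hs[t, ] <- h
  }
  if (visit_attention) {
    q <- numeric(Tn)
    for (t in seq_len(Tn)) {
      ut <- tanh(sapply(seq_len(H), function(k)
        sum(Hs[t, ] * params$vat_Wp[, k]) + params$vat_bp[k]))
      q[t] <- sum(ut * params$vat_up)
    }
    e <- exp(q - max(q))
    beta <- e / sum(e)
    r <- numeric(H)
    for (t in seq_len(Tn)) r <- r + beta[t] * Hs[t, ]
  } else {
    beta <- NULL
    r <- Hs[Tn, ]
  }
  a <- sapply(seq_len(ncol(params$dense_W)), function(k)
    sum(r * params$dense_W[, k]) + params$dense_b[k])
  z <- phi(a)
  logits <- sapply(1:2, function(k)
    sum(z * params$out_W[, k]) + params$out_b[k])
  e <- exp(logits - max(logits))
  prob <- e / sum(e)
  list(p = prob[2], prob = prob, alpha = alphas, beta = beta)
}

# All-pairs concordance AUC with ties counting 1/2.
oracle_auc_pairs <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# Random encoded sequence over a given vocabulary size.
random_encoded <- function(vocab_size, n_visits = 3L, max_codes = 4L,
                           id = "X") {
  gaps <- c(if (n_visits > 1L)
    sort(sample.int(364L, n_visits - 1L), decreasing = TRUE), 0L)
  visits <- lapply(seq_len(n_visits), function(i) {
    k <- sample.int(max_codes, 1L)
    list(codes = sample.int(vocab_size - 1L, k),  # 1..V-1, no padding
         code_names = NULL,
         gap = gaps[i])
  })
  structure(list(patient_id = id, label = sample(0:1, 1L), visits = visits),
            class = "tsann_encoded")
}

# local softmax for constructing test inputs
softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }
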