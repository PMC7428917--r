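make_model <- function(variant = "TSANN_II", vocab_size = 20L, D_c = 6L,
                       m = 3L, H = 5L, seed = 2L, ...) {
  init_model(vocab_size, variant, D_c = D_c, m = m, H = H, seed = seed, ...)
}

test_that("code-level attention handles degenerate visits and matches brute force", {
  m <- make_model()
  p <- m$params
  # single code: softmax of one element
  C1 <- p$E[5L, , drop = FALSE]
  ca <- code_level_attention(C1, p)
  expect_equal(ca$alpha, 1)
  expect_equal(ca$v, drop(C1))
  # identical codes: symmetric weights
  C2 <- p$E[c(5L, 5L), ]
  ca <- code_level_attention(C2, p)
  expect_equal(ca$alpha, c(0.5, 0.5))
  # random vectors against a loop-coded recomputation
  set.seed(4)
  C3 <- matrix(rnorm(3 * 6), 3)
  ca <- code_level_attention(C3, p)
  s <- numeric(3)
  for (j in 1:3) {
    u <- tanh(sapply(1:6, function(k) sum(C3[j, ] * p$att_Wv[, k]) +
                       p$att_bv[k]))
    s[j] <- sum(u * p$att_uv)
  }
  a <- exp(s) / sum(exp(s))
  expect_equal(ca$alpha, a, tolerance = 1e-6)
  expect_equal(ca$v, drop(t(C3) %*% a), tolerance = 1e-6)
  expect_error(code_level_attention(C3[0, , drop = FALSE], p), "at least one")
})

test_that("visit-level attention matches brute force and collapses correctly", {
  m <- make_model()
  p <- m$params
  set.seed(5)
  Hs <- matrix(rnorm(4 * 5), 4)
  va <- visit_level_attention(Hs, p)
  q <- numeric(4)
  for (i in 1:4) {
    u <- tanh(sapply(1:5, function(k) sum(Hs[i, ] * p$vat_Wp[, k]) +
                       p$vat_bp[k]))
    q[i] <- sum(u * p$vat_up)
  }
  b <- exp(q - max(q)) / sum(exp(q - max(q)))
  expect_equal(va$beta, b, tolerance = 1e-6)
  expect_equal(va$r, drop(t(Hs) %*% b), tolerance = 1e-6)
  # one visit: beta = 1, r = h
  va1 <- visit_level_attention(Hs[1, , drop = FALSE], p)
  expect_equal(va1$beta, 1)
  expect_equal(va1$r, Hs[1, ])
  # identical states: uniform beta
  va2 <- visit_level_attention(Hs[c(2, 2, 2), ], p)
  expect_equal(va2$beta, rep(1 / 3, 3))
})

test_that("time attachment looks up the right row, zero-fills ablations, keeps shape", {
  m <- make_model()
  v <- rnorm(6)
  te <- attach_time_embedding(v, 0L, 1L, m)
  expect_length(te$x, 9L)
  expect_equal(te$x[7:9], m$params$Temb[1L, ])
  te <- attach_time_embedding(v, 123L, 2L, m)
  expect_equal(te$x[7:9], m$params$Temb[124L, ])
  expect_error(attach_time_embedding(v, 365L, 1L, m), "out of range")

  m0 <- make_model(use_time = FALSE)
  te0 <- attach_time_embedding(v, 123L, 2L, m0)
  expect_equal(te0$x[7:9], rep(0, 3))

  ms <- make_model("TSANN_I_STEP")
  tes <- attach_time_embedding(v, 123L, 2L, ms)
  expect_equal(tes$x[7:9], ms$params$Temb[2L, ])  # order rank, not gap
})

test_that("LSTM recurrence matches step-by-step gate equations", {
  m <- make_model()
  p <- m$params
  # zero inputs with zero weights/biases are a fixed point under tanh
  pz <- lapply(p, function(x) x * 0)
  X0 <- matrix(0, 3, 9)
  expect_equal(lstm_forward(X0, pz, "tanh")$H, matrix(0, 3, 5))
  # single step from the zero state, hand-computed
  set.seed(6)
  x <- rnorm(9)
  f <- 1 / (1 + exp(-(drop(x %*% p$lstm_Wf) + p$lstm_bf)))
  i <- 1 / (1 + exp(-(drop(x %*% p$lstm_Wi) + p$lstm_bi)))
  o <- 1 / (1 + exp(-(drop(x %*% p$lstm_Wo) + p$lstm_bo)))
  g <- tanh(drop(x %*% p$lstm_Wc) + p$lstm_bc)
  h1 <- o * tanh(i * g)
  out <- lstm_forward(matrix(x, 1), p, "tanh")
  expect_equal(out$H[1, ], h1, tolerance = 1e-6)
  # three steps against an explicit loop for each activation
  for (act in c("tanh", "relu", "leaky_relu")) {
    X <- matrix(rnorm(27), 3)
    got <- lstm_forward(X, p, act)$H
    phi <- function(z) switch(act, tanh = tanh(z), relu = pmax(z, 0),
                              leaky_relu = ifelse(z > 0, z, 0.01 * z))
    h <- numeric(5); cc <- numeric(5)
    for (t in 1:3) {
      xt <- X[t, ]
      ft <- 1 / (1 + exp(-(drop(xt %*% p$lstm_Wf) + drop(h %*% p$lstm_Uf) + p$lstm_bf)))
      it <- 1 / (1 + exp(-(drop(xt %*% p$lstm_Wi) + drop(h %*% p$lstm_Ui) + p$lstm_bi)))
      ot <- 1 / (1 + exp(-(drop(xt %*% p$lstm_Wo) + drop(h %*% p$lstm_Uo) + p$lstm_bo)))
      gt <- phi(drop(xt %*% p$lstm_Wc) + drop(h %*% p$lstm_Uc) + p$lstm_bc)
      cc <- ft * cc + it * gt
      h <- ot * phi(cc)
      expect_equal(got[t, ], h, tolerance = 1e-6)
    }
  }
})

test_that("predictions are proper probabilities for every variant", {
  set.seed(10)
  encs <- lapply(1:3, function(i) random_encoded(20L, n_visits = i + 1L,
                                                 id = paste0("R", i)))
  for (vn in c("TSANN_II", "TSANN_I", "TSANN_I_STEP", "ALSTM", "LSTM",
               "MLP")) {
    m <- make_model(vn)
    for (e in encs) {
      r <- predict_risk(m, e)
      expect_equal(sum(r$prob), 1, tolerance = 1e-9)
      expect_true(r$p > 0 && r$p < 1)
      for (a in r$alpha) expect_equal(sum(a), 1, tolerance = 1e-9)
      if (!is.null(r$beta)) expect_equal(sum(r$beta), 1, tolerance = 1e-9)
    }
  }
})

test_that("on a single-visit patient the two-level model equals the one-level model", {
  # with one visit the visit-attention layer is the identity, so TSANN_II
  # and TSANN_I coincide under shared parameters
  m2 <- make_model("TSANN_II", seed = 8)
  m1 <- make_model("TSANN_I", seed = 8)
  for (nm in names(m1$params)) m1$params[[nm]] <- m2$params[[nm]]
  set.seed(11)
  e <- random_encoded(20L, n_visits = 1L)
  expect_equal(predict_risk(m2, e)$p, predict_risk(m1, e)$p,
               tolerance = 1e-12)
})

test_that("shuffling codes within a visit leaves the prediction unchanged", {
  m <- make_model("TSANN_II")
  set.seed(12)
  e <- random_encoded(20L, n_visits = 3L, max_codes = 5L)
  p0 <- predict_risk(m, e)$p
  for (k in 1:5) {
    e2 <- e
    e2$visits <- lapply(e$visits, function(v) {
      perm <- sample(length(v$codes))
      list(codes = v$codes[perm], code_names = NULL, gap = v$gap)
    })
    expect_equal(predict_risk(m, e2)$p, p0, tolerance = 1e-12)
  }
})

test_that("padding codes and padding visits never change the prediction", {
  for (vn in c("TSANN_II", "TSANN_I", "MLP")) {
    m <- make_model(vn)
    set.seed(13)
    e <- random_encoded(20L, n_visits = 3L)
    p0 <- predict_risk(m, e)$p
    e2 <- e
    e2$visits[[2L]]$codes <- c(e2$visits[[2L]]$codes, 0L, 0L)
    e2$visits <- append(e2$visits, list(list(codes = c(0L, 0L),
                                             code_names = NULL, gap = 50L)),
                        after = 1L)
    expect_identical(predict_risk(m, e2)$p, p0)
  }
})

test_that("checkpoints restore a model exactly", {
  m <- make_model("TSANN_II", batch_norm = TRUE)
  m$bn_stats$mean <- rnorm(5)
  m$bn_stats$var <- abs(rnorm(5)) + 0.5
  path <- withr::local_tempfile(fileext = ".txt")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$params, m$params, tolerance = 1e-14)
  expect_equal(m2$bn_stats, m$bn_stats, tolerance = 1e-14)
  expect_identical(m2$variant$name, m$variant$name)
  set.seed(14)
  e <- random_encoded(20L)
  expect_equal(predict_risk(m2, e)$p, predict_risk(m, e)$p,
               tolerance = 1e-12)
})
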