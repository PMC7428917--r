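## Training loop (mini-batch Adam/RMSprop with l2 on all parameters),
## stratified splits, five-fold cross-validated grid search with
## best-epoch selection, rank-based AUC and paired Wilcoxon comparison.

#' Rank-based AUC
#'
#' Mann-Whitney AUC: the probability a random case scores above a random
#' control, ties counting 1/2 (midranks).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' auc_score(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_config("AUC requires both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified train/test split and five-fold partition
#'
#' Splits samples 8:2 into training and held-out testing, stratified by
#' label, then partitions the training ids into five label-stratified
#' folds of near-equal size.  Deterministic given the seed.
#'
#' @param labels 0/1 vector (ids are positions).
#' @param seed integer seed.
#' @param test_fraction held-out fraction (default 0.2).
#' @param n_folds number of CV folds (default 5).
#' @return list of class \code{tsann_split}: \code{train}, \code{test}
#'   (integer id vectors) and \code{fold} (fold number for each train id).
#' @export
make_splits <- function(labels, seed = 1L, test_fraction = 0.2,
                        n_folds = 5L) {
  labels <- as.integer(labels)
  if (length(labels) < 10L || length(unique(labels)) < 2L) {
    stop_config("need >= 10 samples with both classes")
  }
  with_seed(seed, {
    test <- integer(0)
    for (cl in c(0L, 1L)) {
      ids <- which(labels == cl)
      ids <- ids[sample.int(length(ids))]
      n_test <- round(length(ids) * test_fraction)
      test <- c(test, ids[seq_len(n_test)])
    }
    test <- sort(test)
    train <- setdiff(seq_along(labels), test)
    fold <- integer(length(train))
    for (cl in c(0L, 1L)) {
      pos <- which(labels[train] == cl)
      pos <- pos[sample.int(length(pos))]
      fold[pos] <- rep_len(seq_len(n_folds), length(pos))
    }
    structure(list(train = train, test = test, fold = fold,
                   n_folds = n_folds, seed = seed),
              class = "tsann_split")
  })
}

#' Hyperparameter grid
#'
#' Defaults mirror the full tuning grid (learning rate, l2 penalty, batch
#' size, LSTM activation, batch normalization, optimizer; up to 30
#' epochs).  \code{desk_grid()} is a restricted grid sized for laptop-scale
#' experiments.
#'
#' @param learning_rate,l2,batch_size,activation,batch_norm,optimizer
#'   vectors of candidate values.
#' @param max_epochs training epochs per configuration.
#' @return data.frame with one row per grid point.
#' @export
hyper_grid <- function(learning_rate = c(0.0005, 0.001, 0.005, 0.01),
                       l2 = c(0.0001, 0.0005, 0.001),
                       batch_size = c(32L, 64L, 128L),
                       activation = c("relu", "leaky_relu"),
                       batch_norm = c(TRUE, FALSE),
                       optimizer = c("rmsprop", "adam"),
                       max_epochs = 30L) {
  g <- expand.grid(learning_rate = learning_rate, l2 = l2,
                   batch_size = batch_size, activation = activation,
                   batch_norm = batch_norm, optimizer = optimizer,
                   stringsAsFactors = FALSE)
  attr(g, "max_epochs") <- as.integer(max_epochs)
  g
}

#' @rdname hyper_grid
#' @export
desk_grid <- function(learning_rate = c(0.001, 0.005), l2 = 0.0001,
                      batch_size = 32L, activation = "leaky_relu",
                      batch_norm = FALSE, optimizer = "adam",
                      max_epochs = 8L) {
  hyper_grid(learning_rate, l2, batch_size, activation, batch_norm,
             optimizer, max_epochs)
}

## ---- optimizers -------------------------------------------------------

opt_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

opt_step <- function(params, grads, state, optimizer, lr,
                     beta1 = 0.9, beta2 = 0.999, rho = 0.9, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (optimizer == "adam") {
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]] / (1 - beta1^state$t)
      vhat <- state$v[[nm]] / (1 - beta2^state$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    } else if (optimizer == "rmsprop") {
      state$v[[nm]] <- rho * state$v[[nm]] + (1 - rho) * g^2
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(state$v[[nm]]) + eps)
    } else stop_config("unknown optimizer: ", optimizer)
  }
  list(params = params, state = state)
}

## ---- training ---------------------------------------------------------

#' Train a model by mini-batch gradient descent
#'
#' Class-weighted cross-entropy with an l2 penalty on all parameters,
#' optimized by Adam or RMSprop.  Records the validation AUC after every
#' epoch when a validation set is given.  Aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param model a \code{tsann_model} (freshly initialized or warm).
#' @param train_encs list of encoded training samples.
#' @param val_encs optional list of encoded validation samples.
#' @param epochs number of epochs.
#' @param batch_size mini-batch size.
#' @param learning_rate,optimizer,l2 optimization settings.
#' @param class_weights c(control, case) loss weights.
#' @param seed seed for shuffling.
#' @param verbose print per-epoch progress.
#' @return list of class \code{tsann_fit}: \code{model} (trained),
#'   \code{val_auc} (per-epoch), \code{train_loss} (per-epoch mean batch
#'   loss).
#' @export
train_model <- function(model, train_encs, val_encs = NULL, epochs = 10L,
                        batch_size = 32L, learning_rate = 0.001,
                        optimizer = "adam", l2 = 1e-4,
                        class_weights = c(1, 1), seed = 1L,
                        verbose = FALSE) {
  n <- length(train_encs)
  state <- opt_init(model$params)
  val_auc <- numeric(0)
  train_loss <- numeric(0)
  y_val <- if (!is.null(val_encs))
    vapply(val_encs, `[[`, integer(1), "label")
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b0 in seq.int(1L, n, by = batch_size)) {
        ids <- ord[seq.int(b0, min(b0 + batch_size - 1L, n))]
        lg <- model_loss_grad(model, train_encs[ids], class_weights, l2,
                              train = TRUE)
        if (!is.finite(lg$loss)) {
          stop("training diverged: non-finite loss at epoch ", ep)
        }
        losses <- c(losses, lg$loss)
        st <- opt_step(model$params, lg$grads, state, optimizer,
                       learning_rate)
        model$params <- st$params
        state <- st$state
        model$params$E[PAD_INDEX + 1L, ] <- 0
        if (model$config$batch_norm && !is.null(lg$bn)) {
          mom <- 0.9
          model$bn_stats$mean <- mom * model$bn_stats$mean +
            (1 - mom) * lg$bn$mu
          model$bn_stats$var <- mom * model$bn_stats$var +
            (1 - mom) * lg$bn$var
        }
      }
      train_loss[ep] <- mean(losses)
      if (!is.null(val_encs)) {
        preds <- predict_cohort(model, val_encs)
        val_auc[ep] <- auc_score(preds$score, y_val)
      }
      if (verbose) {
        message(sprintf("epoch %d loss %.4f%s", ep, train_loss[ep],
                        if (length(val_auc)) sprintf(" val AUC %.4f",
                                                     val_auc[ep]) else ""))
      }
    }
  })
  structure(list(model = model, val_auc = val_auc,
                 train_loss = train_loss),
            class = "tsann_fit")
}

#' Grid search with five-fold cross-validation and best-epoch selection
#'
#' For every grid point, trains on each fold's complement and records the
#' fold-out AUC after every epoch; the per-epoch AUCs are averaged across
#' folds and the (grid point, epoch) pair with the best mean AUC is
#' selected.  The winning configuration is then retrained on the full
#' training set for that many epochs.
#'
#' @param encs list of all encoded samples.
#' @param split a \code{\link{make_splits}} plan.
#' @param grid a \code{\link{hyper_grid}} data.frame.
#' @param model_args list of arguments for \code{\link{init_model}}
#'   (vocab_size, variant, D_c, m, H, use_time, ...).
#' @param class_weights loss weights.
#' @param seed base seed.
#' @param verbose print progress.
#' @return list: \code{best} (grid row + \code{epoch} +
#'   \code{mean_auc}), \code{fold_auc} (per grid point: folds x epochs
#'   AUC matrices), \code{final} (the retrained \code{tsann_fit}),
#'   \code{test_pred} — predictions on the held-out test ids.
#' @export
grid_search_cv <- function(encs, split, grid, model_args,
                           class_weights = c(1, 1), seed = 1L,
                           verbose = FALSE) {
  if (!nrow(grid)) stop_config("empty hyperparameter grid")
  max_epochs <- attr(grid, "max_epochs") %||% 10L
  train_ids <- split$train
  fold_auc <- vector("list", nrow(grid))

  for (gi in seq_len(nrow(grid))) {
    gp <- grid[gi, ]
    aucs <- matrix(NA_real_, split$n_folds, max_epochs)
    for (fd in seq_len(split$n_folds)) {
      tr <- train_ids[split$fold != fd]
      va <- train_ids[split$fold == fd]
      model <- do.call(init_model, c(model_args, list(
        activation = gp$activation, batch_norm = gp$batch_norm,
        seed = derive_seed(seed, paste0("init", gi, "_", fd)))))
      fit <- train_model(model, encs[tr], encs[va], epochs = max_epochs,
                         batch_size = gp$batch_size,
                         learning_rate = gp$learning_rate,
                         optimizer = gp$optimizer, l2 = gp$l2,
                         class_weights = class_weights,
                         seed = derive_seed(seed, paste0("sh", gi, "_", fd)))
      aucs[fd, ] <- fit$val_auc
      if (verbose) message(sprintf("grid %d fold %d best AUC %.4f",
                                   gi, fd, max(fit$val_auc)))
    }
    fold_auc[[gi]] <- aucs
  }
  mean_by_epoch <- lapply(fold_auc, colMeans)
  best_gi <- which.max(vapply(mean_by_epoch, max, numeric(1)))
  best_epoch <- which.max(mean_by_epoch[[best_gi]])
  best <- cbind(grid[best_gi, , drop = FALSE],
                epoch = best_epoch,
                mean_auc = mean_by_epoch[[best_gi]][best_epoch])

  gp <- grid[best_gi, ]
  model <- do.call(init_model, c(model_args, list(
    activation = gp$activation, batch_norm = gp$batch_norm,
    seed = derive_seed(seed, "final_init"))))
  final <- train_model(model, encs[train_ids], NULL, epochs = best_epoch,
                       batch_size = gp$batch_size,
                       learning_rate = gp$learning_rate,
                       optimizer = gp$optimizer, l2 = gp$l2,
                       class_weights = class_weights,
                       seed = derive_seed(seed, "final_shuffle"))
  test_pred <- if (length(split$test))
    predict_cohort(final$model, encs[split$test])
  list(best = best, fold_auc = fold_auc, final = final,
       test_pred = test_pred)
}

#' Paired Wilcoxon signed-rank comparison of two AUC samples
#'
#' Two-sided signed-rank test on the paired differences (per-fold or
#' bootstrap AUCs of two models).  All-zero differences return p = 1 with
#' a warning.
#'
#' @param auc_a,auc_b paired numeric vectors of equal length >= 5.
#' @return the two-sided p-value.
#' @export
compare_models <- function(auc_a, auc_b) {
  if (length(auc_a) != length(auc_b) || length(auc_a) < 5L) {
    stop_config("need paired samples of equal length >= 5")
  }
  d <- auc_a - auc_b
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1")
    return(1)
  }
  ## exact null distribution when there are no ties/zeros (small samples);
  ## wilcox.test falls back to the normal approximation otherwise
  suppressWarnings(
    stats::wilcox.test(auc_a, auc_b, paired = TRUE)$p.value
  )
}

## ---- logistic-regression baseline ------------------------------------

#' Logistic-regression baseline on frequency features
#'
#' Builds a fixed-length feature vector of code frequencies per patient
#' (with \code{use_time = TRUE}, features are code-by-month pairs, month =
#' floor(gap/30), expanding the vocabulary as in the time-aware LR
#' baseline) and fits a ridge-penalized logistic model via
#' \pkg{glmnet} (the time expansion routinely makes the feature count
#' exceed the sample count, where an unpenalized fit saturates); the
#' penalty is chosen by cross-validation.  Optional random minority
#' oversampling counteracts class imbalance.
#'
#' @param train_encs,test_encs encoded samples.
#' @param use_time expand features by month bucket.
#' @param oversample logical; duplicate minority samples at random until
#'   balanced (plain random oversampling).
#' @param seed seed for oversampling and penalty cross-validation.
#' @return list: \code{fit} (cv.glmnet), \code{features} (feature names),
#'   \code{test_pred} data.frame(patient_id, label, score).
#' @export
fit_lr <- function(train_encs, test_encs = NULL, use_time = FALSE,
                   oversample = FALSE, seed = 1L) {
  feat_of <- function(e) {
    unlist(lapply(e$visits, function(v) {
      if (use_time) paste0(v$codes, "/", v$gap %/% 30L) else
        as.character(v$codes)
    }))
  }
  counts <- lapply(train_encs, function(e) table(feat_of(e)))
  features <- sort(unique(unlist(lapply(counts, names))))
  mat_of <- function(cnt_list) {
    M <- matrix(0, length(cnt_list), length(features),
                dimnames = list(NULL, features))
    for (i in seq_along(cnt_list)) {
      cn <- cnt_list[[i]]
      hit <- intersect(names(cn), features)
      M[i, hit] <- as.numeric(cn[hit])
    }
    M
  }
  X <- mat_of(counts)
  y <- vapply(train_encs, `[[`, integer(1), "label")
  if (oversample) {
    with_seed(seed, {
      minor <- which(y == as.integer(mean(y) < 0.5))
      need <- abs(sum(y == 1L) - sum(y == 0L))
      extra <- minor[sample.int(length(minor), need, replace = TRUE)]
      X <- rbind(X, X[extra, , drop = FALSE])
      y <- c(y, y[extra])
    })
  }
  fit <- with_seed(derive_seed(seed, "cvglmnet"),
                   glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                                     nfolds = 5L))
  test_pred <- NULL
  if (!is.null(test_encs)) {
    Xt <- mat_of(lapply(test_encs, function(e) table(feat_of(e))))
    score <- drop(stats::predict(fit, Xt, s = "lambda.min",
                                 type = "response"))
    test_pred <- data.frame(
      patient_id = vapply(test_encs, `[[`, character(1), "patient_id"),
      label = vapply(test_encs, `[[`, integer(1), "label"),
      score = score, stringsAsFactors = FALSE)
  }
  list(fit = fit, features = features, test_pred = test_pred)
}
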