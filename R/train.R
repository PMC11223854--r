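# ---- gradient machinery -----------------------------------------------------
# Reverse-mode gradients of the mean binary cross-entropy through the whole
# network.  Structures mirror net$weights so the optimizer can walk both in
# parallel.

zero_like <- function(w) rapply(w, function(p) p * 0, how = "replace")

# One LSTM direction, processing order t = 1..T (callers reverse the
# sequence for the backward direction).  `ext_dh` is the externally injected
# gradient on each step's hidden state.
lstm_backward <- function(par, caches, ext_dh) {
  T_ <- length(caches)
  H <- length(par$b) / 4
  B <- nrow(caches[[1]]$x)
  dWx <- par$Wx * 0
  dWh <- par$Wh * 0
  db <- par$b * 0
  dh_rec <- matrix(0, B, H)
  dc <- matrix(0, B, H)
  dxs <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    cc <- caches[[t]]
    dh <- dh_rec + (if (is.null(ext_dh[[t]])) 0 else ext_dh[[t]])
    do <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- dz %*% t(par$Wx)
    dh_rec <- dz %*% t(par$Wh)
    dc <- dc * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db, dxs = dxs)
}

network_backward <- function(net, fwd, y, sample_weight = NULL) {
  w <- net$weights
  B <- length(fwd$scores)
  T_ <- length(fwd$proj_in)
  nd <- length(w$dense)
  nb <- length(w$rnn)
  grad <- list(proj = list(W = w$proj$W * 0, b = w$proj$b * 0),
               rnn = vector("list", nb), dense = vector("list", nd))
  err <- (fwd$scores - y) / B
  if (!is.null(sample_weight)) err <- err * sample_weight
  da <- NULL
  for (k in rev(seq_len(nd))) {
    cc <- fwd$dense[[k]]
    if (k == nd) {
      dz <- matrix(err, B, 1)
    } else {
      if (!is.null(cc$mask)) da <- da * cc$mask
      dz <- da * (cc$z > 0)
    }
    grad$dense[[k]] <- list(W = crossprod(cc$input, dz), b = colSums(dz))
    da <- dz %*% t(w$dense[[k]]$W)
  }
  # da is now the gradient on the last recurrent layer's output vector
  d_seq <- NULL
  for (l in rev(seq_len(nb))) {
    H <- length(w$rnn[[l]]$fwd$b) / 4
    ext_f <- vector("list", T_)
    ext_b <- vector("list", T_)
    if (l == nb) {
      ext_f[[T_]] <- da[, seq_len(H), drop = FALSE]
      ext_b[[T_]] <- da[, H + seq_len(H), drop = FALSE]
    } else {
      for (t in seq_len(T_)) {
        ext_f[[t]] <- d_seq[[t]][, seq_len(H), drop = FALSE]
        ext_b[[T_ - t + 1]] <- d_seq[[t]][, H + seq_len(H), drop = FALSE]
      }
    }
    bf <- lstm_backward(w$rnn[[l]]$fwd, fwd$rnn[[l]]$fwd$caches, ext_f)
    bb <- lstm_backward(w$rnn[[l]]$bwd, fwd$rnn[[l]]$bwd$caches, ext_b)
    grad$rnn[[l]] <- list(fwd = bf[c("Wx", "Wh", "b")],
                          bwd = bb[c("Wx", "Wh", "b")])
    d_seq <- lapply(seq_len(T_), function(t) {
      bf$dxs[[t]] + bb$dxs[[T_ - t + 1]]
    })
  }
  for (t in seq_len(T_)) {
    grad$proj$W <- grad$proj$W + crossprod(fwd$proj_in[[t]], d_seq[[t]])
    grad$proj$b <- grad$proj$b + colSums(d_seq[[t]])
  }
  grad
}

# Adam with bias correction; walks the nested weight/gradient lists.
adam_step <- function(state, w, g, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  t_ <- state$t
  upd <- function(wi, gi, mi, vi) {
    mi <- beta1 * mi + (1 - beta1) * gi
    vi <- beta2 * vi + (1 - beta2) * gi^2
    mhat <- mi / (1 - beta1^t_)
    vhat <- vi / (1 - beta2^t_)
    list(w = wi - lr * mhat / (sqrt(vhat) + eps), m = mi, v = vi)
  }
  walk <- function(wn, gn, mn, vn) {
    if (is.numeric(wn)) return(upd(wn, gn, mn, vn))
    out <- mapply(walk, wn, gn, mn, vn, SIMPLIFY = FALSE)
    list(w = lapply(out, `[[`, "w"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  }
  res <- walk(w, g, state$m, state$v)
  state$m <- res$m
  state$v <- res$v
  list(state = state, weights = res$w)
}

# ---- single-network fit -----------------------------------------------------

#' Train one network with ROC-divergence early stopping
#'
#' Minimizes binary cross-entropy with Adam at the configured learning
#' rate, recording training and validation AuROCC each epoch.  Training
#' stops once the validation AuROCC has not improved by at least
#' `min_delta` for `patience` consecutive epochs (the point where the
#' training and validation ROC curves diverge); the returned network
#' carries the weights of the best-validation epoch
#' (see [select_stopping_epoch()]).
#'
#' @param x,y Encoded training windows (n x 6 x 36 array) and 0/1 labels.
#' @param x_val,y_val Held-out validation windows and labels.
#' @param config A [network_config()].
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @param max_epochs Epoch cap; default 200.
#' @param patience,min_delta Early-stopping parameters; defaults 5 and
#'   0.001.
#' @param standardize Fit a per-feature z-score scaler on `x` and apply it
#'   to all inputs (training-split statistics only)?  Default `TRUE`.
#' @param class_weight `NULL` (unweighted loss, the default) or
#'   `"balanced"` to upweight the minority class inversely to prevalence.
#' @return A trained [apr_network][build_network] with `history`,
#'   `stopping_epoch` and (optionally) `scaler` filled in.
#' @export
fit_network <- function(x, y, x_val, y_val, config = network_config(),
                        seed = 1L, max_epochs = 200L, patience = 5L,
                        min_delta = 0.001, standardize = TRUE,
                        class_weight = NULL) {
  stopifnot(length(y) == dim(x)[1], length(y_val) == dim(x_val)[1])
  scaler <- NULL
  if (standardize) {
    scaler <- fit_scaler(x)
    x <- apply_scaler(x, scaler)
    x_val <- apply_scaler(x_val, scaler)
  }
  sw <- NULL
  if (identical(class_weight, "balanced")) {
    n <- length(y)
    wpos <- n / (2 * sum(y == 1))
    wneg <- n / (2 * sum(y == 0))
    sw <- ifelse(y == 1, wpos, wneg)
  }
  net <- build_network(config, seed)
  net$scaler <- scaler
  n <- length(y)
  bs <- config$batch_size
  state <- list(m = zero_like(net$weights), v = zero_like(net$weights), t = 0)
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  best_val <- -Inf
  best_weights <- net$weights
  best_epoch <- 0L
  stall <- 0L
  with_run_seed(seed + 17L, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        xb <- x[idx, , , drop = FALSE]
        fwd <- network_forward(net, xb, training = TRUE, cache = TRUE)
        grad <- network_backward(net, fwd, y[idx],
                                 if (is.null(sw)) NULL else sw[idx])
        res <- adam_step(state, net$weights, grad, config$learning_rate)
        state <- res$state
        net$weights <- res$weights
      }
      hist_train[epoch] <- auc_rank(network_forward(net, x), y)
      hist_val[epoch] <- auc_rank(network_forward(net, x_val), y_val)
      if (hist_val[epoch] > best_val + min_delta) stall <- 0L else stall <- stall + 1L
      if (hist_val[epoch] > best_val) {
        best_val <- hist_val[epoch]
        best_weights <- net$weights
        best_epoch <- epoch
      }
      if (stall >= patience) break
    }
  })
  net$weights <- best_weights
  net$history <- tibble(epoch = seq_along(hist_val),
                        train_auc = hist_train, val_auc = hist_val)
  net$stopping_epoch <- select_stopping_epoch(net$history, patience, min_delta)
  net
}

# ---- cross-validated ensemble ----------------------------------------------

#' Train the five-member ensemble by cross-validation
#'
#' Splits the labelled hexapeptides into `k` stratified folds and trains
#' one network per fold (on the other `k - 1` folds, early-stopped on the
#' held-out fold), yielding one member per data split.  The ensemble
#' prediction is the arithmetic mean of the member scores.  The default
#' classification threshold stored with the ensemble is the Youden-J
#' optimum of the out-of-fold predictions, computed on the training data
#' at train time.
#'
#' @param data A data frame with columns `sequence` and `label`.
#' @param config A [network_config()].
#' @param k Number of folds (= ensemble members); default 5.
#' @param seed Integer seed.
#' @param table A [feature_table][load_feature_table].
#' @param folds Optional precomputed [make_folds()] plan.
#' @inheritParams fit_network
#' @return An `apr_ensemble` object; see [predict_ensemble()],
#'   [profile_sequence()], [save_model()].
#' @export
train_crossval <- function(data, config = network_config(), k = 5L,
                           seed = 1L, table = default_feature_table(),
                           folds = NULL, max_epochs = 200L, patience = 5L,
                           min_delta = 0.001, standardize = TRUE,
                           class_weight = NULL) {
  enc <- encode_dataset(data, table)
  if (is.null(folds)) folds <- make_folds(enc$y, k = k, seed = seed)
  k <- folds$k
  fa <- folds$fold_assignments
  members <- vector("list", k)
  oof <- numeric(length(enc$y))
  fold_val_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fa != f)
    va <- which(fa == f)
    member_seed <- (as.integer(seed) * 131L + f) %% 2147483629L
    net <- tryCatch(
      fit_network(enc$x[tr, , , drop = FALSE], enc$y[tr],
                  enc$x[va, , , drop = FALSE], enc$y[va],
                  config = config, seed = member_seed,
                  max_epochs = max_epochs, patience = patience,
                  min_delta = min_delta, standardize = standardize,
                  class_weight = class_weight),
      error = function(e) stop_input("training failed on fold %d: %s", f,
                                     conditionMessage(e)))
    members[[f]] <- net
    oof[va] <- predict_batch(net, enc$x[va, , , drop = FALSE])
    fold_val_auc[f] <- max(net$history$val_auc)
  }
  roc <- roc_curve(oof, enc$y)
  yj <- youden_threshold(roc)
  structure(list(members = members, config = config,
                 feature_table_id = feature_table_id(table),
                 aggregation = "mean", threshold = yj$threshold,
                 youden_j = yj$J, oof_auc = attr(roc, "auc"),
                 fold_val_auc = fold_val_auc, folds = folds,
                 seed = as.integer(seed)),
            class = "apr_ensemble")
}

# ---- hyperparameter search --------------------------------------------------

#' Search the hyperparameter grid
#'
#' Evaluates candidate configurations from the optimization grid (layer
#' counts, dropout grid, power-of-two widths, batch size, learning-rate
#' decades) by cross-validated mean validation AuROCC and returns them
#' ranked.  `strategy = "grid"` walks a deterministic enumeration of the
#' grid (one shared width per configuration); `strategy = "random"` samples
#' configurations -- including independent per-layer widths -- under
#' `seed`.  `budget` caps how many configurations are trained.
#'
#' @param data A data frame with columns `sequence` and `label`.
#' @param budget Number of configurations to evaluate (>= 1).
#' @param strategy `"random"` or `"grid"`.
#' @param configs Optional explicit list of [network_config()]s to evaluate
#'   instead of drawing from the grid.
#' @param k,seed,table,max_epochs,patience,min_delta,standardize Passed to
#'   [train_crossval()]; `max_epochs` defaults lower (30) because the
#'   search compares configurations, not final models.
#' @return A tibble with one row per configuration, columns `rank`,
#'   `mean_val_auc` and a `config` list-column, sorted by decreasing score.
#' @export
hyperparameter_search <- function(data, budget = 5L,
                                  strategy = c("random", "grid"),
                                  configs = NULL, k = 5L, seed = 1L,
                                  table = default_feature_table(),
                                  max_epochs = 30L, patience = 5L,
                                  min_delta = 0.001, standardize = TRUE) {
  strategy <- match.arg(strategy)
  if (is.null(configs)) {
    if (budget < 1) stop_input("budget must be >= 1")
    configs <- draw_search_space(budget, strategy, seed)
  }
  if (length(configs) == 0) stop_input("empty search space")
  scores <- vapply(seq_along(configs), function(i) {
    ens <- train_crossval(data, config = configs[[i]], k = k,
                          seed = (as.integer(seed) + i) %% 2147483629L,
                          table = table, max_epochs = max_epochs,
                          patience = patience, min_delta = min_delta,
                          standardize = standardize)
    mean(ens$fold_val_auc)
  }, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  tibble(rank = seq_along(ord), mean_val_auc = scores[ord],
         config = configs[ord])
}

# Candidate configurations from the optimization grid.
draw_search_space <- function(budget, strategy, seed) {
  widths <- 2^(3:9)  # 8 .. 512
  if (strategy == "grid") {
    full <- expand.grid(nb = 1:2, nd = 1:3, dropout = c(0, 0.2, 0.4, 0.6, 0.8),
                        width = widths, batch = c(16L, 32L),
                        lr = 10^(-(4:1)), KEEP.OUT.ATTRS = FALSE)
    full <- full[seq_len(min(budget, nrow(full))), , drop = FALSE]
    lapply(seq_len(nrow(full)), function(i) {
      r <- full[i, ]
      network_config(r$nb, r$nd, r$dropout,
                     rep(r$width, 1 + r$nb + (r$nd - 1)), r$batch, r$lr)
    })
  } else {
    with_run_seed(seed, {
      lapply(seq_len(budget), function(i) {
        nb <- sample(1:2, 1)
        nd <- sample(1:3, 1)
        n_widths <- 1 + nb + (nd - 1)
        network_config(nb, nd, sample(c(0, 0.2, 0.4, 0.6, 0.8), 1),
                       sample(widths, n_widths, replace = TRUE),
                       sample(c(16L, 32L), 1), sample(10^(-(4:1)), 1))
      })
    })
  }
}
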