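#' Network configuration
#'
#' Hyperparameters of one hexapeptide classifier, restricted to the search
#' grid used to optimize the published architecture: 1-2 bidirectional
#' recurrent layers, 1-3 dense layers, dropout on a 0.2 grid in `[0, 0.8]`,
#' layer widths in `[8, 512]`, batch size 16 or 32, and learning rate on the
#' decade grid `1e-4 .. 1e-1`.
#'
#' `neurons_per_layer` gives output widths for, in order: the per-residue
#' input projection, each bidirectional layer (total width across the two
#' directions, hence even), and each dense layer except the final 1-unit
#' output.  Its length must equal
#' `1 + n_bidirectional_layers + (n_dense_layers - 1)`.
#'
#' The default is the published top-performing architecture: projection
#' 36 -> 64 per residue, two bidirectional LSTM layers of output widths 64
#' (returning sequences) and 96 (returning final states), then dense layers
#' 96 -> 32 -> 32 -> 1 with dropout after the two hidden dense layers --
#' eight layers in total.
#'
#' @param n_bidirectional_layers 1 or 2.
#' @param n_dense_layers 1, 2 or 3.
#' @param dropout Dropout rate for the hidden dense layers.
#' @param neurons_per_layer Integer vector of layer output widths (see
#'   Details).
#' @param batch_size 16 or 32.
#' @param learning_rate 1e-4, 1e-3, 1e-2 or 1e-1.
#' @return A validated `network_config` list.
#' @examples
#' cfg <- network_config()
#' cfg$neurons_per_layer
#' @export
network_config <- function(n_bidirectional_layers = 2L,
                           n_dense_layers = 3L,
                           dropout = 0.2,
                           neurons_per_layer = c(64L, 64L, 96L, 32L, 32L),
                           batch_size = 32L,
                           learning_rate = 1e-3) {
  nb <- as.integer(n_bidirectional_layers)
  nd <- as.integer(n_dense_layers)
  if (!nb %in% 1:2) {
    stop_input("n_bidirectional_layers must be 1 or 2, got %s", nb)
  }
  if (!nd %in% 1:3) {
    stop_input("n_dense_layers must be 1, 2 or 3, got %s", nd)
  }
  grid <- c(0, 0.2, 0.4, 0.6, 0.8)
  if (!is.numeric(dropout) || min(abs(dropout - grid)) > 1e-9) {
    stop_input("dropout must be on the 0.2 grid in [0, 0.8], got %s", dropout)
  }
  npl <- as.integer(neurons_per_layer)
  want <- 1L + nb + (nd - 1L)
  if (length(npl) != want) {
    stop_input("neurons_per_layer must have %d entries (projection + %d recurrent + %d hidden dense), got %d",
               want, nb, nd - 1L, length(npl))
  }
  if (any(npl < 8L | npl > 512L)) {
    stop_input("neurons_per_layer entries must lie in [8, 512]")
  }
  rec <- npl[1L + seq_len(nb)]
  if (any(rec %% 2L != 0L)) {
    stop_input("bidirectional layer widths must be even (two concatenated directions)")
  }
  if (!batch_size %in% c(16L, 32L)) {
    stop_input("batch_size must be 16 or 32, got %s", batch_size)
  }
  lr_grid <- 10^(-(1:4))
  if (!is.numeric(learning_rate) ||
      min(abs(log10(learning_rate) - log10(lr_grid))) > 1e-9) {
    stop_input("learning_rate must be one of 1e-4, 1e-3, 1e-2, 1e-1, got %s",
               learning_rate)
  }
  structure(list(n_bidirectional_layers = nb, n_dense_layers = nd,
                 dropout = as.numeric(dropout), neurons_per_layer = npl,
                 batch_size = as.integer(batch_size),
                 learning_rate = as.numeric(learning_rate)),
            class = "network_config")
}

# Layer-width bookkeeping shared by init/forward/backward.
config_dims <- function(config) {
  npl <- config$neurons_per_layer
  nb <- config$n_bidirectional_layers
  nd <- config$n_dense_layers
  proj <- npl[1]
  rec <- npl[1L + seq_len(nb)]
  dense_hidden <- if (nd > 1) npl[(1L + nb) + seq_len(nd - 1L)] else integer(0)
  rec_in <- c(proj, head(rec, -1))
  dense_in <- c(tail(rec, 1), dense_hidden)
  dense_out <- c(dense_hidden, 1L)
  list(proj = proj, rec = rec, rec_in = rec_in, hidden = rec %/% 2L,
       dense_in = dense_in, dense_out = dense_out)
}

#' Build an untrained network
#'
#' Instantiates the weights of a [network_config()] with Glorot-uniform
#' initialization (LSTM forget-gate biases start at 1), deterministically
#' under `seed`.  The forward pass maps a 6 x 36 encoded window to a single
#' sigmoid score in `[0, 1]`.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An `apr_network` object.
#' @examples
#' net <- build_network(network_config(), seed = 1)
#' n_layers(net)
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  d <- config_dims(config)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  lstm_par <- function(nin, h) {
    b <- rep(0, 4 * h)
    b[(h + 1):(2 * h)] <- 1  # forget gate opens by default
    list(Wx = glorot(nin, 4 * h), Wh = glorot(h, 4 * h), b = b)
  }
  w <- NULL
  with_run_seed(seed, {
    w <- list(
      proj = list(W = glorot(N_FEATURES, d$proj), b = rep(0, d$proj)),
      rnn = lapply(seq_along(d$rec), function(l) {
        list(fwd = lstm_par(d$rec_in[l], d$hidden[l]),
             bwd = lstm_par(d$rec_in[l], d$hidden[l]))
      }),
      dense = lapply(seq_along(d$dense_in), function(k) {
        list(W = glorot(d$dense_in[k], d$dense_out[k]),
             b = rep(0, d$dense_out[k]))
      }))
  })
  structure(list(config = config, weights = w, seed = as.integer(seed),
                 scaler = NULL, stopping_epoch = NA_integer_,
                 history = NULL,
                 wiring = paste("last bidirectional layer returns the final",
                                "state of each direction, concatenated;",
                                "earlier ones return full sequences")),
            class = "apr_network")
}

#' @rdname build_network
#' @param net An `apr_network`.
#' @return `n_layers()` counts layers the way the architecture is described:
#'   input projection, each bidirectional layer, each hidden dense layer
#'   together with its dropout, and the output layer (8 for the published
#'   configuration).
#' @export
n_layers <- function(net) {
  stopifnot(inherits(net, "apr_network"))
  cfg <- net$config
  1L + cfg$n_bidirectional_layers + 2L * (cfg$n_dense_layers - 1L) + 1L
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM direction over a list of T input matrices (B x nin each).
# Returns per-step hidden states and the caches the backward pass needs.
lstm_forward <- function(xs, par, cache = FALSE) {
  T_ <- length(xs)
  B <- nrow(xs[[1]])
  H <- length(par$b) / 4
  h <- matrix(0, B, H)
  c_ <- matrix(0, B, H)
  hs <- vector("list", T_)
  caches <- if (cache) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    z <- xs[[t]] %*% par$Wx + h %*% par$Wh +
      matrix(par$b, B, 4 * H, byrow = TRUE)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, H + 1:H, drop = FALSE])
    g <- tanh(z[, 2 * H + 1:H, drop = FALSE])
    o <- sigmoid(z[, 3 * H + 1:H, drop = FALSE])
    c_prev <- c_
    c_ <- f * c_prev + i * g
    tc <- tanh(c_)
    h_prev <- h
    h <- o * tc
    hs[[t]] <- h
    if (cache) {
      caches[[t]] <- list(x = xs[[t]], i = i, f = f, g = g, o = o,
                          c = c_, c_prev = c_prev, tc = tc, h_prev = h_prev)
    }
  }
  list(hs = hs, caches = caches)
}

# Full forward pass on an n x 6 x 36 array (already standardized if the
# network carries a scaler -- callers go through predict_batch()).
network_forward <- function(net, x, training = FALSE, cache = FALSE) {
  cfg <- net$config
  w <- net$weights
  d <- config_dims(cfg)
  B <- dim(x)[1]
  T_ <- dim(x)[2]
  keep <- 1 - if (training) cfg$dropout else 0
  xs <- lapply(seq_len(T_), function(t) {
    matrix(x[, t, ], nrow = B, ncol = dim(x)[3])
  })
  proj <- lapply(xs, function(m) {
    m %*% w$proj$W + matrix(w$proj$b, B, d$proj, byrow = TRUE)
  })
  seq_in <- proj
  rnn_caches <- vector("list", length(w$rnn))
  out_vec <- NULL
  nb <- length(w$rnn)
  for (l in seq_len(nb)) {
    fw <- lstm_forward(seq_in, w$rnn[[l]]$fwd, cache = cache)
    bw <- lstm_forward(rev(seq_in), w$rnn[[l]]$bwd, cache = cache)
    rnn_caches[[l]] <- list(fwd = fw, bwd = bw, x = seq_in)
    if (l < nb) {
      seq_in <- lapply(seq_len(T_), function(t) {
        cbind(fw$hs[[t]], bw$hs[[T_ - t + 1]])
      })
    } else {
      out_vec <- cbind(fw$hs[[T_]], bw$hs[[T_]])
    }
  }
  a <- out_vec
  dense_caches <- vector("list", length(w$dense))
  nd <- length(w$dense)
  for (k in seq_len(nd)) {
    z <- a %*% w$dense[[k]]$W +
      matrix(w$dense[[k]]$b, B, ncol(w$dense[[k]]$W), byrow = TRUE)
    if (k < nd) {
      act <- pmax(z, 0)
      mask <- NULL
      if (training && keep < 1) {
        mask <- matrix((runif(length(act)) < keep) / keep,
                       nrow(act), ncol(act))
        act <- act * mask
      }
      dense_caches[[k]] <- list(input = a, z = z, mask = mask)
      a <- act
    } else {
      dense_caches[[k]] <- list(input = a, z = z)
      a <- sigmoid(z)
    }
  }
  scores <- as.numeric(a)
  if (!cache) return(scores)
  list(scores = scores, proj_in = xs, proj = proj, rnn = rnn_caches,
       dense = dense_caches)
}

# Score a batch of encoded windows with one network (inference mode;
# dropout inactive).  Applies the network's feature scaler if present.
predict_batch <- function(net, x) {
  if (is.matrix(x)) x <- array(x, dim = c(1, dim(x)))
  if (length(dim(x)) != 3 || dim(x)[2] != WINDOW_SIZE ||
      dim(x)[3] != N_FEATURES) {
    stop_input("input must be a 6 x %d window or an n x 6 x %d array",
               N_FEATURES, N_FEATURES)
  }
  x <- apply_scaler(x, net$scaler)
  network_forward(net, x, training = FALSE, cache = FALSE)
}

#' Score encoded windows with a single network
#'
#' Inference-mode forward pass (dropout inactive): one score in `[0, 1]`
#' per window.
#'
#' @param net An [apr_network][build_network].
#' @param window A 6 x 36 encoded window ([encode_hexapeptide()]) or an
#'   n x 6 x 36 array.
#' @return A numeric vector of scores in `[0, 1]`.
#' @export
predict_window <- function(net, window) {
  stopifnot(inherits(net, "apr_network"))
  predict_batch(net, window)
}

#' @export
print.apr_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<apr_network> %d-layer bidirectional LSTM classifier\n",
              n_layers(x)))
  cat(sprintf("  widths: %s | dropout %.1f | lr %g | batch %d\n",
              paste(cfg$neurons_per_layer, collapse = "-"), cfg$dropout,
              cfg$learning_rate, cfg$batch_size))
  if (!is.na(x$stopping_epoch)) {
    cat(sprintf("  trained; stopping epoch %d\n", x$stopping_epoch))
  } else {
    cat("  untrained (freshly initialized)\n")
  }
  invisible(x)
}

#' @export
tidy.apr_network <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(0), train_auc = numeric(0),
                  val_auc = numeric(0)))
  }
  as_tibble(x$history)
}

#' @export
glance.apr_network <- function(x, ...) {
  tibble(n_layers = n_layers(x),
         n_parameters = sum(rapply(x$weights, length, how = "unlist")),
         stopping_epoch = x$stopping_epoch,
         best_val_auc = if (is.null(x$history)) NA_real_
                        else max(x$history$val_auc),
         dropout = x$config$dropout,
         learning_rate = x$config$learning_rate)
}
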