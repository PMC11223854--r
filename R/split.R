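#' Stratified train/test split
#'
#' Splits indices into train and test keeping the class ratio: for each
#' class, `round(fraction * n_class)` items (round-half-even, R's `round()`)
#' go to train and the remainder to test.  Deterministic under `seed`.
#'
#' @param labels Binary (0/1 or logical) label vector.
#' @param fraction Train fraction in (0, 1); default 0.9.
#' @param seed Integer seed.
#' @return A `split_spec` list: `train_indices`, `test_indices`, `fraction`,
#'   `seed`, `stratified = TRUE`.
#' @examples
#' sp <- stratified_split(rep(c(1, 0), c(30, 70)), 0.9, seed = 1)
#' length(sp$train_indices)
#' @export
stratified_split <- function(labels, fraction = 0.9, seed = 1L) {
  labels <- as.numeric(as.logical(labels))
  if (length(labels) == 0) stop_input("labels must be nonempty")
  if (length(unique(labels)) < 2) {
    stop_input("stratified split needs both classes present")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_input("fraction must be strictly inside (0, 1)")
  }
  train <- integer(0)
  with_run_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(labels == cls)
      n_train <- as.integer(round(fraction * length(idx)))
      train <- c(train, sample(idx, n_train))
    }
  })
  train <- sort(train)
  structure(list(train_indices = train,
                 test_indices = setdiff(seq_along(labels), train),
                 fraction = fraction, seed = as.integer(seed),
                 stratified = TRUE),
            class = "split_spec")
}

#' Stratified k-fold assignment
#'
#' Assigns each index to one of `k` folds, stratified by label so per-class
#' fold sizes differ by at most one.  Deterministic under `seed`.
#'
#' @param labels Binary label vector (of the training split).
#' @param k Number of folds; default 5.
#' @param seed Integer seed.
#' @return A `fold_plan` list: `k`, `fold_assignments` (integer vector in
#'   `1..k`, one per index), `seed`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.numeric(as.logical(labels))
  if (length(unique(labels)) < 2) stop_input("folds need both classes present")
  counts <- table(labels)
  if (k > min(counts)) {
    stop_input("k = %d exceeds the minority class count (%d)", k, min(counts))
  }
  fold <- integer(length(labels))
  with_run_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(labels == cls)
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = as.integer(k), fold_assignments = fold,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Early-stopping epoch from a training history
#'
#' Operationalizes "stop where the training and validation ROC curves
#' diverge": walk the epochs, and once the validation AuROCC has failed to
#' improve by at least `min_delta` for `patience` consecutive epochs, stop
#' and return the epoch with the best validation AuROCC seen so far
#' (earliest epoch on ties).  If the run never stalls, the best epoch of
#' the whole history is returned.
#'
#' @param history A data frame with columns `train_auc` and `val_auc` (one
#'   row per epoch), or a numeric vector of validation AuROCC values.
#' @param patience Consecutive non-improving epochs tolerated; default 5.
#' @param min_delta Minimum validation-AuROCC improvement that resets the
#'   patience counter; default 0.001.
#' @return The selected epoch (1-based integer).
#' @examples
#' select_stopping_epoch(c(0.6, 0.7, 0.7, 0.69, 0.68), patience = 2,
#'                       min_delta = 0)
#' @export
select_stopping_epoch <- function(history, patience = 5L, min_delta = 0.001) {
  val <- if (is.data.frame(history)) history$val_auc else as.numeric(history)
  if (length(val) == 0) stop_input("history must be nonempty")
  best <- val[1]
  best_epoch <- 1L
  stall <- 0L
  for (e in seq_along(val)[-1]) {
    if (val[e] > best + min_delta) {
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (val[e] > best) {
      best <- val[e]
      best_epoch <- e
    }
    if (stall >= patience) break
  }
  best_epoch
}
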