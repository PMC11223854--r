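#' Assemble an ensemble from trained networks
#'
#' The predictor proper is an ensemble of five networks whose consensus
#' score is the arithmetic mean of the member scores.  Ensembles with a
#' member count other than five are refused unless `allow_any_members =
#' TRUE` (useful in reduced test settings; the deviation is logged).
#'
#' @param members List of trained [apr_network][build_network]s.
#' @param feature_table_id Identifier of the feature table the members were
#'   encoded with (see [train_crossval()], which fills this in).
#' @param threshold Default classification threshold (typically the
#'   Youden-J optimum computed on training data).
#' @param allow_any_members Permit a member count other than 5?
#' @return An `apr_ensemble` object.
#' @export
new_ensemble <- function(members, feature_table_id = NA_character_,
                         threshold = 0.5, allow_any_members = FALSE) {
  if (!all(vapply(members, inherits, logical(1), "apr_network"))) {
    stop_input("all ensemble members must be apr_network objects")
  }
  if (length(members) != 5L) {
    if (!allow_any_members) {
      stop_input("an ensemble has exactly 5 members, got %d (set allow_any_members = TRUE to override)",
                 length(members))
    }
    inform(sprintf("note: building an ensemble with %d members instead of 5",
                   length(members)))
  }
  structure(list(members = members, config = members[[1]]$config,
                 feature_table_id = feature_table_id, aggregation = "mean",
                 threshold = threshold, youden_j = NA_real_,
                 oof_auc = NA_real_,
                 fold_val_auc = rep(NA_real_, length(members)),
                 folds = NULL, seed = NA_integer_),
            class = "apr_ensemble")
}

#' Ensemble consensus score
#'
#' Scores encoded windows with every member and averages: the consensus is
#' the arithmetic mean of the member scores, so it is invariant to member
#' order and stays in `[0, 1]`.
#'
#' @param ensemble An `apr_ensemble` ([train_crossval()], [new_ensemble()]).
#' @param window A 6 x 36 encoded window or an n x 6 x 36 array.
#' @return Numeric vector of consensus scores in `[0, 1]`.
#' @export
predict_ensemble <- function(ensemble, window) {
  stopifnot(inherits(ensemble, "apr_ensemble"))
  nw <- if (is.matrix(window)) 1L else dim(window)[1]
  member_scores <- vapply(ensemble$members,
                          function(m) predict_batch(m, window), numeric(nw))
  if (nw == 1L) member_scores <- matrix(member_scores, nrow = 1L)
  rowMeans(member_scores)
}

#' Classify hexapeptides with a trained ensemble
#'
#' Data-frame-in, tibble-out scoring: adds consensus scores (and calls at
#' the ensemble's stored threshold) to a table of hexapeptides.
#'
#' @param object An `apr_ensemble`.
#' @param new_data Data frame with a `sequence` column of hexapeptides.
#' @param table Feature table matching the one used at training.
#' @param threshold Classification threshold; defaults to the ensemble's
#'   stored Youden-J threshold.
#' @param ... Unused.
#' @return `new_data` as a tibble with `score` and `predicted_label`
#'   columns appended.
#' @export
predict.apr_ensemble <- function(object, new_data,
                                 table = default_feature_table(),
                                 threshold = NULL, ...) {
  threshold <- threshold %||% object$threshold
  enc <- encode_dataset(new_data, table, require_labels = FALSE)
  scores <- predict_ensemble(object, enc$x)
  dplyr::mutate(as_tibble(new_data), score = scores,
                predicted_label = as.integer(scores >= threshold))
}

#' @export
print.apr_ensemble <- function(x, ...) {
  cat(sprintf("<apr_ensemble> %d members, consensus by %s\n",
              length(x$members), x$aggregation))
  cat(sprintf("  default threshold %.4f (Youden J = %.3f), out-of-fold AuROCC %.3f\n",
              x$threshold, x$youden_j, x$oof_auc))
  invisible(x)
}

#' @export
tidy.apr_ensemble <- function(x, ...) {
  tibble(member = seq_along(x$members),
         stopping_epoch = vapply(x$members, `[[`, integer(1), "stopping_epoch"),
         val_auc = x$fold_val_auc)
}

#' @export
glance.apr_ensemble <- function(x, ...) {
  tibble(n_members = length(x$members),
         oof_auc = x$oof_auc, youden_j = x$youden_j,
         threshold = x$threshold,
         mean_val_auc = mean(x$fold_val_auc))
}

# ---- persistence ------------------------------------------------------------

MODEL_FORMAT_VERSION <- "1.0"

#' Save / load models
#'
#' An ensemble is persisted as a directory: a `manifest.json` recording the
#' format version, configuration, seeds, stopping epochs, wiring note,
#' default threshold and feature-table identifier, plus one weight file per
#' member (`member_1.rds` ...).  A single network saves the same way with
#' one member.  `load_model(save_model(m))` reproduces scores
#' bit-identically.
#'
#' @param model An `apr_ensemble` or `apr_network`.
#' @param path Directory to write to / read from.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored model.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  single <- inherits(model, "apr_network")
  members <- if (single) list(model) else model$members
  manifest <- list(
    format_version = MODEL_FORMAT_VERSION,
    type = if (single) "network" else "ensemble",
    n_members = length(members),
    config = unclass(if (single) model$config else model$config),
    aggregation = if (single) NULL else model$aggregation,
    threshold = if (single) NULL else model$threshold,
    youden_j = if (single) NULL else model$youden_j,
    oof_auc = if (single) NULL else model$oof_auc,
    feature_table_id = if (single) NULL else model$feature_table_id,
    seed = if (single) model$seed else model$seed,
    stopping_epochs = vapply(members, `[[`, integer(1), "stopping_epoch"),
    wiring = members[[1]]$wiring)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (i in seq_along(members)) {
    saveRDS(members[[i]], file.path(path, sprintf("member_%d.rds", i)))
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_input("no manifest.json under %s", path)
  manifest <- tryCatch(jsonlite::read_json(mf),
                       error = function(e) stop_input(
                         "corrupted manifest in %s: %s", path,
                         conditionMessage(e)))
  if (!identical(manifest$format_version, MODEL_FORMAT_VERSION)) {
    stop_input("model format version mismatch: file has %s, package reads %s",
               manifest$format_version %||% "<none>", MODEL_FORMAT_VERSION)
  }
  n <- manifest$n_members
  members <- lapply(seq_len(n), function(i) {
    f <- file.path(path, sprintf("member_%d.rds", i))
    if (!file.exists(f)) stop_input("missing member weight file: %s", f)
    m <- tryCatch(readRDS(f),
                  error = function(e) stop_input(
                    "corrupted member weight file %s: %s", f,
                    conditionMessage(e)))
    if (!inherits(m, "apr_network")) {
      stop_input("corrupted member weight file %s: not a network", f)
    }
    m
  })
  if (identical(manifest$type, "network")) return(members[[1]])
  ens <- new_ensemble(members,
                      feature_table_id = manifest$feature_table_id %||%
                        NA_character_,
                      threshold = manifest$threshold %||% 0.5,
                      allow_any_members = n != 5L)
  ens$youden_j <- manifest$youden_j %||% NA_real_
  ens$oof_auc <- manifest$oof_auc %||% NA_real_
  ens$seed <- manifest$seed %||% NA_integer_
  ens
}
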