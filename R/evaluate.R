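#' Benchmark profiles against APR annotations
#'
#' Whole-protein evaluation: each annotated protein is profiled (or its
#' precomputed profile supplied), per-residue scores are compared with the
#' union of the annotated APR intervals, and four statistics are computed
#' per protein -- AuROCC, AuPRC, and the Segment OVerlap scores of the APR
#' and non-APR segmentations of the thresholded prediction.  Dataset-level
#' numbers are macro-averages over proteins; per-protein statistics that
#' are undefined (e.g. a protein whose residues are all one class) are
#' `NA` and excluded from the average.
#'
#' @param annotations A tibble with `id`, `sequence`, `aprs` columns
#'   ([read_annotations()], [gen_annotated_proteins()]).
#' @param ensemble An `apr_ensemble` used to profile each sequence; omit it
#'   and pass `profiles` to evaluate precomputed profiles.
#' @param profiles Optional named list (by protein id) of
#'   [residue_profile][profile_sequence]s.
#' @param threshold Classification threshold for APR calling; default: the
#'   ensemble's stored Youden-J threshold (0.5 for precomputed profiles
#'   without one).
#' @param min_length Minimum APR length; default 6.
#' @param table Feature table (when profiling with an ensemble).
#' @return An `apr_evaluation` tibble: one row per protein with columns
#'   `id`, `auroc`, `auprc`, `sov_apr`, `sov_non_apr`; macro-averages are
#'   available through [glance()].
#' @export
evaluate_proteins <- function(annotations, ensemble = NULL, profiles = NULL,
                              threshold = NULL, min_length = 6L,
                              table = default_feature_table()) {
  if (is.null(ensemble) && is.null(profiles)) {
    stop_input("supply either an ensemble or precomputed profiles")
  }
  threshold <- threshold %||%
    (if (!is.null(ensemble)) ensemble$threshold else 0.5)
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    id <- annotations$id[i]
    seq_i <- annotations$sequence[i]
    prof <- if (!is.null(profiles)) {
      profiles[[id]] %||% stop_input("no profile supplied for protein %s", id)
    } else {
      profile_sequence(ensemble, seq_i, table = table, sequence_id = id)
    }
    truth <- intervals_to_labels(annotations$aprs[[i]], nchar(seq_i))
    calls <- call_aprs(prof, threshold, min_length)
    pred <- intervals_to_labels(calls, nchar(seq_i))
    auroc <- if (length(unique(truth)) < 2) NA_real_ else
      attr(roc_curve(prof$score, truth), "auc")
    auprc <- if (sum(truth) == 0) NA_real_ else
      attr(pr_curve(prof$score, truth), "auc")
    tibble(id = id, auroc = auroc, auprc = auprc,
           sov_apr = sov(pred, truth, "apr"),
           sov_non_apr = sov(pred, truth, "non_apr"))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("apr_evaluation", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' @export
glance.apr_evaluation <- function(x, ...) {
  tibble(n_proteins = nrow(x),
         auroc = mean(x$auroc, na.rm = TRUE),
         auprc = mean(x$auprc, na.rm = TRUE),
         sov_apr = mean(x$sov_apr, na.rm = TRUE),
         sov_non_apr = mean(x$sov_non_apr, na.rm = TRUE),
         threshold = attr(x, "threshold"))
}

#' Write an evaluation report
#'
#' Writes the per-protein table and the macro-averaged summary as CSV or
#' JSON.
#'
#' @param evaluation An [evaluate_proteins()] result.
#' @param path Output path.
#' @param format `"csv"` (per-protein rows, then a `macro_average` row) or
#'   `"json"` (object with `per_protein` and `macro_average`).
#' @export
write_evaluation_report <- function(evaluation, path,
                                    format = c("csv", "json")) {
  format <- match.arg(format)
  macro <- glance(evaluation)
  if (format == "csv") {
    per <- dplyr::mutate(as_tibble(evaluation), row_type = "protein")
    avg <- tibble(id = "macro_average", auroc = macro$auroc,
                  auprc = macro$auprc, sov_apr = macro$sov_apr,
                  sov_non_apr = macro$sov_non_apr, row_type = "macro_average")
    readr::write_csv(dplyr::bind_rows(per, avg), path)
  } else {
    jsonlite::write_json(
      list(per_protein = as_tibble(evaluation), macro_average = macro),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
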