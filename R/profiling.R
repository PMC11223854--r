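#' Fragment a sequence into overlapping hexapeptide windows
#'
#' Slides a six-residue window one position at a time: a length-`L`
#' sequence yields exactly `L - 5` windows, window `j` spanning residues
#' `j .. j + 5` (1-based inclusive).
#'
#' @param sequence Protein sequence (length >= 6, canonical alphabet).
#' @return A tibble with columns `start` and `sequence` (the hexapeptide).
#' @examples
#' sequence_to_windows("ACDEFGHI")
#' @export
sequence_to_windows <- function(sequence) {
  sequence <- check_sequence(sequence)
  L <- nchar(sequence)
  if (L < WINDOW_SIZE) {
    stop_input("sequence must have at least %d residues, got %d",
               WINDOW_SIZE, L)
  }
  starts <- seq_len(L - WINDOW_SIZE + 1L)
  tibble(start = starts,
         sequence = substring(sequence, starts, starts + WINDOW_SIZE - 1L))
}

#' Average window scores to per-residue scores
#'
#' Mirrors the windowing: residue `i` is covered by windows
#' `max(1, i - 5) .. min(i, L - 5)`, and its score is the plain mean of the
#' scores of those windows.  Terminal residues are averaged over their
#' reduced coverage (no padding or imputation).
#'
#' @param window_scores Numeric vector of `L - 5` per-window scores in
#'   `[0, 1]`.
#' @param length Sequence length `L`.
#' @return A list with `scores` (length `L`) and `coverage` (number of
#'   windows covering each residue, between 1 and 6).
#' @examples
#' aggregate_per_residue(c(0, 1), length = 7)$scores
#' @export
aggregate_per_residue <- function(window_scores, length) {
  L <- as.integer(length)
  nw <- L - WINDOW_SIZE + 1L
  if (base::length(window_scores) != nw) {
    stop_input("expected %d window scores for a length-%d sequence, got %d",
               nw, L, base::length(window_scores))
  }
  if (any(window_scores < 0 | window_scores > 1)) {
    stop_input("window scores must lie in [0, 1]")
  }
  scores <- numeric(L)
  coverage <- integer(L)
  for (i in seq_len(L)) {
    lo <- max(1L, i - WINDOW_SIZE + 1L)
    hi <- min(i, nw)
    scores[i] <- mean(window_scores[lo:hi])
    coverage[i] <- hi - lo + 1L
  }
  list(scores = scores, coverage = coverage)
}

#' Per-residue aggregation profile of a protein
#'
#' The whole-sequence pipeline: fragment into overlapping hexapeptides,
#' score every window with the ensemble consensus, and average window
#' scores per residue.
#'
#' @param ensemble An `apr_ensemble`.
#' @param sequence Protein sequence (length >= 6).
#' @param table Feature table matching the one used at training.
#' @param sequence_id Identifier carried into the output.
#' @param aux_channels Optional named list of extra per-residue numeric
#'   vectors (length `L`), e.g. externally computed transmembrane
#'   propensity or relative solvent accessibility; they are attached as
#'   columns, never computed here.
#' @return A `residue_profile`: a tibble with columns `sequence_id`,
#'   `position`, `residue`, `score`, `coverage` (plus any aux channels);
#'   the ensemble's default threshold is carried in attribute
#'   `"threshold"`.
#' @export
profile_sequence <- function(ensemble, sequence,
                             table = default_feature_table(),
                             sequence_id = "seq1", aux_channels = NULL) {
  stopifnot(inherits(ensemble, "apr_ensemble"))
  sequence <- check_sequence(sequence)
  windows <- sequence_to_windows(sequence)
  enc <- encode_dataset(windows, table, require_labels = FALSE)
  wscores <- predict_ensemble(ensemble, enc$x)
  L <- nchar(sequence)
  agg <- aggregate_per_residue(wscores, L)
  out <- tibble(sequence_id = sequence_id, position = seq_len(L),
                residue = chars(sequence), score = agg$scores,
                coverage = agg$coverage)
  if (!is.null(aux_channels)) {
    for (nm in names(aux_channels)) {
      ch <- aux_channels[[nm]]
      if (base::length(ch) != L) {
        stop_input("aux channel '%s' has length %d, sequence has %d residues",
                   nm, base::length(ch), L)
      }
      out[[nm]] <- as.numeric(ch)
    }
  }
  class(out) <- c("residue_profile", class(out))
  attr(out, "threshold") <- ensemble$threshold
  out
}

#' Call aggregation-prone regions from a profile
#'
#' An APR is a maximal run of consecutive residues with score at or above
#' the threshold, kept only if it spans at least `min_length` residues
#' (default 6: shorter above-threshold peaks are not APRs).  Calls are
#' disjoint and sorted by start.
#'
#' @param profile A [residue_profile][profile_sequence], or any data frame
#'   with `sequence_id`, `position` and `score` columns.
#' @param threshold Score cut-off in `[0, 1]`; defaults to the profile's
#'   stored threshold (the ensemble's Youden-J value).
#' @param min_length Minimum APR length; default 6.
#' @return A tibble with columns `sequence_id`, `start`, `end`, `length`,
#'   `mean_score`, `max_score` (1-based inclusive coordinates).
#' @export
call_aprs <- function(profile, threshold = NULL, min_length = 6L) {
  threshold <- threshold %||% attr(profile, "threshold") %||% 0.5
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop_input("threshold must lie in [0, 1]")
  }
  stopifnot(all(c("sequence_id", "position", "score") %in% names(profile)))
  profile <- dplyr::arrange(as_tibble(profile), sequence_id, position)
  out <- lapply(split(profile, profile$sequence_id), function(p) {
    runs <- segment_runs(p$score >= threshold)
    if (nrow(runs) == 0) return(NULL)
    runs <- runs[runs$end - runs$start + 1L >= min_length, , drop = FALSE]
    if (nrow(runs) == 0) return(NULL)
    tibble(sequence_id = p$sequence_id[1],
           start = p$position[runs$start], end = p$position[runs$end],
           length = runs$end - runs$start + 1L,
           mean_score = vapply(seq_len(nrow(runs)), function(r) {
             mean(p$score[runs$start[r]:runs$end[r]])
           }, numeric(1)),
           max_score = vapply(seq_len(nrow(runs)), function(r) {
             max(p$score[runs$start[r]:runs$end[r]])
           }, numeric(1)))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble(sequence_id = character(0), start = integer(0),
                  end = integer(0), length = integer(0),
                  mean_score = numeric(0), max_score = numeric(0))
  }
  dplyr::arrange(out, sequence_id, start)
}

#' Per-residue binary APR labels from interval annotations
#'
#' Utility converting 1-based inclusive `[start, end]` intervals (calls or
#' reference annotations; overlapping intervals are unioned) into a 0/1
#' per-residue vector of the given length.
#'
#' @param intervals Data frame with `start` and `end` columns (may be
#'   empty), or a list of `c(start, end)` pairs.
#' @param length Sequence length.
#' @return Integer 0/1 vector of `length`.
#' @export
intervals_to_labels <- function(intervals, length) {
  lab <- integer(length)
  if (is.data.frame(intervals)) {
    pairs <- Map(c, intervals$start, intervals$end)
  } else {
    pairs <- intervals
  }
  for (p in pairs) {
    s <- max(1L, as.integer(p[1]))
    e <- min(length, as.integer(p[2]))
    if (s <= e) lab[s:e] <- 1L
  }
  lab
}
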