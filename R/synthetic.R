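# Residue sampling weights for the synthetic world.  Positives are biased
# toward hydrophobic / beta-prone residues, negatives toward charged,
# proline-rich and polar ones, so class is a (learnable) function of
# composition rather than of any exact motif.
SYNTH_POSITIVE_WEIGHTS <- c(
  I = 5, V = 5, F = 4, L = 4, Y = 3, W = 2, M = 2, A = 2, T = 1, C = 1,
  G = 0.5, S = 0.5, N = 0.2, Q = 0.2, H = 0.2, D = 0.1, E = 0.1, K = 0.1,
  R = 0.1, P = 0.1)
SYNTH_NEGATIVE_WEIGHTS <- c(
  D = 4, E = 4, K = 4, R = 3, P = 3, G = 2, S = 2, N = 2, Q = 2, H = 1,
  T = 1, A = 0.5, Y = 0.3, M = 0.2, C = 0.2, L = 0.2, V = 0.2, I = 0.1,
  F = 0.1, W = 0.1)

# Kyte-Doolittle hydropathy: the composition oracle that makes the
# generating rule recoverable without training anything.
KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7,
                   V = 4.2, W = -0.9, Y = -1.3)

sample_peptide <- function(n_res, weights) {
  paste(sample(names(weights), n_res, replace = TRUE,
               prob = weights / sum(weights)), collapse = "")
}

#' Generate a labelled synthetic hexapeptide dataset
#'
#' Emulates an experimentally labelled hexapeptide collection with a known
#' separable rule: positives are drawn from a hydrophobic/beta-prone
#' residue composition, negatives from a charged/proline-rich one, and
#' labels are then flipped with probability `noise`.  Exactly
#' `round(positive_fraction * n)` sequences are positive before noise;
#' sequences are distinct; generation is deterministic under `seed`.  At
#' `noise = 0` the mean Kyte-Doolittle hydropathy of the hexapeptide
#' ([hydropathy_score()]) separates the classes with AuROCC >= 0.9, so the
#' rule is recoverable without any trained model.
#'
#' @param n Number of hexapeptides.
#' @param positive_fraction Fraction of amyloid-prone (label 1) sequences,
#'   strictly inside (0, 1).
#' @param noise Label-flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A tibble with columns `sequence`, `label` (after noise) and
#'   `label_pre_noise`.
#' @examples
#' gen_hexapeptides(10, 0.3, seed = 1)
#' @export
gen_hexapeptides <- function(n, positive_fraction = 0.36, noise = 0,
                             seed = 1L) {
  if (!is.numeric(positive_fraction) || positive_fraction <= 0 ||
      positive_fraction >= 1) {
    stop_input("positive_fraction must be strictly inside (0, 1)")
  }
  if (!is.numeric(noise) || noise < 0 || noise >= 0.5) {
    stop_input("noise must lie in [0, 0.5)")
  }
  n_pos <- as.integer(round(positive_fraction * n))
  labels <- rep(c(1L, 0L), c(n_pos, n - n_pos))
  seqs <- character(n)
  with_run_seed(seed, {
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      w <- if (labels[i] == 1L) SYNTH_POSITIVE_WEIGHTS else SYNTH_NEGATIVE_WEIGHTS
      repeat {
        s <- sample_peptide(WINDOW_SIZE, w)
        if (is.null(seen[[s]])) {
          seen[[s]] <- TRUE
          seqs[i] <- s
          break
        }
      }
    }
    flip <- runif(n) < noise
    observed <- ifelse(flip, 1L - labels, labels)
    ord <- sample.int(n)
    tibble(sequence = seqs[ord], label = observed[ord],
           label_pre_noise = labels[ord])
  })
}

#' @rdname gen_hexapeptides
#' @param sequences Character vector of peptide/protein sequences.
#' @return `hydropathy_score()` returns the mean Kyte-Doolittle hydropathy
#'   per sequence.
#' @export
hydropathy_score <- function(sequences) {
  vapply(sequences, function(s) mean(KD_HYDROPATHY[chars(toupper(s))]),
         numeric(1), USE.NAMES = FALSE)
}

#' Generate synthetic proteins with annotated APRs
#'
#' Emulates a benchmark of amyloid proteins with literature-annotated
#' aggregation-prone intervals: background sequence is drawn from the
#' negative (charged/polar) composition and 1 or more segments of positive
#' (hydrophobic) composition are embedded and recorded as the true APR
#' intervals (1-based inclusive).  APR lengths stay in `[6, apr_max_len]`
#' with `apr_max_len <= 50`, embedded segments never touch the first or
#' last six residues, and distinct APRs are separated by at least six
#' background residues.  Deterministic under `seed`.
#'
#' @param n Number of proteins.
#' @param length_range Protein length range (inclusive), default 90-160.
#' @param n_apr_range Range of APR counts per protein, default 1-3.
#' @param apr_length_range APR length range, default 8-20 (upper bound
#'   capped at 50).
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `sequence` and `aprs` (list-column
#'   of data frames with `start`, `end`).
#' @export
gen_annotated_proteins <- function(n = 10L, length_range = c(90L, 160L),
                                   n_apr_range = c(1L, 3L),
                                   apr_length_range = c(8L, 20L),
                                   seed = 1L) {
  stopifnot(length_range[1] >= 40, apr_length_range[1] >= WINDOW_SIZE)
  if (apr_length_range[2] > 50L) {
    stop_input("APR lengths above 50 residues are excluded; cap apr_length_range at 50")
  }
  if (apr_length_range[2] + 2L * WINDOW_SIZE >= length_range[1]) {
    stop_input("APR length range does not fit inside the shortest protein")
  }
  with_run_seed(seed, {
    entries <- lapply(seq_len(n), function(i) {
      L <- sample(length_range[1]:length_range[2], 1)
      seq_bg <- chars(sample_peptide(L, SYNTH_NEGATIVE_WEIGHTS))
      n_apr <- sample(n_apr_range[1]:n_apr_range[2], 1)
      placed <- data.frame(start = integer(0), end = integer(0))
      for (a in seq_len(n_apr)) {
        len <- sample(apr_length_range[1]:apr_length_range[2], 1)
        # keep clear of the termini and of previously placed APRs
        for (try in 1:200) {
          s <- sample((WINDOW_SIZE + 1L):(L - WINDOW_SIZE - len + 1L), 1)
          e <- s + len - 1L
          clash <- nrow(placed) > 0 &&
            any(pmax(placed$start - WINDOW_SIZE, 1) <= e &
                  (placed$end + WINDOW_SIZE) >= s)
          if (!clash) {
            placed <- rbind(placed, data.frame(start = s, end = e))
            seq_bg[s:e] <- chars(sample_peptide(len, SYNTH_POSITIVE_WEIGHTS))
            break
          }
        }
      }
      placed <- placed[order(placed$start), , drop = FALSE]
      rownames(placed) <- NULL
      list(id = sprintf("synthprot_%03d", i),
           sequence = paste(seq_bg, collapse = ""), aprs = placed)
    })
    tibble(id = vapply(entries, `[[`, character(1), "id"),
           sequence = vapply(entries, `[[`, character(1), "sequence"),
           aprs = lapply(entries, `[[`, "aprs"))
  })
}
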