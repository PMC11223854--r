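#' Segment OVerlap (SOV) score
#'
#' Segment-level agreement between a predicted and a reference binary
#' per-residue labelling, following the refined (1999) definition used for
#' secondary-structure assessment: for every pair of overlapping reference
#' and predicted segments of the target class, the score credits
#' `(minov + delta) / maxov`, weighted by the reference segment length,
#' where `minov` is the length of their intersection, `maxov` the length of
#' their union span, and the allowance `delta` is capped by
#' `maxov - minov`, `minov`, and half of either segment length.  Reference
#' segments with no overlapping prediction contribute only to the
#' normalizer.  The score is scaled to `[0, 100]`; 100 means the predicted
#' segmentation reproduces the reference exactly.
#'
#' The score is computed per class: `class = "apr"` scores the positive
#' (aggregation-prone) segments, `class = "non_apr"` the complementary
#' ones.  With no reference segment of the class, the score is 100 when the
#' prediction also has none and 0 otherwise.
#'
#' @param pred,truth Equal-length binary (0/1 or logical) per-residue
#'   vectors; 1 marks the residue as inside an APR.
#' @param class `"apr"` or `"non_apr"`: which class's segments to score.
#' @return A number in `[0, 100]`.
#' @examples
#' truth <- rep(c(0, 1, 0), c(9, 11, 10))
#' pred <- rep(c(0, 1, 0), c(14, 11, 5))
#' sov(pred, truth, "apr")
#' @export
sov <- function(pred, truth, class = c("apr", "non_apr")) {
  class <- match.arg(class)
  if (length(pred) != length(truth)) {
    stop_input("pred (%d) and truth (%d) differ in length",
               length(pred), length(truth))
  }
  target <- class == "apr"
  ref <- segment_runs(as.logical(truth) == target)
  prd <- segment_runs(as.logical(pred) == target)
  if (nrow(ref) == 0) return(if (nrow(prd) == 0) 100 else 0)
  total <- 0
  norm <- 0
  for (i in seq_len(nrow(ref))) {
    s1 <- ref[i, ]
    len1 <- s1$end - s1$start + 1L
    hit <- FALSE
    if (nrow(prd) > 0) {
      for (j in seq_len(nrow(prd))) {
        s2 <- prd[j, ]
        minov <- min(s1$end, s2$end) - max(s1$start, s2$start) + 1L
        if (minov <= 0) next
        hit <- TRUE
        len2 <- s2$end - s2$start + 1L
        maxov <- max(s1$end, s2$end) - min(s1$start, s2$start) + 1L
        delta <- min(maxov - minov, minov, floor(len1 / 2), floor(len2 / 2))
        total <- total + (minov + delta) / maxov * len1
        norm <- norm + len1
      }
    }
    if (!hit) norm <- norm + len1
  }
  100 * total / norm
}

#' @rdname sov
#' @return `sov_both()` returns a one-row tibble with `sov_apr` and
#'   `sov_non_apr`.
#' @export
sov_both <- function(pred, truth) {
  tibble(sov_apr = sov(pred, truth, "apr"),
         sov_non_apr = sov(pred, truth, "non_apr"))
}

# Maximal runs of TRUE as a data frame of 1-based inclusive [start, end].
segment_runs <- function(flag) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
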