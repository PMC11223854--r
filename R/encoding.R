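#' Encode hexapeptides as numeric windows
#'
#' A hexapeptide is encoded as a 6 x 36 matrix: row *i* is the feature-table
#' vector of residue *i*.  Flattened, this is the 216-value input the
#' networks consume.  Encoding is a pure lookup: identical inputs give
#' bit-identical outputs.
#'
#' @param sequence A length-6 string over the canonical amino-acid alphabet.
#' @param table A [feature_table][load_feature_table] (default: the shipped
#'   table).
#' @param origin Optional list `(sequence_id, start)` recording where the
#'   window came from in a parent sequence (1-based).
#' @return A 6 x 36 numeric matrix with residue rownames and feature
#'   colnames; `origin` is attached as an attribute when supplied.
#' @examples
#' w <- encode_hexapeptide("NFGAIL")
#' dim(w)
#' @export
encode_hexapeptide <- function(sequence, table = default_feature_table(),
                               origin = NULL) {
  sequence <- check_sequence(sequence, table$residues, "hexapeptide")
  if (nchar(sequence) != WINDOW_SIZE) {
    stop_input("hexapeptide must have exactly %d residues, got %d",
               WINDOW_SIZE, nchar(sequence))
  }
  m <- table$features[chars(sequence), , drop = FALSE]
  rownames(m) <- chars(sequence)
  if (!is.null(origin)) attr(m, "origin") <- origin
  m
}

#' Encode a labelled hexapeptide dataset
#'
#' Batch version of [encode_hexapeptide()]: order-preserving, so slice `k` of
#' the returned array equals the single-window encoding of row `k`.
#'
#' @param data A data frame with columns `sequence` (length-6 strings) and
#'   `label` (0/1; 1 = amyloid-prone).  Pass `require_labels = FALSE` to
#'   encode unlabelled sequences (e.g. profiling windows).
#' @param table A [feature_table][load_feature_table].
#' @param require_labels Error on missing labels? Default `TRUE`.
#' @return A list with `x` (an n x 6 x 36 array), `y` (numeric 0/1 vector,
#'   or `NULL`), and `sequences`.
#' @export
encode_dataset <- function(data, table = default_feature_table(),
                           require_labels = TRUE) {
  if (!is.data.frame(data) || !"sequence" %in% names(data)) {
    stop_input("`data` must be a data frame with a `sequence` column")
  }
  n <- nrow(data)
  y <- NULL
  if (require_labels) {
    if (!"label" %in% names(data)) {
      stop_input("`data` must have a `label` column (or set require_labels = FALSE)")
    }
    y <- data$label
    bad <- which(is.na(y) | !y %in% c(0, 1))
    if (length(bad) > 0) {
      stop_input("unlabelled or non-binary label at row %d", bad[1])
    }
    y <- as.numeric(y)
  }
  x <- array(NA_real_, dim = c(n, WINDOW_SIZE, N_FEATURES))
  for (k in seq_len(n)) {
    x[k, , ] <- encode_hexapeptide(data$sequence[k], table)
  }
  list(x = x, y = y, sequences = as.character(data$sequence))
}

# Per-feature standardization, fitted on training windows only.  Operates on
# the 36 feature channels pooled across all residue positions and samples.
fit_scaler <- function(x) {
  flat <- matrix(aperm(x, c(2, 1, 3)), ncol = dim(x)[3])
  center <- colMeans(flat)
  scale <- apply(flat, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  for (j in seq_len(dim(x)[3])) {
    x[, , j] <- (x[, , j] - scaler$center[j]) / scaler$scale[j]
  }
  x
}
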