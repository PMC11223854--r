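#' Per-residue feature tables
#'
#' The hexapeptide classifier encodes every residue as a fixed-length vector
#' of 36 numeric descriptors; a *feature table* maps each of the 20 canonical
#' amino acids to its descriptor vector.  The package ships a default table
#' (atomic composition counts plus physicochemical AAindex scales, see
#' `system.file("extdata", "aa_features.tsv", package = "aprscan")`), and any
#' 20 x 36 table can be plugged in via [load_feature_table()] or
#' [as_feature_table()].
#'
#' @param path Path to a delimited text file (TSV or CSV) with a header row
#'   of 36 feature names and 20 rows whose first column is the one-letter
#'   residue code.
#' @return A `feature_table` object: a list with elements `residues` (the 20
#'   one-letter codes), `features` (a 20 x 36 numeric matrix with residue
#'   rownames), `feature_names`, and `provenance`.
#' @examples
#' ft <- default_feature_table()
#' dim(ft$features)
#' @export
load_feature_table <- function(path) {
  if (!file.exists(path)) stop_input("feature table file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  as_feature_table(df, provenance = path)
}

#' @rdname load_feature_table
#' @param df A data frame: first column the residue code, remaining columns
#'   numeric features.
#' @param provenance Free-text description of where the table came from.
#' @export
as_feature_table <- function(df, provenance = "user-supplied") {
  if (ncol(df) != N_FEATURES + 1L) {
    stop_input("feature table must have 1 residue column + %d feature columns, got %d",
               N_FEATURES, ncol(df) - 1L)
  }
  residues <- toupper(as.character(df[[1]]))
  dup <- residues[duplicated(residues)]
  if (length(dup) > 0) {
    stop_input("duplicate residue row: %s", paste(unique(dup), collapse = ", "))
  }
  missing <- setdiff(AA_ALPHABET, residues)
  if (length(missing) > 0) {
    stop_input("missing residue row: %s", paste(missing, collapse = ", "))
  }
  extra <- setdiff(residues, AA_ALPHABET)
  if (length(extra) > 0) {
    stop_input("unknown residue row: %s", paste(extra, collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow = 20L, ncol = N_FEATURES,
                dimnames = list(residues, colnames(df)[-1]))
  for (j in seq_len(N_FEATURES)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad) > 0) {
      stop_input("non-numeric or non-finite value in feature table: residue row '%s', column '%s'",
                 residues[bad[1]], colnames(df)[j + 1L])
    }
    mat[, j] <- num
  }
  mat <- mat[AA_ALPHABET, , drop = FALSE]
  structure(
    list(residues = AA_ALPHABET, features = mat,
         feature_names = colnames(mat), provenance = provenance),
    class = "feature_table")
}

#' @rdname load_feature_table
#' @export
default_feature_table <- function() {
  cached <- .aprscan_env$default_feature_table
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "aa_features.tsv", package = "aprscan")
  ft <- load_feature_table(path)
  ft$provenance <- "aprscan default: atom counts + AAindex physicochemical scales"
  .aprscan_env$default_feature_table <- ft
  ft
}

.aprscan_env <- new.env(parent = emptyenv())

# Stable identifier binding a trained model to the table it was encoded with.
feature_table_id <- function(ft) {
  v <- c(as.vector(ft$features), nchar(ft$feature_names))
  sprintf("ft20x36-%.6f", sum(v * seq_along(v) %% 997) %% 1e6)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> 20 residues x", ncol(x$features), "features\n")
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}
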