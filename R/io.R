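#' Read protein sequences from FASTA
#'
#' Scans the file for integrity first (a sequence line before any header,
#' an empty header, or a record with no sequence are reported with their
#' line number), then parses with Biostrings.  Sequences are upper-cased;
#' record ids are the header up to the first whitespace.
#'
#' @param path Path to a FASTA file (multi-record allowed).
#' @return A tibble with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) stop_input("empty FASTA file: %s", path)
  headers <- which(startsWith(trimws(lines), ">"))
  if (length(headers) == 0 || nonblank[1] < headers[1]) {
    stop_input("FASTA integrity error at line %d: sequence before first header",
               nonblank[1])
  }
  for (h in headers) {
    if (nchar(trimws(sub("^>", "", trimws(lines[h])))) == 0) {
      stop_input("FASTA integrity error at line %d: empty header", h)
    }
    nxt <- c(headers, length(lines) + 1L)
    nxt <- min(nxt[nxt > h])
    body <- lines[setdiff(seq(h + 1L, length.out = nxt - h - 1L), integer(0))]
    if (nxt - h - 1L <= 0 || all(trimws(body) == "")) {
      stop_input("FASTA integrity error at line %d: record with empty sequence", h)
    }
  }
  aa <- Biostrings::readBStringSet(path)
  tibble(id = sub("\\s.*$", "", names(aa)),
         sequence = unname(toupper(as.character(aa))))
}

#' @rdname read_fasta
#' @param data A data frame with `id` and `sequence` columns.
#' @export
write_fasta <- function(data, path) {
  x <- Biostrings::BStringSet(setNames(data$sequence, data$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Hexapeptide dataset files
#'
#' The native dialect is CSV with header `sequence,label` (label 0/1,
#' 1 = amyloid-prone).  Reading validates every record (length-6 canonical
#' sequences, binary labels, no duplicate sequence with conflicting
#' labels), reporting offending line numbers.  `read_waltzdb()` adapts an
#' exported table with arbitrary column names (e.g. a WaltzDB export) onto
#' this dialect.
#'
#' @param path File path.
#' @return A tibble with columns `sequence` and `label`.
#' @export
read_hexdataset <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sequence = readr::col_character(), label = readr::col_double()))
  validate_hexdataset(df, path)
}

validate_hexdataset <- function(df, path = "<data>") {
  if (!all(c("sequence", "label") %in% names(df))) {
    stop_input("%s must have columns `sequence` and `label`", path)
  }
  df$sequence <- toupper(df$sequence)
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    if (is.na(df$sequence[i]) || nchar(df$sequence[i]) != WINDOW_SIZE) {
      stop_input("%s line %d: sequence is not a hexapeptide", path, line)
    }
    bad <- which(!chars(df$sequence[i]) %in% AA_ALPHABET)
    if (length(bad) > 0) {
      stop_input("%s line %d: non-canonical residue '%s' at position %d",
                 path, line, chars(df$sequence[i])[bad[1]], bad[1])
    }
    if (is.na(df$label[i]) || !df$label[i] %in% c(0, 1)) {
      stop_input("%s line %d: label must be 0 or 1", path, line)
    }
  }
  conflicts <- dplyr::summarise(dplyr::group_by(df, .data$sequence),
                                n_labels = dplyr::n_distinct(.data$label))
  bad <- conflicts$sequence[conflicts$n_labels > 1]
  if (length(bad) > 0) {
    stop_input("%s: duplicate sequence with conflicting labels: %s",
               path, bad[1])
  }
  tibble(sequence = df$sequence, label = as.integer(df$label))
}

#' @rdname read_hexdataset
#' @param data A data frame with `sequence` and `label` columns.
#' @export
write_hexdataset <- function(data, path) {
  readr::write_csv(dplyr::select(as_tibble(data), "sequence", "label"), path)
  invisible(path)
}

#' @rdname read_hexdataset
#' @param col_sequence,col_label Column names in the export holding the
#'   peptide sequence and the class.
#' @param positive_values Values of `col_label` meaning amyloid-prone.
#' @export
read_waltzdb <- function(path, col_sequence = "Sequence",
                         col_label = "Classification",
                         positive_values = c("amyloid", "Amyloid", "1")) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (!col_sequence %in% names(df) || !col_label %in% names(df)) {
    stop_input("%s: expected columns '%s' and '%s'", path, col_sequence,
               col_label)
  }
  validate_hexdataset(
    tibble(sequence = df[[col_sequence]],
           label = as.integer(df[[col_label]] %in% positive_values)),
    path)
}

#' APR interval annotations
#'
#' Native dialect: a JSON array of objects `{id, sequence, aprs:
#' [[start, end], ...]}` with 1-based inclusive coordinates.  Reading
#' validates that intervals lie within the sequence and that
#' `start <= end`.
#'
#' @param path File path.
#' @return A tibble with columns `id`, `sequence`, `aprs` (list-column of
#'   data frames with `start`, `end`).
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path)
  entries <- lapply(seq_along(raw), function(i) {
    e <- raw[[i]]
    if (is.null(e$id) || is.null(e$sequence)) {
      stop_input("%s entry %d: needs `id` and `sequence`", path, i)
    }
    sequence <- check_sequence(e$sequence, what = sprintf("entry %d", i))
    aprs <- lapply(e$aprs, function(iv) as.integer(unlist(iv)))
    for (iv in aprs) {
      if (length(iv) != 2 || iv[1] > iv[2]) {
        stop_input("%s entry %s: malformed interval [%s]", path, e$id,
                   paste(iv, collapse = ", "))
      }
      if (iv[1] < 1 || iv[2] > nchar(sequence)) {
        stop_input("%s entry %s: interval [%d, %d] outside sequence of length %d",
                   path, e$id, iv[1], iv[2], nchar(sequence))
      }
    }
    iv_df <- if (length(aprs) == 0) {
      data.frame(start = integer(0), end = integer(0))
    } else {
      data.frame(start = vapply(aprs, `[`, integer(1), 1),
                 end = vapply(aprs, `[`, integer(1), 2))
    }
    list(id = as.character(e$id), sequence = sequence, aprs = iv_df)
  })
  tibble(id = vapply(entries, `[[`, character(1), "id"),
         sequence = vapply(entries, `[[`, character(1), "sequence"),
         aprs = lapply(entries, `[[`, "aprs"))
}

#' @rdname read_annotations
#' @param data A tibble as returned by [read_annotations()] or
#'   [gen_annotated_proteins()].
#' @export
write_annotations <- function(data, path) {
  payload <- lapply(seq_len(nrow(data)), function(i) {
    list(id = data$id[i], sequence = data$sequence[i],
         aprs = lapply(seq_len(nrow(data$aprs[[i]])), function(r) {
           c(data$aprs[[i]]$start[r], data$aprs[[i]]$end[r])
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' BED-style interval adapters
#'
#' BED uses 0-based half-open coordinates; the package uses 1-based
#' inclusive everywhere.  The conversion (`start_bed = start - 1`,
#' `end_bed = end`) is exact and round-trips bit-identically.
#'
#' @param calls A data frame of APR calls with `sequence_id`, `start`,
#'   `end` and optionally `mean_score` (1-based inclusive).
#' @param path File path.
#' @export
write_apr_bed <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED intervals: 0-based half-open; columns: chrom start end score", con)
  if (nrow(calls) > 0) {
    score <- if ("mean_score" %in% names(calls)) calls$mean_score else 0
    writeLines(sprintf("%s\t%d\t%d\t%.15g", calls$sequence_id,
                       calls$start - 1L, calls$end, score), con)
  }
  invisible(path)
}

#' @rdname write_apr_bed
#' @export
read_apr_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & trimws(lines) != ""]
  if (length(lines) == 0) {
    return(tibble(sequence_id = character(0), start = integer(0),
                  end = integer(0), mean_score = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop_input("%s line %d: BED rows need at least 3 columns", path, bad[1])
  }
  tibble(sequence_id = vapply(parts, `[`, character(1), 1),
         start = as.integer(vapply(parts, `[`, character(1), 2)) + 1L,
         end = as.integer(vapply(parts, `[`, character(1), 3)),
         mean_score = vapply(parts, function(p) {
           if (length(p) >= 4) as.numeric(p[4]) else NA_real_
         }, numeric(1)))
}

#' Profile writers and readers
#'
#' A per-residue profile is written as CSV with columns `sequence_id`,
#' `position`, `residue`, `aggregation_score`, `coverage`, `in_apr`
#' (or as an equivalent JSON document with `format = "json"`); APR calls
#' are written as BED-like intervals via [write_apr_bed()].  Scores
#' round-trip to at least 1e-9.
#'
#' @param profile A [residue_profile][profile_sequence].
#' @param path File path.
#' @param threshold Threshold used for the `in_apr` flag (default: the
#'   profile's stored threshold).
#' @param min_length Minimum APR length for the flag; default 6.
#' @param format `"csv"` or `"json"`.
#' @export
write_profile <- function(profile, path, threshold = NULL, min_length = 6L,
                          format = c("csv", "json")) {
  format <- match.arg(format)
  threshold <- threshold %||% attr(profile, "threshold") %||% 0.5
  calls <- call_aprs(profile, threshold, min_length)
  in_apr <- rep(0L, nrow(profile))
  for (r in seq_len(nrow(calls))) {
    hit <- profile$sequence_id == calls$sequence_id[r] &
      profile$position >= calls$start[r] & profile$position <= calls$end[r]
    in_apr[hit] <- 1L
  }
  out <- tibble(sequence_id = profile$sequence_id,
                position = profile$position, residue = profile$residue,
                aggregation_score = profile$score,
                coverage = profile$coverage, in_apr = in_apr)
  if (format == "csv") {
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(list(threshold = threshold, profile = out), path,
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(
      sequence_id = "c", position = "i", residue = "c",
      aggregation_score = "d", coverage = "i", in_apr = "i"))
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as_tibble(raw$profile)
  }
  out <- tibble(sequence_id = df$sequence_id, position = df$position,
                residue = df$residue, score = df$aggregation_score,
                coverage = df$coverage, in_apr = df$in_apr)
  class(out) <- c("residue_profile", class(out))
  out
}

#' @rdname write_profile
#' @param calls APR calls from [call_aprs()].
#' @export
write_apr_calls <- function(calls, path) {
  write_apr_bed(calls, path)
}
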