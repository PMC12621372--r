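#' Segment-file input/output
#'
#' A *segment file* is the plain-text hand-off between the seed/filter stage
#' of an aligner and its gapped-extension stage: one high-scoring ungapped
#' pair (HSP) per line, with the fields
#' `target_name target_start target_end query_name query_start query_end
#' strand score`. Coordinates on disk are 1-based closed intervals;
#' internally every function in this package works with 0-based half-open
#' intervals, and the conversion happens only here, at the I/O boundary.
#'
#' `read_segments()` accepts any run of tabs/spaces as a field separator,
#' skips `#` comment lines and blank lines, and treats the score field as
#' optional (default 0). `write_segments()` always emits single tabs and
#' always writes the score.
#'
#' @param path Path of the segment file.
#' @param records A segment data frame as returned by [read_segments()] (see
#'   [segments_df()] for the column contract).
#' @param comments Optional character vector of comment lines (without the
#'   leading `#`) written at the top of the file; used by the pipeline to
#'   carry chunk-window metadata.
#' @return `read_segments()` returns a data frame with one row per HSP, in
#'   file order; `write_segments()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".segments")
#' writeLines("chr1\t101\t150\tchrA\t201\t250\t+\t4500", p)
#' read_segments(p)
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(segments_df())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 7L)
  if (length(bad)) {
    stop("malformed segment line ", lineno[bad[1]], ": expected >= 7 fields, got ",
         nf[bad[1]])
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  num <- function(x, what) {
    suppressWarnings(v <- as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("malformed segment line ", lineno[bad[1]], ": non-numeric ", what,
           " '", x[bad[1]], "'")
    }
    v
  }
  strand <- get(7)
  strand[strand == "−"] <- "-"  # tolerate typographic minus
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop("malformed segment line ", lineno[bad[1]], ": strand '", strand[bad[1]],
         "' not one of +, -")
  }
  score <- ifelse(nf >= 8L, vapply(fields, function(f) f[8], ""), "0")
  df <- segments_df(
    target_name = get(1),
    tstart = num(get(2), "target start") - 1,
    tend   = num(get(3), "target end"),
    query_name = get(4),
    qstart = num(get(5), "query start") - 1,
    qend   = num(get(6), "query end"),
    strand = strand,
    score  = num(score, "score")
  )
  validate_segments(df)
  df
}

#' @rdname read_segments
#' @export
write_segments <- function(records, path, comments = character()) {
  validate_segments(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("#", comments), con)
  if (nrow(records)) {
    out <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d",
                   records$target_name,
                   as.integer(records$tstart) + 1L, as.integer(records$tend),
                   records$query_name,
                   as.integer(records$qstart) + 1L, as.integer(records$qend),
                   records$strand, as.integer(records$score))
    writeLines(out, con)
  }
  invisible(path)
}

#' Construct and validate segment data frames
#'
#' The in-memory representation of a collection of HSPs is an ordinary data
#' frame with columns `target_name`, `tstart`, `tend`, `query_name`,
#' `qstart`, `qend` (0-based half-open), `strand` (`"+"` or `"-"`) and
#' integer `score`. Row order is meaningful: it is the file order, and the
#' gapped extender processes records in that order.
#'
#' @param target_name,query_name Sequence identifiers.
#' @param tstart,tend,qstart,qend 0-based half-open interval bounds (bp).
#' @param strand `"+"` or `"-"`.
#' @param score Non-negative integer alignment score.
#' @return A validated segment data frame.
#' @export
segments_df <- function(target_name = character(), tstart = integer(),
                        tend = integer(), query_name = character(),
                        qstart = integer(), qend = integer(),
                        strand = character(), score = integer()) {
  data.frame(target_name = as.character(target_name),
             tstart = as.integer(tstart), tend = as.integer(tend),
             query_name = as.character(query_name),
             qstart = as.integer(qstart), qend = as.integer(qend),
             strand = as.character(strand), score = as.integer(score),
             stringsAsFactors = FALSE)
}

#' @rdname segments_df
#' @param records A segment data frame.
#' @export
validate_segments <- function(records) {
  req <- c("target_name", "tstart", "tend", "query_name", "qstart", "qend",
           "strand", "score")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("segment data frame lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(records) == 0L) return(invisible(records))
  if (any(records$tstart >= records$tend) || any(records$qstart >= records$qend))
    stop("segment intervals must be non-empty (start < end, half-open)")
  if (any(records$tstart < 0) || any(records$qstart < 0))
    stop("segment coordinates must be non-negative")
  if (!all(records$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(records$score < 0)) stop("scores must be non-negative")
  invisible(records)
}

#' Estimate the number of lines in a segment file from its byte size
#'
#' Counting HSPs by reading a multi-gigabyte segment file would defeat the
#' purpose of cheap split decisions, so the line count is approximated by
#' dividing the file's byte size by the byte size of a single sampled line
#' (the first data line). For files whose rows are all the same width the
#' estimate is exact; otherwise the relative error is bounded by the
#' relative spread of row widths.
#'
#' @param byte_size File size in bytes (non-negative).
#' @param sample_line_bytes Byte size of one sampled row, including its
#'   newline; must be positive.
#' @return `floor(byte_size / sample_line_bytes)`.
#' @export
estimate_line_count <- function(byte_size, sample_line_bytes) {
  if (length(sample_line_bytes) != 1L || !is.finite(sample_line_bytes) ||
      sample_line_bytes <= 0)
    stop("sample_line_bytes must be a single positive number")
  if (byte_size < 0) stop("byte_size must be non-negative")
  as.integer(byte_size %/% sample_line_bytes)
}

#' @rdname estimate_line_count
#' @param path Path of a segment file.
#' @return `segment_file_stats()` returns a list with `path`, `byte_size`,
#'   `sample_line_bytes` (the first data line, 0 if none) and
#'   `estimated_lines`.
#' @export
segment_file_stats <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  byte_size <- file.size(path)
  sample <- 0L
  comment_bytes <- 0L
  con <- file(path, open = "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) break
    if (grepl("^\\s*(#|$)", line)) {
      comment_bytes <- comment_bytes + nchar(line, type = "bytes") + 1L
      next
    }
    sample <- nchar(line, type = "bytes") + 1L
    break
  }
  est <- if (sample > 0) estimate_line_count(byte_size - comment_bytes, sample) else 0L
  list(path = path, byte_size = byte_size, sample_line_bytes = sample,
       estimated_lines = est)
}
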