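#' Write alignments as MAF
#'
#' Standard Multiple Alignment Format: a `##maf` header, then one block per
#' alignment with an `a score=` line and two `s` lines giving source name,
#' 0-based start, aligned size, strand, source length and gapped text. For
#' `-` strand query rows the start and text are given on the reverse
#' complement, per the format.
#'
#' @param alignments List of `toy_alignment` objects.
#' @param target,query The aligned sequences (character or codes), used to
#'   render the alignment text.
#' @param path Output path.
#' @param target_len,query_len Source lengths; default from the sequences.
#' @return `path`, invisibly.
#' @export
write_maf <- function(alignments, target, query, path,
                      target_len = NULL, query_len = NULL) {
  tc <- if (is.character(target)) encode_dna(target) else target
  qc <- if (is.character(query)) encode_dna(query) else query
  if (is.null(target_len)) target_len <- length(tc)
  if (is.null(query_len)) query_len <- length(qc)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##maf version=1 scoring=diagpart_toy", "#"), con)
  chars <- c("N", "A", "C", "G", "T")
  for (aln in alignments) {
    opv <- rep(aln$cigar$ops, aln$cigar$lengths)
    tslice <- tc[(aln$tstart + 1L):aln$tend]
    qslice <- qc[(aln$qstart + 1L):aln$qend]
    if (aln$strand == "-") qslice <- revcomp_codes(qslice)
    ttext <- rep("-", length(opv))
    qtext <- rep("-", length(opv))
    tsel <- opv != "I"
    qsel <- opv != "D"
    ttext[tsel] <- chars[tslice[cumsum(tsel)[tsel]] + 1L]
    qtext[qsel] <- chars[qslice[cumsum(qsel)[qsel]] + 1L]
    qstart_maf <- if (aln$strand == "+") aln$qstart else query_len - aln$qend
    writeLines(c(
      sprintf("a score=%d", aln$score),
      sprintf("s %s %d %d + %d %s", aln$target_name, aln$tstart,
              aln$tend - aln$tstart, target_len, paste(ttext, collapse = "")),
      sprintf("s %s %d %d %s %d %s", aln$query_name, qstart_maf,
              aln$qend - aln$qstart, aln$strand, query_len,
              paste(qtext, collapse = "")),
      ""), con)
  }
  invisible(path)
}

#' @rdname write_maf
#' @return `read_maf()` returns a data frame with one row per block:
#'   `score` plus `name`, `start`, `size`, `strand`, `src_size` and `text`
#'   for the first (`t_`) and second (`q_`) `s` line.
#' @export
read_maf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  a_idx <- grep("^a ", lines)
  parse_s <- function(line) {
    f <- strsplit(trimws(line), "[ \t]+")[[1]]
    list(name = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
         strand = f[5], src_size = as.integer(f[6]), text = f[7])
  }
  rows <- lapply(a_idx, function(i) {
    score <- as.integer(sub(".*score=([-0-9]+).*", "\\1", lines[i]))
    s1 <- parse_s(lines[i + 1L])
    s2 <- parse_s(lines[i + 2L])
    data.frame(score = score,
               t_name = s1$name, t_start = s1$start, t_size = s1$size,
               t_strand = s1$strand, t_src = s1$src_size, t_text = s1$text,
               q_name = s2$name, q_start = s2$start, q_size = s2$size,
               q_strand = s2$strand, q_src = s2$src_size, q_text = s2$text,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(score = integer(), t_name = character(),
                      t_start = integer(), t_size = integer(),
                      t_strand = character(), t_src = integer(),
                      t_text = character(), q_name = character(),
                      q_start = integer(), q_size = integer(),
                      q_strand = character(), q_src = integer(),
                      q_text = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Concatenate MAF files, keeping a single header
#'
#' Joins per-command outputs in the given order; the leading `#` header
#' block of the first file is kept and subsequent headers are stripped, so
#' the result is one valid MAF.
#'
#' @param paths MAF files in the order to concatenate.
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
maf_concat <- function(paths, out) {
  con <- file(out, open = "wt")
  on.exit(close(con))
  first <- TRUE
  for (p in paths) {
    lines <- readLines(p, warn = FALSE)
    if (!first) {
      body_start <- which(!grepl("^#", lines) & lines != "")[1]
      lines <- if (is.na(body_start)) character() else
        lines[body_start:length(lines)]
    }
    if (length(lines)) writeLines(lines, con)
    first <- FALSE
  }
  invisible(out)
}
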