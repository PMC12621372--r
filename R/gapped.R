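#' Gapped (y-drop) extension of anchors with crossing suppression
#'
#' Processes segment records in file order. Each record is reduced to its
#' anchor (the interval midpoints), which is extended forward and backward
#' by banded affine-gap dynamic programming; a band row terminates once its
#' best score falls more than `y_drop` below the running maximum. After an
#' extension is produced, every not-yet-processed same-strand anchor whose
#' midpoint lies on an aligned pair of that alignment is marked covered and
#' is not extended — the dependency that makes partitioning matter: when
#' such records are split into different extension jobs the suppression
#' cannot happen and overlapping ("straddling") alignments appear.
#'
#' Records on strand `"-"` are extended against the reverse complement of
#' the query; all reported coordinates are on the forward strands.
#'
#' @param target,query Character strings or integer code vectors.
#' @param records Segment data frame; row order is the processing order.
#' @param model A [score_model()].
#' @param t_window,q_window Optional 0-based half-open windows restricting
#'   the extension (the chunk boundaries in the pipeline); anchors must lie
#'   inside them.
#' @param suppress Set `FALSE` to extend every anchor regardless of
#'   coverage (diagnostic use).
#' @return A list of `toy_alignment` objects (see Details). Each has
#'   `tstart`, `tend`, `qstart`, `qend` (0-based half-open, forward
#'   strand), `strand`, `score`, `cigar` (list of `ops`/`lengths` runs over
#'   `M`, `I` = gap in target, `D` = gap in query), and the originating
#'   `anchor`.
#' @export
gapped_extend <- function(target, query, records, model = score_model(),
                          t_window = NULL, q_window = NULL, suppress = TRUE) {
  tc <- if (is.character(target)) encode_dna(target) else target
  qc <- if (is.character(query)) encode_dna(query) else query
  if (is.null(t_window)) t_window <- c(0L, length(tc))
  if (is.null(q_window)) q_window <- c(0L, length(qc))
  validate_segments(records)
  n <- nrow(records)
  if (n == 0L) return(list())
  a <- anchors(records)
  if (any(a$target_mid < t_window[1] | a$target_mid >= t_window[2] |
          a$query_mid < q_window[1] | a$query_mid >= q_window[2])) {
    bad <- which(a$target_mid < t_window[1] | a$target_mid >= t_window[2] |
                 a$query_mid < q_window[1] | a$query_mid >= q_window[2])[1]
    stop("record ", bad, ": anchor (", a$target_mid[bad], ",",
         a$query_mid[bad], ") outside the extension window")
  }
  tw <- tc[(t_window[1] + 1L):t_window[2]]
  qw_f <- qc[(q_window[1] + 1L):q_window[2]]
  qw_r <- revcomp_codes(qw_f)
  wqlen <- length(qw_f)

  out <- vector("list", n)
  nout <- 0L
  covered <- logical(n)
  tmid <- a$target_mid - t_window[1]
  qmid_f <- a$query_mid - q_window[1]
  strand <- a$strand

  for (i in seq_len(n)) {
    if (covered[i]) next
    qw <- if (strand[i] == "+") qw_f else qw_r
    qm <- if (strand[i] == "+") qmid_f[i] else wqlen - 1L - qmid_f[i]
    tm <- tmid[i]
    anchor_score <- model$matrix[tw[tm + 1L] + 1L, qw[qm + 1L] + 1L]

    fwd <- .ydrop_extend_dir(tw[seq_len(length(tw) - tm - 1L) + tm + 1L],
                             qw[seq_len(wqlen - qm - 1L) + qm + 1L],
                             model$matrix, model$gap_open, model$gap_extend,
                             model$y_drop)
    bwd <- .ydrop_extend_dir(rev(tw[seq_len(tm)]), rev(qw[seq_len(qm)]),
                             model$matrix, model$gap_open, model$gap_extend,
                             model$y_drop)
    ops <- paste0(reverse_ops(bwd$ops), "M", fwd$ops)
    score <- fwd$score + bwd$score + anchor_score
    ts_w <- tm - bwd$tlen
    te_w <- tm + 1L + fwd$tlen
    qs_w <- qm - bwd$qlen
    qe_w <- qm + 1L + fwd$qlen

    # aligned M pairs in working coordinates
    opv <- strsplit(ops, "")[[1]]
    dt <- as.integer(opv != "I")  # M and D consume target
    dq <- as.integer(opv != "D")  # M and I consume query
    tpos <- ts_w + cumsum(dt) - dt  # position consumed by this column
    qpos <- qs_w + cumsum(dq) - dq
    mcols <- opv == "M"
    pt_w <- tpos[mcols]
    pq_w <- qpos[mcols]

    # convert to forward-strand, global coordinates
    if (strand[i] == "+") {
      qs <- qs_w; qe <- qe_w; pq <- pq_w
    } else {
      qs <- wqlen - qe_w; qe <- wqlen - qs_w
      pq <- wqlen - 1L - pq_w
    }
    r <- rle(opv)
    aln <- structure(list(
      target_name = records$target_name[i], query_name = records$query_name[i],
      tstart = ts_w + t_window[1], tend = te_w + t_window[1],
      qstart = qs + q_window[1], qend = qe + q_window[1],
      strand = strand[i], score = as.integer(score),
      cigar = list(lengths = r$lengths, ops = r$values),
      anchor = c(target_mid = a$target_mid[i], query_mid = a$query_mid[i]),
      record = i), class = "toy_alignment")
    nout <- nout + 1L
    out[[nout]] <- aln

    if (suppress && i < n) {
      # same-strand pending anchors whose midpoint sits on an aligned pair
      pend <- which(!covered & seq_len(n) > i & strand == strand[i])
      if (length(pend)) {
        # an alignment's M columns have strictly increasing target
        # positions, so match() on target is unambiguous
        hit <- match(tmid[pend], pt_w)
        on_pair <- !is.na(hit)
        on_pair[on_pair] <- pq[hit[on_pair]] == qmid_f[pend[on_pair]]
        covered[pend[on_pair]] <- TRUE
      }
    }
  }
  out[seq_len(nout)]
}

reverse_ops <- function(ops) {
  if (nchar(ops) == 0L) return("")
  paste(rev(strsplit(ops, "")[[1]]), collapse = "")
}

#' @export
print.toy_alignment <- function(x, ...) {
  cat(sprintf("<toy_alignment> %s:[%d,%d) %s %s:[%d,%d) score %d\n",
              x$target_name, x$tstart, x$tend, x$strand,
              x$query_name, x$qstart, x$qend, x$score))
  invisible(x)
}

#' Aligned target/query pairs of an alignment
#'
#' @param aln A `toy_alignment`.
#' @return Two-column integer matrix of 0-based (target, query) positions
#'   for the match/mismatch columns, on forward strands.
#' @export
alignment_pairs <- function(aln) {
  opv <- rep(aln$cigar$ops, aln$cigar$lengths)
  dt <- as.integer(opv != "I")
  dq <- as.integer(opv != "D")
  tpos <- aln$tstart + cumsum(dt) - dt
  mcols <- opv == "M"
  if (aln$strand == "+") {
    qpos <- aln$qstart + cumsum(dq) - dq
  } else {
    # columns walk the reverse complement: first column pairs with qend-1
    qpos <- aln$qend - 1L - (cumsum(dq) - dq)
  }
  cbind(target = tpos[mcols], query = qpos[mcols])
}

#' Recompute an alignment's score from its column runs
#'
#' Exact integer check used by the score-validity invariant: sums the
#' substitution scores of match/mismatch columns and charges
#' `gap_open + len * gap_extend` per gap run.
#'
#' @param aln A `toy_alignment`.
#' @param target,query The sequences (character or codes) the alignment was
#'   produced from.
#' @param model The [score_model()] used.
#' @return Integer score.
#' @export
score_alignment <- function(aln, target, query, model) {
  tc <- if (is.character(target)) encode_dna(target) else target
  qc <- if (is.character(query)) encode_dna(query) else query
  pairs <- alignment_pairs(aln)
  qcodes <- qc[pairs[, "query"] + 1L]
  if (aln$strand == "-") qcodes <- 5L - qcodes
  sub_sum <- sum(model$matrix[cbind(tc[pairs[, "target"] + 1L] + 1L,
                                    qcodes + 1L)])
  gaps <- aln$cigar$ops != "M"
  gap_cost <- sum(model$gap_open * gaps +
                  model$gap_extend * aln$cigar$lengths * gaps)
  as.integer(sub_sum - gap_cost)
}
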