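#' Exact k-mer seeding
#'
#' CPU stand-in for a GPU seeder: reports every exact k-mer match between
#' target and query, in both query orientations. Reverse-orientation
#' matches carry strand `"-"` and query coordinates given on the forward
#' query sequence (`qpos` is the leftmost base of the matched k-mer on the
#' forward strand).
#'
#' @param target,query DNA as character strings or integer code vectors.
#' @param k Seed length (>= 4).
#' @return A data frame with 0-based columns `tpos`, `qpos` and `strand`,
#'   ordered by strand, diagonal, then `tpos`.
#' @export
find_seeds <- function(target, query, k) {
  if (k < 4) stop("seed length k must be >= 4")
  tseq <- if (is.character(target)) target else decode_dna(target)
  qseq <- if (is.character(query)) query else decode_dna(query)
  qlen <- nchar(qseq)
  qrc <- decode_dna(revcomp_codes(encode_dna(qseq)))

  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(data.table(kmer = character(), pos = integer()))
    data.table(kmer = substring(s, 1:(n - k + 1L), k:n), pos = 0:(n - k))
  }
  tk <- kmers(tseq)
  match_one <- function(qk, strand) {
    if (nrow(tk) == 0L || nrow(qk) == 0L)
      return(data.frame(tpos = integer(), qpos = integer(),
                        strand = character()))
    m <- merge(tk, qk, by = "kmer", allow.cartesian = TRUE,
               suffixes = c(".t", ".q"))
    if (nrow(m) == 0L)
      return(data.frame(tpos = integer(), qpos = integer(),
                        strand = character()))
    qpos <- if (strand == "+") m$pos.q else qlen - k - m$pos.q
    data.frame(tpos = m$pos.t, qpos = qpos,
               strand = rep(strand, nrow(m)))
  }
  out <- rbind(match_one(kmers(qseq), "+"), match_one(kmers(qrc), "-"))
  if (nrow(out)) {
    # working-space diagonal: on '-' the extension runs in revcomp space
    qw <- ifelse(out$strand == "+", out$qpos, qlen - k - out$qpos)
    out <- out[order(out$strand, out$tpos - qw, out$tpos), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# x-drop extension in one direction along a diagonal. scores: vector of
# per-position substitution scores walking away from the seed. Returns
# c(extension length, score gained).
xdrop_run <- function(scores, x_drop) {
  if (length(scores) == 0L) return(c(0L, 0L))
  cum <- cumsum(scores)
  peak <- cummax(cum)
  stop_at <- which(peak - cum > x_drop)
  lim <- if (length(stop_at)) stop_at[1] - 1L else length(scores)
  if (lim == 0L) return(c(0L, 0L))
  best <- which.max(cum[seq_len(lim)])
  if (cum[best] <= 0L) return(c(0L, 0L))
  c(best, cum[best])
}

#' Gap-free (x-drop) extension of a seed into an HSP
#'
#' Extends an exact seed match in both directions without gaps, tracking
#' the running score under the model's substitution matrix; a direction
#' stops once the score falls more than `x_drop` below that direction's
#' maximum, and the maximal-scoring span is kept. Seeds whose extended
#' score stays below `model$hsp_thresh` are discarded as likely false
#' positives.
#'
#' @param target,query Integer code vectors (see `encode_dna`) or character
#'   strings.
#' @param match One row of [find_seeds()] output (list or data frame with
#'   `tpos`, `qpos`, `strand`).
#' @param model A [score_model()].
#' @return A one-row segment data frame ([segments_df()]), or `NULL` if the
#'   extension does not reach `hsp_thresh`. Query coordinates are always on
#'   the forward strand.
#' @export
ungapped_extend <- function(target, query, match, model) {
  tc <- if (is.character(target)) encode_dna(target) else target
  qc <- if (is.character(query)) encode_dna(query) else query
  k <- model$k
  qlen <- length(qc)
  strand <- match$strand
  qw <- if (strand == "+") qc else revcomp_codes(qc)
  qpos_w <- if (strand == "+") match$qpos else qlen - k - match$qpos
  tpos <- match$tpos
  M <- model$matrix

  pair_scores <- function(ti, qi) M[cbind(tc[ti] + 1L, qw[qi] + 1L)]
  seed_score <- sum(pair_scores(tpos + 1:k, qpos_w + 1:k))

  nr <- min(length(tc) - (tpos + k), length(qw) - (qpos_w + k))
  right <- xdrop_run(if (nr > 0) pair_scores(tpos + k + 1:nr, qpos_w + k + 1:nr)
                     else integer(), model$x_drop)
  nl <- min(tpos, qpos_w)
  left <- xdrop_run(if (nl > 0) pair_scores(tpos - 1:nl + 1L, qpos_w - 1:nl + 1L)
                    else integer(), model$x_drop)

  score <- seed_score + right[2] + left[2]
  if (score < model$hsp_thresh) return(NULL)
  ts <- tpos - left[1]; te <- tpos + k + right[1]
  qs_w <- qpos_w - left[1]; qe_w <- qpos_w + k + right[1]
  if (strand == "+") {
    qs <- qs_w; qe <- qe_w
  } else {
    qs <- qlen - qe_w; qe <- qlen - qs_w
  }
  segments_df("target", ts, te, "query", qs, qe, strand, score)
}

#' Seed, filter, and emit HSPs for a sequence pair
#'
#' The CPU analogue of the seed + filter stages: finds all exact k-mer
#' seeds, extends each gap-free with the x-drop rule, and keeps extensions
#' scoring at least `hsp_thresh`. Seeds falling inside an HSP already
#' produced on the same diagonal are skipped (they would reproduce it), and
#' duplicate spans are removed, so the output is one record per distinct
#' HSP, ordered by strand then target start.
#'
#' @param target,query Character strings or integer code vectors.
#' @param model A [score_model()].
#' @param target_name,query_name Names written into the records.
#' @return A segment data frame of HSPs.
#' @export
seed_and_filter <- function(target, query, model = score_model(),
                            target_name = "target", query_name = "query") {
  tc <- if (is.character(target)) encode_dna(target) else target
  qc <- if (is.character(query)) encode_dna(query) else query
  seeds <- find_seeds(tc, qc, model$k)
  if (nrow(seeds) == 0L) return(segments_df())
  qlen <- length(qc)
  k <- model$k
  res <- vector("list", 64L)
  nres <- 0L
  # per-strand, per-diagonal rightmost covered target end (working space)
  off <- qlen + 1L
  cover <- list("+" = integer(length(tc) + qlen + 1L) - 1L,
                "-" = integer(length(tc) + qlen + 1L) - 1L)
  s_tpos <- seeds$tpos; s_qpos <- seeds$qpos; s_strand <- seeds$strand
  for (i in seq_along(s_tpos)) {
    qw <- if (s_strand[i] == "+") s_qpos[i] else qlen - k - s_qpos[i]
    d <- s_tpos[i] - qw + off
    if (s_tpos[i] + k <= cover[[s_strand[i]]][d]) next
    rec <- ungapped_extend(tc, qc,
                           list(tpos = s_tpos[i], qpos = s_qpos[i],
                                strand = s_strand[i]), model)
    cov_end <- s_tpos[i] + k
    if (!is.null(rec)) {
      cov_end <- max(cov_end, rec$tend)
      nres <- nres + 1L
      if (nres > length(res)) res <- c(res, vector("list", length(res)))
      res[[nres]] <- rec
    }
    cover[[s_strand[i]]][d] <- max(cover[[s_strand[i]]][d], cov_end)
  }
  if (nres == 0L) return(segments_df())
  out <- as.data.frame(data.table::rbindlist(res[seq_len(nres)]))
  out$target_name <- target_name
  out$query_name <- query_name
  out <- unique(out)
  out <- out[order(out$strand, out$tstart, out$qstart), , drop = FALSE]
  rownames(out) <- NULL
  out
}
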