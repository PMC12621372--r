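#' Assign HSPs to dot-plot chunks
#'
#' The pipeline mirrors the production layout: the alignment matrix is cut
#' into `chunk_size` x `chunk_size` tiles, each tile's HSPs form one
#' segment file, and gapped extension of a tile is bounded by the tile. An
#' HSP belongs to the tile containing its anchor midpoint.
#'
#' @param records Segment data frame.
#' @param chunk_size Tile side length in bp.
#' @return The records with integer columns `chunk_t` and `chunk_q`
#'   appended.
#' @export
assign_chunks <- function(records, chunk_size) {
  stopifnot(chunk_size >= 1)
  a <- anchors(records)
  records$chunk_t <- a$target_mid %/% as.integer(chunk_size)
  records$chunk_q <- a$query_mid %/% as.integer(chunk_size)
  records
}

chunk_window <- function(chunk_idx, chunk_size, seq_len_) {
  lo <- chunk_idx * chunk_size
  c(lo, min(lo + chunk_size, seq_len_))
}

# Run gapped extension chunk by chunk, optionally partitioning each chunk's
# records first. partition_fun(records) -> list of hsp_partition (or NULL
# for no partitioning). Returns a list of alignments tagged with their
# chunk and partition of origin.
run_chunked <- function(tc, qc, records, model, chunk_size, partition_fun = NULL) {
  records <- assign_chunks(records, chunk_size)
  keys <- unique(records[, c("chunk_t", "chunk_q")])
  keys <- keys[order(keys$chunk_t, keys$chunk_q), , drop = FALSE]
  out <- list()
  for (ci in seq_len(nrow(keys))) {
    sel <- records$chunk_t == keys$chunk_t[ci] &
           records$chunk_q == keys$chunk_q[ci]
    chunk_recs <- records[sel, , drop = FALSE]
    tw <- chunk_window(keys$chunk_t[ci], chunk_size, length(tc))
    qw <- chunk_window(keys$chunk_q[ci], chunk_size, length(qc))
    parts <- if (is.null(partition_fun)) list(list(index = 1L, records = chunk_recs))
             else partition_fun(chunk_recs)
    for (p in parts) {
      alns <- gapped_extend(tc, qc, p$records, model,
                            t_window = tw, q_window = qw)
      for (a in alns) {
        a$chunk <- c(keys$chunk_t[ci], keys$chunk_q[ci])
        a$partition <- p$index
        out[[length(out) + 1L]] <- a
      }
    }
  }
  out
}

#' Quantify straddling alignments in a partitioned run
#'
#' Straddling alignments are the duplicate and extra alignments produced
#' when anchors that depend on each other (one extension would cross the
#' other anchor) are processed in different partitions. The report counts,
#' over same-strand alignment pairs originating from *different partitions
#' of the same chunk*: `duplicated_columns` — target positions covered
#' more than once; `overlapping_pairs` — alignment pairs with overlapping
#' target intervals; plus `total_alignments` and `output_bytes` (size of
#' the merged MAF). An unpartitioned run has zeroes by construction.
#'
#' @param alignments Tagged alignment list from a partitioned run.
#' @param target,query Sequences, used to render the output MAF for the
#'   byte count.
#' @return A one-row data frame.
#' @export
straddle_report <- function(alignments, target, query) {
  total <- length(alignments)
  dup_cols <- 0L
  overlap_pairs <- 0L
  if (total > 1L) {
    meta <- data.frame(
      chunk = vapply(alignments, function(a) paste(a$chunk, collapse = ","), ""),
      strand = vapply(alignments, `[[`, "", "strand"),
      part = vapply(alignments, function(a) as.integer(a$partition), integer(1)),
      tstart = vapply(alignments, function(a) as.integer(a$tstart), integer(1)),
      tend = vapply(alignments, function(a) as.integer(a$tend), integer(1)))
    for (grp in split(seq_len(total), paste(meta$chunk, meta$strand))) {
      if (length(grp) < 2L) next
      sub <- meta[grp, , drop = FALSE]
      if (length(unique(sub$part)) < 2L) next
      # per-partition reduced target coverage, then count columns hit by
      # more than one partition
      w <- max(sub$tend)
      by_part <- lapply(split(seq_len(nrow(sub)), sub$part), function(ii)
        IRanges::reduce(IRanges::IRanges(sub$tstart[ii] + 1L, sub$tend[ii])))
      cov <- Reduce(`+`, lapply(by_part, IRanges::coverage, width = w))
      dup_cols <- dup_cols + sum(S4Vectors::runLength(cov)[
        S4Vectors::runValue(cov) >= 2L])
      ir <- IRanges::IRanges(sub$tstart + 1L, sub$tend)
      hits <- IRanges::findOverlaps(ir, ir)
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      overlap_pairs <- overlap_pairs +
        sum(qh < sh & sub$part[qh] != sub$part[sh])
    }
  }
  maf <- tempfile(fileext = ".maf")
  write_maf(alignments, target, query, maf)
  bytes <- file.size(maf)
  unlink(maf)
  data.frame(total_alignments = total, duplicated_columns = dup_cols,
             overlapping_pairs = overlap_pairs, output_bytes = bytes)
}

#' Compare partitioning strategies on one sequence pair
#'
#' End-to-end desk-scale experiment: seeds and filters the pair into HSPs,
#' tiles them into chunks, and for each strategy splits every chunk's
#' records at `max_size` (`"none"` leaves them whole), runs gapped
#' extension per partition independently, and summarises straddling with
#' [straddle_report()]. `"none"` is the baseline: by definition it has zero
#' duplicated columns, and any strategy with `max_size = Inf` reproduces
#' its alignment set exactly.
#'
#' @param target,query Sequences (character or codes).
#' @param model A [score_model()].
#' @param chunk_size Tile side (bp).
#' @param max_size Partition cap (records); may be `Inf`.
#' @param strategies Subset of `c("none", "row", "diagonal")`.
#' @param records Optional precomputed HSPs (skips seeding).
#' @return A list with `records` (the HSPs used), `alignments` (per
#'   strategy) and `report` (data frame, one row per strategy).
#' @export
evaluate_strategies <- function(target, query, model = score_model(),
                                chunk_size = 10000L, max_size = 25L,
                                strategies = c("none", "row", "diagonal"),
                                records = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  tc <- if (is.character(target)) encode_dna(target) else target
  qc <- if (is.character(query)) encode_dna(query) else query
  if (is.null(records)) records <- seed_and_filter(tc, qc, model)
  part_fun <- function(strategy) {
    if (strategy == "none" || !is.finite(max_size)) return(NULL)
    function(recs) partition_records(recs, max_size,
                                     by_diagonal = (strategy == "diagonal"))
  }
  alignments <- list()
  reports <- list()
  for (s in strategies) {
    alns <- run_chunked(tc, qc, records, model, chunk_size, part_fun(s))
    rep <- straddle_report(alns, tc, qc)
    rep$strategy <- s
    rep$max_size <- max_size
    alignments[[s]] <- alns
    reports[[s]] <- rep
  }
  list(records = records,
       alignments = alignments,
       report = do.call(rbind, reports))
}

#' Compact alignment-set fingerprint
#'
#' Coordinate/strand/score tuples of an alignment list, sorted — used to
#' compare alignment sets across strategies and worker counts.
#'
#' @param alignments List of `toy_alignment`s.
#' @return A sorted character vector, one element per alignment.
#' @export
alignment_key <- function(alignments) {
  sort(vapply(alignments, function(a)
    sprintf("%s:%d-%d/%s:%d-%d/%s/%d", a$target_name, a$tstart, a$tend,
            a$query_name, a$qstart, a$qend, a$strand, a$score), ""))
}
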