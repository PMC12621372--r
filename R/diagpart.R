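#' Reduce HSPs to anchors with strand-dependent diagonal keys
#'
#' Gapped extension starts from a single point on each HSP, the *anchor*.
#' Computing the aligner's true optimal start point would require scoring
#' each HSP, so the anchor is approximated by the midpoint of both
#' intervals. In dot-plot coordinates a forward alignment extends along a
#' line of constant `target - query` and a reverse alignment along constant
#' `target + query`; the corresponding diagonal key is what partitioning
#' sorts on, so that anchors likely to lie on the same alignment end up in
#' the same partition.
#'
#' @param records A segment data frame ([segments_df()]).
#' @return The input with columns `target_mid`, `query_mid` (floor midpoints
#'   on 0-based coordinates) and `diag_key` (`target_mid - query_mid` on
#'   `+`, `target_mid + query_mid` on `-`) appended.
#' @examples
#' r <- segments_df("t", 10, 20, "q", 110, 120, "+", 100)
#' anchors(r)[, c("target_mid", "query_mid", "diag_key")]
#' @export
anchors <- function(records) {
  validate_segments(records)
  records$target_mid <- (records$tstart + records$tend) %/% 2L
  records$query_mid <- (records$qstart + records$qend) %/% 2L
  records$diag_key <- ifelse(records$strand == "+",
                             records$target_mid - records$query_mid,
                             records$target_mid + records$query_mid)
  records
}

#' @rdname anchors
#' @param record A single-row segment data frame.
#' @return `anchor_of()` returns a list with `target_mid`, `query_mid`,
#'   `strand` and `diag_key` for one record.
#' @export
anchor_of <- function(record) {
  stopifnot(nrow(record) == 1L)
  a <- anchors(record)
  list(target_mid = a$target_mid, query_mid = a$query_mid,
       strand = a$strand, diag_key = a$diag_key)
}

partition_obj <- function(index, strand, records, diag_min, diag_max) {
  structure(list(index = index, strand = strand, records = records,
                 diag_min = diag_min, diag_max = diag_max,
                 n = nrow(records)),
            class = "hsp_partition")
}

#' @export
print.hsp_partition <- function(x, ...) {
  cat(sprintf("<hsp_partition #%d> strand %s, %d records, diagonals [%d, %d]\n",
              x$index, x$strand, x$n, x$diag_min, x$diag_max))
  invisible(x)
}

cut_sorted <- function(records, ord, strand, max_size, start_index) {
  idx <- split(ord, ceiling(seq_along(ord) / max_size))
  lapply(seq_along(idx), function(i) {
    recs <- records[idx[[i]], , drop = FALSE]
    rownames(recs) <- NULL
    partition_obj(start_index + i - 1L, strand, recs,
                  min(recs$diag_key), max(recs$diag_key))
  })
}

#' Split HSP collections into extension-sized partitions
#'
#' `partition_by_diagonal()` is the core operation: records are split by
#' strand, anchors within a strand are ordered by `(diag_key, target_mid,
#' query_mid, input order)`, and the ordered run is cut greedily into
#' consecutive partitions of at most `max_size` anchors. Every partition is
#' therefore a contiguous diagonal band, and same-strand partitions have
#' non-interleaving diagonal ranges; anchors that would be crossed by the
#' same extension stay together, so the extension jobs that later process
#' each partition independently almost never produce straddling (duplicate
#' or extra) alignments. Bands only share a diagonal when more than
#' `max_size` anchors sit on one diagonal, in which case the hard size cap
#' wins.
#'
#' `partition_rowwise()` is the naive baseline used for comparison: the same
#' greedy cut, but over anchors ordered by `(target_mid, query_mid)`, i.e.
#' horizontal stripes of the dot plot.
#'
#' @param records A segment data frame.
#' @param max_size Maximum number of records per partition (>= 1).
#' @return An ordered list of `hsp_partition` objects (forward-strand
#'   partitions first), each holding `index`, `strand`, `records`,
#'   `diag_min`, `diag_max` and `n`.
#' @seealso [split_segment_file()] for the file-level driver,
#'   [adaptive_max_size()] for choosing `max_size`.
#' @export
partition_by_diagonal <- function(records, max_size) {
  partition_records(records, max_size, by_diagonal = TRUE)
}

#' @rdname partition_by_diagonal
#' @export
partition_rowwise <- function(records, max_size) {
  partition_records(records, max_size, by_diagonal = FALSE)
}

partition_records <- function(records, max_size, by_diagonal) {
  if (length(max_size) != 1L || is.na(max_size) || max_size < 1)
    stop("max_size must be >= 1")
  a <- anchors(records)
  out <- list()
  nxt <- 1L
  for (s in c("+", "-")) {
    rows <- which(a$strand == s)
    if (length(rows) == 0L) next
    sub <- a[rows, , drop = FALSE]
    ord <- if (by_diagonal) {
      order(sub$diag_key, sub$target_mid, sub$query_mid)  # stable: input order last
    } else {
      order(sub$target_mid, sub$query_mid)
    }
    parts <- cut_sorted(sub, ord, s, max_size, nxt)
    nxt <- nxt + length(parts)
    out <- c(out, parts)
  }
  out
}

#' Manifest of a partition plan
#'
#' @param plan A list of partitions from [partition_by_diagonal()] or
#'   [partition_rowwise()], optionally with a `file` attribute per
#'   partition.
#' @return A data frame with one row per partition: `index`, `strand`,
#'   `size`, `diag_min`, `diag_max` and (when present) `file`.
#' @export
partition_manifest <- function(plan) {
  df <- data.frame(
    index = vapply(plan, `[[`, integer(1), "index"),
    strand = vapply(plan, `[[`, character(1), "strand"),
    size = vapply(plan, `[[`, integer(1), "n"),
    diag_min = vapply(plan, function(p) as.integer(p$diag_min), integer(1)),
    diag_max = vapply(plan, function(p) as.integer(p$diag_max), integer(1)),
    stringsAsFactors = FALSE)
  files <- vapply(plan, function(p) if (is.null(p$file)) NA_character_ else p$file,
                  character(1))
  if (!all(is.na(files))) df$file <- files
  df
}

#' Adaptive choice of the maximum partition size
#'
#' The best maximum-partition-size setting depends on genome size,
#' similarity and core count, and is hard to guess up front. The adaptive
#' policy therefore tracks the pre-split sizes of segment files seen so far
#' and uses their upper quartile as the current cap: early oversized files
#' are split aggressively, and the cap settles as the size distribution
#' fills in. The quartile is the nearest-rank order statistic
#' `ceiling(0.75 * n)` of the history — integer-valued, like the counts it
#' summarises.
#'
#' @param mode `"adaptive"` (upper-quartile of history, falling back to
#'   `default_max` while the history is empty) or `"fixed"`.
#' @param fixed_max Cap used in `"fixed"` mode.
#' @param default_max Cap used in `"adaptive"` mode before any file has been
#'   observed.
#' @param history Integer vector of previously observed pre-split segment
#'   file sizes (record counts).
#' @return `size_policy()` returns a policy object; `adaptive_max_size()`
#'   returns the current cap; `record_observation()` returns the policy with
#'   one size appended to its history.
#' @examples
#' p <- size_policy("adaptive", history = c(100, 200, 300, 400))
#' adaptive_max_size(p)  # 300
#' @export
size_policy <- function(mode = c("adaptive", "fixed"), fixed_max = 20000L,
                        default_max = 20000L, history = integer()) {
  mode <- match.arg(mode)
  if (fixed_max < 1 || default_max < 1)
    stop("fixed_max and default_max must be positive")
  structure(list(mode = mode, fixed_max = as.integer(fixed_max),
                 default_max = as.integer(default_max),
                 history = as.integer(history)),
            class = "size_policy")
}

#' @rdname size_policy
#' @param policy A `size_policy` object.
#' @export
adaptive_max_size <- function(policy) {
  stopifnot(inherits(policy, "size_policy"))
  if (policy$mode == "fixed") return(policy$fixed_max)
  n <- length(policy$history)
  if (n == 0L) return(policy$default_max)
  sort(policy$history)[ceiling(0.75 * n)]
}

#' @rdname size_policy
#' @param size Observed pre-split size (record count) to append.
#' @export
record_observation <- function(policy, size) {
  stopifnot(inherits(policy, "size_policy"))
  policy$history <- c(policy$history, as.integer(size))
  policy
}

#' @rdname size_policy
#' @param dir Directory scanned for `*.segments` files; their sizes are
#'   estimated by the byte method ([estimate_line_count()]) and used as the
#'   starting history, mirroring a shared segment-file folder acting as an
#'   implicit size registry.
#' @export
size_policy_from_dir <- function(dir, mode = "adaptive", default_max = 20000L) {
  files <- list.files(dir, pattern = "\\.segments$", full.names = TRUE)
  hist <- vapply(files, function(f) segment_file_stats(f)$estimated_lines,
                 integer(1))
  size_policy(mode, default_max = default_max, history = unname(hist))
}

#' Split one segment file into partition files
#'
#' The file-level driver: estimates the file's line count from its byte
#' size, and if it exceeds the policy's current cap (and `strategy` is not
#' `"none"`), partitions its records and writes one segment file per
#' partition, named `<stem>.part<k>.<strand>.segments`, together with a
#' plain-text plan manifest `<stem>.plan.tsv`. Files at or under the cap
#' pass through as a single partition. The file's pre-split record count is
#' appended to the policy history either way, so later files see an
#' up-to-date size distribution.
#'
#' @param path Segment file to split.
#' @param policy A [size_policy()].
#' @param output_dir Directory for partition files (created if needed).
#' @param strategy `"diagonal"`, `"row"` or `"none"`.
#' @return A list with `files` (partition paths, in plan order), `manifest`
#'   (data frame), `manifest_path`, and the updated `policy`.
#' @export
split_segment_file <- function(path, policy, output_dir,
                               strategy = c("diagonal", "row", "none")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(policy, "size_policy"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sub("\\.segments$", "", basename(path))
  max_size <- adaptive_max_size(policy)
  est <- segment_file_stats(path)$estimated_lines
  records <- read_segments(path)
  comments <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  comments <- sub("^#", "", comments)
  policy <- record_observation(policy, nrow(records))

  if (strategy == "none" || est <= max_size) {
    strands <- unique(records$strand)
    tag <- if (length(strands) == 1L) strands else "both"
    out <- file.path(output_dir, sprintf("%s.part1.%s.segments", stem, tag))
    write_segments(records, out, comments = comments)
    a <- if (nrow(records)) anchors(records) else NULL
    plan <- list(partition_obj(1L, tag, records,
                               if (is.null(a)) NA_integer_ else min(a$diag_key),
                               if (is.null(a)) NA_integer_ else max(a$diag_key)))
    plan[[1]]$file <- out
  } else {
    plan <- if (strategy == "diagonal") partition_by_diagonal(records, max_size)
            else partition_rowwise(records, max_size)
    plan <- lapply(plan, function(p) {
      p$file <- file.path(output_dir,
                          sprintf("%s.part%d.%s.segments", stem, p$index, p$strand))
      write_segments(p$records, p$file, comments = comments)
      p
    })
  }
  manifest <- partition_manifest(plan)
  manifest_path <- file.path(output_dir, paste0(stem, ".plan.tsv"))
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(files = vapply(plan, `[[`, character(1), "file"),
       manifest = manifest, manifest_path = manifest_path, policy = policy)
}
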