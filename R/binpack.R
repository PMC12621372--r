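#' Pack chromosomes into similarly sized bins (LPT rule)
#'
#' To run several aligner instances side by side, whole genomes are split
#' *across* chromosomes — never through one — into bins of roughly equal
#' total length, so no coordinates need remapping and no alignment can
#' straddle a bin boundary. `lpt_pack()` applies the classic
#' longest-processing-time-first rule: sort sequences by decreasing length
#' and assign each to the currently least-loaded bin (ties to the lowest
#' bin index), which guarantees a makespan within `4/3 - 1/(3m)` of
#' optimal. `pack_to_capacity()` derives the bin count from a target
#' capacity (around 200 Mbp in production use) by ceiling division, then
#' delegates to `lpt_pack()`.
#'
#' @param items Data frame with columns `name` and `length` (bp, positive).
#' @param num_bins Number of bins (>= 1).
#' @return A list of bins; each bin is a list with `index`, `members` (an
#'   `items` subset) and `load` (total bp).
#' @examples
#' items <- data.frame(name = letters[1:5], length = c(5, 4, 3, 3, 2))
#' sapply(lpt_pack(items, 2), `[[`, "load")
#' @export
lpt_pack <- function(items, num_bins) {
  if (length(num_bins) != 1L || is.na(num_bins) || num_bins < 1)
    stop("num_bins must be >= 1")
  stopifnot(is.data.frame(items), all(c("name", "length") %in% names(items)),
            nrow(items) > 0L)
  if (any(items$length <= 0)) stop("sequence lengths must be positive")
  num_bins <- as.integer(num_bins)
  ord <- order(-items$length)  # stable: equal lengths keep input order
  loads <- numeric(num_bins)
  assign_to <- integer(nrow(items))
  for (i in ord) {
    b <- which.min(loads)  # first minimum = lowest index
    assign_to[i] <- b
    loads[b] <- loads[b] + items$length[i]
  }
  lapply(seq_len(num_bins), function(b) {
    list(index = b, members = items[assign_to == b, , drop = FALSE],
         load = loads[b])
  })
}

#' @rdname lpt_pack
#' @param target_bin_size Target capacity per bin in bp (> 0).
#' @export
pack_to_capacity <- function(items, target_bin_size) {
  if (length(target_bin_size) != 1L || is.na(target_bin_size) ||
      target_bin_size <= 0)
    stop("target_bin_size must be positive")
  num_bins <- max(1L, as.integer(ceiling(sum(items$length) / target_bin_size)))
  lpt_pack(items, num_bins)
}

#' Enumerate target x query bin pairs as work units
#'
#' Each aligner instance processes one (target bin, query bin) pair; the
#' full cross product covers the whole alignment matrix.
#'
#' @param target_bins,query_bins Bin lists from [lpt_pack()].
#' @return A data frame with columns `target_bin` and `query_bin`, ordered
#'   by target index then query index.
#' @export
make_bin_pairs <- function(target_bins, query_bins) {
  stopifnot(length(target_bins) > 0L, length(query_bins) > 0L)
  ti <- vapply(target_bins, `[[`, integer(1), "index")
  qi <- vapply(query_bins, `[[`, integer(1), "index")
  data.frame(target_bin = rep(ti, each = length(qi)),
             query_bin = rep(qi, times = length(ti)))
}

#' Read sequence lengths for bin packing
#'
#' Accepts either a FASTA file (lengths read via Biostrings without keeping
#' sequence in memory longer than needed) or a two-column `name<TAB>length`
#' table.
#'
#' @param path FASTA or TSV path.
#' @return A data frame with columns `name` and `length`.
#' @export
read_seq_lengths <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, ">")) {
    w <- Biostrings::fasta.seqlengths(path)
    data.frame(name = sub("\\s.*", "", names(w)), length = unname(w),
               stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    stopifnot(ncol(df) >= 2L)
    data.frame(name = as.character(df[[1]]), length = as.numeric(df[[2]]))
  }
}

#' @rdname lpt_pack
#' @param bins A bin list from [lpt_pack()].
#' @param path Output TSV path.
#' @export
write_bin_manifest <- function(bins, path) {
  rows <- do.call(rbind, lapply(bins, function(b) {
    if (nrow(b$members) == 0L) return(NULL)
    data.frame(bin = b$index, name = b$members$name,
               length = b$members$length, bin_load = b$load)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
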