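#' Simulate a diverged homologous sequence pair
#'
#' Generates a random target core, derives the query core from it by
#' i.i.d. substitutions at rate `divergence` (always to a different base)
#' and by short indels — insertion or deletion with equal probability,
#' length uniform on `indel_len_range` — at per-base rate `indel_rate`,
#' then pads both sequences with independent random flanks of
#' `flank_length` on each end. This emulates a pair of homologous loci
#' embedded in unrelated context: the flanks bound every alignment, and the
#' indels scatter the homology over many dot-plot diagonals, which is what
#' makes partitioning behaviour visible at desk scale.
#'
#' @param core_length Length of the homologous core (bp).
#' @param divergence Substitution fraction in `[0, 1]` (study range 0-0.40).
#' @param indel_rate Per-base indel probability (default 0.01).
#' @param indel_len_range Inclusive indel length range (default 1-5 bp).
#' @param flank_length Random flank added to each end (default 1000 bp).
#' @param seed RNG seed; the same spec and seed always reproduce the same
#'   pair.
#' @return A list with `target` and `query` (character strings), and
#'   `truth`: the 0-based half-open core interval on each
#'   (`target_core`, `query_core`).
#' @examples
#' p <- simulate_pair(1000, divergence = 0.1, seed = 1)
#' nchar(p$target)  # 3000
#' @export
simulate_pair <- function(core_length, divergence, indel_rate = 0.01,
                          indel_len_range = c(1L, 5L), flank_length = 1000L,
                          seed = 1L) {
  stopifnot(core_length >= 1, divergence >= 0, divergence <= 1,
            indel_rate >= 0, flank_length >= 0,
            length(indel_len_range) == 2L,
            indel_len_range[1] >= 1, indel_len_range[1] <= indel_len_range[2])
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    core <- sample(bases, core_length, replace = TRUE)

    # substitutions: resample uniformly among the three other bases
    qcore <- core
    sub_at <- which(runif(core_length) < divergence)
    if (length(sub_at)) {
      qcore[sub_at] <- vapply(qcore[sub_at], function(b)
        sample(setdiff(bases, b), 1L), "")
    }

    # indels: walk the mutated core, inserting or deleting short runs
    if (indel_rate > 0) {
      ev_at <- which(runif(core_length) < indel_rate)
      if (length(ev_at)) {
        pieces <- vector("list", 2L * length(ev_at) + 1L)
        prev <- 1L
        k <- 1L
        for (pos in ev_at) {
          if (pos < prev) next  # swallowed by an earlier deletion
          len <- sample(seq.int(indel_len_range[1], indel_len_range[2]), 1L)
          if (runif(1) < 0.5) {  # insertion before pos
            pieces[[k]] <- qcore[prev:(pos - 1L)][seq_len(max(0L, pos - prev))]
            pieces[[k + 1L]] <- sample(bases, len, replace = TRUE)
            prev <- pos
          } else {               # deletion of [pos, pos+len)
            pieces[[k]] <- qcore[prev:(pos - 1L)][seq_len(max(0L, pos - prev))]
            pieces[[k + 1L]] <- character()
            prev <- min(core_length + 1L, pos + len)
          }
          k <- k + 2L
        }
        if (prev <= core_length) pieces[[k]] <- qcore[prev:core_length]
        qcore <- unlist(pieces)
      }
    }

    flank <- function() sample(bases, flank_length, replace = TRUE)
    t5 <- flank(); t3 <- flank(); q5 <- flank(); q3 <- flank()
    target <- paste(c(t5, core, t3), collapse = "")
    query <- paste(c(q5, qcore, q3), collapse = "")
    list(target = target, query = query,
         truth = list(
           target_core = c(flank_length, flank_length + core_length),
           query_core = c(flank_length, flank_length + length(qcore))),
         seed = seed)
  })
}

#' Simulate a pair with multiple rearranged homologous blocks
#'
#' A richer fixture than [simulate_pair()]: `n_blocks` independently
#' diverged homologous blocks are placed in order along the target but in a
#' shuffled order along the query, separated by random spacers, and a
#' fraction of blocks is additionally duplicated at a second random query
#' position. The result is a dot plot with many distinct, well-separated
#' diagonals — including overlapping target ranges from the duplications —
#' which is the regime where row-wise partitioning visibly cuts alignments
#' apart while diagonal partitioning keeps them intact.
#'
#' @param n_blocks Number of homologous blocks.
#' @param block_length Length of each block core (bp).
#' @param divergence,indel_rate,indel_len_range As in [simulate_pair()].
#' @param spacer_length Random spacer between consecutive blocks (bp).
#' @param dup_fraction Fraction of blocks duplicated at an extra query
#'   position.
#' @param seed RNG seed.
#' @return A list with `target`, `query` (character strings) and
#'   `blocks`, a data frame of true block placements.
#' @export
simulate_rearranged_pair <- function(n_blocks = 10L, block_length = 3000L,
                                     divergence = 0.02, indel_rate = 0.01,
                                     indel_len_range = c(1L, 5L),
                                     spacer_length = 1000L,
                                     dup_fraction = 0.2, seed = 1L) {
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    mutate <- function(core) {
      q <- core
      sub_at <- which(runif(length(core)) < divergence)
      if (length(sub_at)) q[sub_at] <- vapply(q[sub_at], function(b)
        sample(setdiff(bases, b), 1L), "")
      ev_at <- which(runif(length(core)) < indel_rate)
      for (pos in rev(ev_at)) {  # right-to-left keeps earlier positions valid
        len <- sample(seq.int(indel_len_range[1], indel_len_range[2]), 1L)
        if (runif(1) < 0.5) {
          q <- append(q, sample(bases, len, replace = TRUE), after = pos - 1L)
        } else {
          q <- q[-(pos:min(length(q), pos + len - 1L))]
        }
      }
      q
    }
    cores <- replicate(n_blocks, sample(bases, block_length, replace = TRUE),
                       simplify = FALSE)
    qblocks <- lapply(cores, mutate)
    ndup <- round(dup_fraction * n_blocks)
    dup_of <- if (ndup > 0) sample.int(n_blocks, ndup) else integer()
    qlist <- c(qblocks, lapply(dup_of, function(i) mutate(cores[[i]])))
    qorder <- sample(length(qlist))

    spacer <- function() sample(bases, spacer_length, replace = TRUE)
    tpieces <- list(spacer())
    tpos <- integer(n_blocks)
    at <- spacer_length
    for (i in seq_len(n_blocks)) {
      tpos[i] <- at
      tpieces <- c(tpieces, list(cores[[i]], spacer()))
      at <- at + block_length + spacer_length
    }
    qpieces <- list(spacer())
    qpos <- integer(length(qlist))
    at <- spacer_length
    for (j in seq_along(qorder)) {
      idx <- qorder[j]
      qpos[idx] <- at
      qpieces <- c(qpieces, list(qlist[[idx]], spacer()))
      at <- at + length(qlist[[idx]]) + spacer_length
    }
    src <- c(seq_len(n_blocks), dup_of)
    blocks <- data.frame(block = src,
                         tstart = tpos[src],
                         tend = tpos[src] + block_length,
                         qstart = qpos, qlen = lengths(qlist))
    list(target = paste(unlist(tpieces), collapse = ""),
         query = paste(unlist(qpieces), collapse = ""),
         blocks = blocks, seed = seed)
  })
}

#' Write simulated fixtures to disk
#'
#' @param pair A list from [simulate_pair()] or
#'   [simulate_rearranged_pair()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written (`target.fa`, `query.fa` and, for
#'   [simulate_pair()] output, a `truth.bed` with the core intervals).
#' @export
write_pair_fasta <- function(pair, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpath <- file.path(dir, paste0(prefix, ".target.fa"))
  qpath <- file.path(dir, paste0(prefix, ".query.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(target = pair$target)), tpath)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(query = pair$query)), qpath)
  paths <- c(target = tpath, query = qpath)
  if (!is.null(pair$truth)) {
    bed <- file.path(dir, paste0(prefix, ".truth.bed"))
    writeLines(c(
      sprintf("target\t%d\t%d\tcore", pair$truth$target_core[1],
              pair$truth$target_core[2]),
      sprintf("query\t%d\t%d\tcore", pair$truth$query_core[1],
              pair$truth$query_core[2])), bed)
    paths <- c(paths, truth = bed)
  }
  invisible(paths)
}
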