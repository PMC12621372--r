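test_that("anchor midpoints and diagonal keys follow the strand rule", {
  # internal 0-based records; '+' key is target - query, '-' key is sum
  r <- segments_df("t", 10, 20, "q", 110, 120, "+", 1)
  a <- anchor_of(r)
  expect_equal(a$target_mid, 15L)
  expect_equal(a$query_mid, 115L)
  expect_equal(a$diag_key, -100L)

  a <- anchor_of(segments_df("t", 10, 20, "q", 110, 120, "-", 1))
  expect_equal(a$diag_key, 130L)

  # degenerate single-base HSP
  a <- anchor_of(segments_df("t", 7, 8, "q", 3, 4, "+", 1))
  expect_equal(c(a$target_mid, a$query_mid, a$diag_key), c(7L, 3L, 4L))
})

test_that("diagonal partitioning cuts sorted keys greedily", {
  # 10 forward anchors on 10 distinct diagonals; expected cut computed by
  # sorting the keys by hand below (independent of the implementation)
  withr::local_seed(7)
  ts <- sample.int(1000L, 10L)
  qs <- sample.int(1000L, 10L)
  recs <- segments_df("t", ts, ts + 10L, "q", qs, qs + 10L, "+", 1L)
  keys <- (ts + 5L) - (qs + 5L)
  stopifnot(!anyDuplicated(keys))
  parts <- partition_by_diagonal(recs, 5L)
  expect_length(parts, 2L)
  expect_equal(vapply(parts, `[[`, integer(1), "n"), c(5L, 5L))
  got_first <- sort(anchors(parts[[1]]$records)$diag_key)
  expect_equal(got_first, sort(keys)[1:5])

  expect_length(partition_by_diagonal(segments_df(), 5L), 0L)

  # strands are partitioned independently; no split when max_size >= n
  recs2 <- rbind(segments_df("t", c(0, 100, 200), c(50, 150, 250),
                             "q", c(0, 100, 200), c(50, 150, 250), "+", 1L),
                 segments_df("t", c(300, 400), c(350, 450),
                             "q", c(300, 400), c(350, 450), "-", 1L))
  parts2 <- partition_by_diagonal(recs2, 100L)
  expect_length(parts2, 2L)
  expect_equal(vapply(parts2, `[[`, character(1), "strand"), c("+", "-"))
})

test_that("row-wise baseline cuts by target order, not diagonal order", {
  # anchors on one diagonal spread over rows -> singletons ordered by row
  ts <- c(50L, 10L, 30L)
  recs <- segments_df("t", ts, ts + 10L, "q", ts, ts + 10L, "+", 1L)
  parts <- partition_rowwise(recs, 1L)
  expect_length(parts, 3L)
  expect_equal(vapply(parts, function(p) p$records$tstart, integer(1)),
               sort(ts))

  withr::local_seed(8)
  ts <- sample.int(1000L, 12L); qs <- sample.int(1000L, 12L)
  recs <- segments_df("t", ts, ts + 10L, "q", qs, qs + 10L, "+", 1L)
  d <- partition_by_diagonal(recs, 4L)
  r <- partition_rowwise(recs, 4L)
  # row partitions are contiguous in target_mid (brute-force sort check)
  rmids <- lapply(r, function(p) sort(anchors(p$records)$target_mid))
  expect_equal(unlist(rmids), sort(ts + 5L))
  # same record universe either way
  key <- function(parts) sort(unlist(lapply(parts, function(p)
    paste(p$records$tstart, p$records$qstart))))
  expect_equal(key(d), key(r))
})

test_that("partitioning conserves records and respects the size bound", {
  withr::local_seed(9)
  for (i in 1:25) {
    n <- sample(1:400, 1)
    max_size <- sample(1:50, 1)
    recs <- rand_segments(n)
    for (fun in list(partition_by_diagonal, partition_rowwise)) {
      parts <- fun(recs, max_size)
      expect_true(all(vapply(parts, `[[`, integer(1), "n") <= max_size))
      got <- do.call(rbind, lapply(parts, function(p) base_cols(p$records)))
      expect_equal(got[do.call(order, got), ],
                   base_cols(recs)[do.call(order, base_cols(recs)), ],
                   ignore_attr = TRUE)
      expect_true(all(vapply(parts, function(p)
        length(unique(p$records$strand)) == 1L, logical(1))))
    }
  }
})

test_that("same-strand diagonal bands never interleave", {
  withr::local_seed(10)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    recs <- rand_segments(n)
    parts <- partition_by_diagonal(recs, sample(1:20, 1))
    for (s in c("+", "-")) {
      ps <- Filter(function(p) p$strand == s, parts)
      if (length(ps) < 2L) next
      ps <- ps[order(vapply(ps, `[[`, integer(1), "diag_min"))]
      for (j in seq_len(length(ps) - 1L)) {
        # ranges may only touch where one diagonal spills over the cap
        expect_lte(ps[[j]]$diag_max, ps[[j + 1L]]$diag_min)
      }
    }
  }
})

test_that("forward partition membership is invariant under translation", {
  withr::local_seed(11)
  recs <- rand_segments(120L, mixed_strands = FALSE)
  membership <- function(recs, delta) {
    shifted <- recs
    shifted$tstart <- shifted$tstart + delta; shifted$tend <- shifted$tend + delta
    shifted$qstart <- shifted$qstart + delta; shifted$qend <- shifted$qend + delta
    parts <- partition_by_diagonal(shifted, 13L)
    lapply(parts, function(p) paste(p$records$tstart - delta,
                                    p$records$qstart - delta))
  }
  expect_equal(membership(recs, 0L), membership(recs, 5000L))
})

test_that("partitioning a strand subset matches that strand's partitions of the full run", {
  withr::local_seed(12)
  recs <- rand_segments(150L)
  full <- partition_by_diagonal(recs, 9L)
  fwd_only <- partition_by_diagonal(recs[recs$strand == "+", , drop = FALSE], 9L)
  fwd_of_full <- Filter(function(p) p$strand == "+", full)
  expect_equal(lapply(fwd_of_full, function(p) base_cols(p$records)),
               lapply(fwd_only, function(p) base_cols(p$records)),
               ignore_attr = TRUE)
})

test_that("adaptive sizing takes the nearest-rank upper quartile of history", {
  expect_equal(adaptive_max_size(size_policy("adaptive",
                                             history = c(100, 200, 300, 400))),
               300L)
  expect_equal(adaptive_max_size(size_policy("adaptive", default_max = 20000L)),
               20000L)
  expect_equal(adaptive_max_size(size_policy("adaptive", history = c(7, 7, 7))),
               7L)
  expect_equal(adaptive_max_size(size_policy("fixed", fixed_max = 42L,
                                             history = c(1, 2, 3))),
               42L)
})

test_that("adaptive sizing agrees with the type-1 quantile oracle", {
  withr::local_seed(13)
  for (i in 1:1000) {
    h <- sample.int(50000L, sample(1:40, 1), replace = TRUE)
    expect_equal(adaptive_max_size(size_policy("adaptive", history = h)),
                 unname(stats::quantile(h, 0.75, type = 1)))
  }
})

test_that("split_segment_file passes small files through and splits big ones", {
  withr::local_seed(14)
  dir <- withr::local_tempdir()
  # below threshold: single output identical modulo dialect
  recs <- rand_segments(4L)
  p <- file.path(dir, "small.segments")
  write_segments(recs, p)
  res <- split_segment_file(p, size_policy("fixed", fixed_max = 10L), dir)
  expect_length(res$files, 1L)
  expect_identical(base_cols(read_segments(res$files)), base_cols(recs))
  expect_equal(res$policy$history, 4L)

  # 12 single-strand records on distinct diagonals, max 5 -> files of 5,5,2
  ts <- (1:12) * 50L
  qs <- rev(ts)
  recs <- segments_df("t", ts, ts + 10L, "q", qs, qs + 10L, "+", 1L)
  p <- file.path(dir, "big.segments")
  write_segments(recs, p)
  res <- split_segment_file(p, size_policy("fixed", fixed_max = 5L), dir)
  expect_length(res$files, 3L)
  expect_equal(res$manifest$size, c(5L, 5L, 2L))
  back <- do.call(rbind, lapply(res$files, read_segments))
  expect_equal(base_cols(back)[order(back$tstart), ],
               base_cols(recs)[order(recs$tstart), ], ignore_attr = TRUE)

  # strategy none never splits
  res <- split_segment_file(p, size_policy("fixed", fixed_max = 5L), dir,
                            strategy = "none")
  expect_length(res$files, 1L)
})

test_that("a shared folder can seed the adaptive history", {
  dir <- withr::local_tempdir()
  withr::local_seed(15)
  for (n in c(20L, 40L, 60L, 80L)) {
    write_segments(rand_segments(n), file.path(dir, paste0("f", n, ".segments")))
  }
  pol <- size_policy_from_dir(dir)
  expect_length(pol$history, 4L)
  # byte estimates of equal-ish width rows are near the true counts
  expect_true(all(abs(sort(pol$history) - c(20L, 40L, 60L, 80L)) <= 8L))
})
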