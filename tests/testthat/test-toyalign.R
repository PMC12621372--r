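test_that("simulated pairs honour the construction contract", {
  # zero divergence, no indels: cores identical
  p <- simulate_pair(500, divergence = 0, indel_rate = 0, flank_length = 100,
                     seed = 1)
  tc <- substr(p$target, p$truth$target_core[1] + 1, p$truth$target_core[2])
  qc <- substr(p$query, p$truth$query_core[1] + 1, p$truth$query_core[2])
  expect_identical(tc, qc)

  # lengths: flanks + core exactly on target, query +/- indel drift
  p <- simulate_pair(1000, divergence = 0.05, indel_rate = 0.01, seed = 2)
  expect_equal(nchar(p$target), 3000L)
  expect_lt(abs(nchar(p$query) - 3000L), 200L)

  # determinism
  p2 <- simulate_pair(1000, divergence = 0.05, indel_rate = 0.01, seed = 2)
  expect_identical(p, p2)
  p3 <- simulate_pair(1000, divergence = 0.05, indel_rate = 0.01, seed = 3)
  expect_false(identical(p$target, p3$target))
})

test_that("realized mismatch fraction matches the divergence setting", {
  n <- 10000L
  p <- simulate_pair(n, divergence = 0.10, indel_rate = 0, flank_length = 0,
                     seed = 4)
  mm <- mean(strsplit(p$target, "")[[1]] != strsplit(p$query, "")[[1]])
  se <- sqrt(0.10 * 0.90 / n)
  expect_lt(abs(mm - 0.10), 3 * se)
})

test_that("exact k-mer seeding matches the brute-force oracle on both strands", {
  # identical 30-mers: 21 forward matches on one diagonal
  withr::local_seed(41)
  s <- rand_dna(30)
  seeds <- find_seeds(s, s, 10L)
  fwd <- seeds[seeds$strand == "+", ]
  expect_gte(nrow(fwd), 21L)  # self-repeats may add off-diagonal hits
  expect_equal(sum(fwd$tpos == fwd$qpos), 21L)

  # disjoint alphabets of k-mers
  expect_equal(nrow(find_seeds(strrep("A", 30), strrep("C", 30), 10L)), 0L)

  # random small pairs, including a planted reverse-complement match
  for (i in 1:10) {
    t <- rand_dna(60)
    insert <- substr(t, 21, 40)
    q <- paste0(rand_dna(15), rc_string(insert), rand_dna(15))
    got <- find_seeds(t, q, 12L)
    want <- brute_seeds(t, q, 12L)
    key <- function(df) sort(paste(df$tpos, df$qpos, df$strand))
    expect_equal(key(got), key(want))
    expect_true(any(want$strand == "-"))
  }
})

test_that("x-drop ungapped extension recovers exact regions and bare seeds", {
  model <- unit_model(x_drop = 5L, k = 4L)
  # seed inside a long exact match extends across the whole region
  withr::local_seed(42)
  region <- rand_dna(40)
  t <- paste0(strrep("A", 20), region, strrep("A", 20))
  q <- paste0(strrep("C", 20), region, strrep("C", 20))
  rec <- ungapped_extend(t, q, list(tpos = 30L, qpos = 30L, strand = "+"),
                         model)
  expect_equal(c(rec$tstart, rec$tend), c(20L, 60L))
  expect_equal(rec$score, 40L)

  # all-mismatch context: HSP equals the bare seed span
  t2 <- paste0(strrep("A", 20), "GGGG", strrep("A", 20))
  q2 <- paste0(strrep("C", 20), "GGGG", strrep("C", 20))
  rec2 <- ungapped_extend(t2, q2, list(tpos = 20L, qpos = 20L, strand = "+"),
                          model)
  expect_equal(c(rec2$tstart, rec2$tend), c(20L, 24L))
  expect_equal(rec2$score, 4L)
})

test_that("x-drop extension maximises over spans (one-mismatch region)", {
  # 40 bp homologous region with one mismatch under +1/-1: best span is the
  # whole region, score 38; verified against exhaustive span enumeration
  model <- unit_model(x_drop = 5L, k = 4L)
  withr::local_seed(43)
  region_t <- rand_dna(40)
  region_q <- region_t
  substr(region_q, 18, 18) <- chartr("ACGT", "GTAC", substr(region_q, 18, 18))
  stopifnot(substr(region_q, 18, 18) != substr(region_t, 18, 18))
  t <- paste0(strrep("A", 30), region_t, strrep("A", 30))
  q <- paste0(strrep("C", 30), region_q, strrep("C", 30))
  rec <- ungapped_extend(t, q, list(tpos = 50L, qpos = 50L, strand = "+"),
                         model)

  # oracle: best-scoring span containing the seed, by enumeration
  tv <- strsplit(t, "")[[1]]; qv <- strsplit(q, "")[[1]]
  col <- ifelse(tv == qv, 1L, -1L)
  best <- -Inf
  for (a in 1:51) for (b in 54:length(col))
    best <- max(best, sum(col[a:b]))
  expect_equal(best, 38L)
  expect_equal(rec$score, 38L)
  expect_equal(c(rec$tstart, rec$tend), c(30L, 70L))
})

test_that("single-anchor gapped extension matches the full affine-gap oracle", {
  model <- score_model(y_drop = 1e9)
  withr::local_seed(44)
  for (i in 1:12) {
    n <- sample(40:200, 1)
    t <- rand_dna(n)
    # derive q from t with substitutions and an indel so gaps matter
    qv <- strsplit(t, "")[[1]]
    mut <- sample(n, round(0.05 * n))
    qv[mut] <- sample(c("A", "C", "G", "T"), length(mut), TRUE)
    if (i %% 2 == 0) {
      at <- sample(5:(n - 5), 1)
      qv <- append(qv, sample(c("A", "C", "G", "T"), 3, TRUE), after = at)
    } else {
      at <- sample(5:(n - 8), 1)
      qv <- qv[-(at:(at + 2))]
    }
    q <- paste(qv, collapse = "")
    rec <- segments_df("t", 0, 4, "q", 0, 4, "+", 1)
    aln <- gapped_extend(t, q, rec, model)[[1]]
    # oracle: full-matrix forward + backward from the anchor (2, 2)
    tc <- diagpart:::encode_dna(t); qc <- diagpart:::encode_dna(q)
    anchor <- model$matrix[tc[3] + 1, qc[3] + 1]
    fwd <- affine_extension_oracle(tc[4:length(tc)], qc[4:length(qc)], model)
    bwd <- affine_extension_oracle(rev(tc[1:2]), rev(qc[1:2]), model)
    expect_equal(aln$score, anchor + fwd + bwd)
    expect_equal(score_alignment(aln, t, q, model), aln$score)
  }
})

test_that("every alignment's stored score equals recomputation from its columns", {
  model <- score_model()
  pair <- simulate_pair(5000, divergence = 0.05, indel_rate = 0.02, seed = 45)
  recs <- seed_and_filter(pair$target, pair$query, model)
  expect_gt(nrow(recs), 5L)
  alns <- gapped_extend(pair$target, pair$query, recs, model,
                        suppress = FALSE)
  expect_length(alns, nrow(recs))
  for (a in alns)
    expect_equal(score_alignment(a, pair$target, pair$query, model), a$score)
})

test_that("anchor-crossing suppression collapses co-linear anchors", {
  model <- score_model()
  pair <- simulate_pair(4000, divergence = 0.02, indel_rate = 0.01, seed = 46)
  recs <- seed_and_filter(pair$target, pair$query, model)
  expect_gt(nrow(recs), 2L)
  alns <- gapped_extend(pair$target, pair$query, recs, model)
  # output never exceeds anchor count; with suppression off it equals it
  expect_lte(length(alns), nrow(recs))
  expect_length(gapped_extend(pair$target, pair$query, recs, model,
                              suppress = FALSE), nrow(recs))
  expect_length(gapped_extend(pair$target, pair$query, segments_df(), model),
                0L)
})

test_that("splitting dependent anchors across jobs creates straddling alignments", {
  # two anchors on one homology: together 1 alignment, apart 2 overlapping
  model <- score_model()
  pair <- simulate_pair(3000, divergence = 0.02, indel_rate = 0.01, seed = 47)
  recs <- seed_and_filter(pair$target, pair$query, model)
  expect_gte(nrow(recs), 2L)
  two <- recs[1:2, ]
  together <- gapped_extend(pair$target, pair$query, two, model)
  expect_length(together, 1L)
  apart <- c(gapped_extend(pair$target, pair$query, two[1, ], model),
             gapped_extend(pair$target, pair$query, two[2, ], model))
  expect_length(apart, 2L)
  # the two independent extensions overlap on the target
  expect_lt(max(apart[[1]]$tstart, apart[[2]]$tstart),
            min(apart[[1]]$tend, apart[[2]]$tend))
})

test_that("out-of-window anchors are reported by record index", {
  model <- score_model()
  rec <- segments_df("t", 100, 120, "q", 100, 120, "+", 1)
  expect_error(gapped_extend(rand_dna(200), rand_dna(200), rec, model,
                             t_window = c(0L, 50L)),
               "record 1")
})
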