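# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (brute force / full matrices) and never
# call the code paths they check.

rand_segments <- function(n, coord_max = 100000L, mixed_strands = TRUE) {
  ts <- sample.int(coord_max, n, replace = TRUE)
  qs <- sample.int(coord_max, n, replace = TRUE)
  len <- sample.int(200L, n, replace = TRUE)
  segments_df(
    target_name = rep("t", n), tstart = ts, tend = ts + len,
    query_name = rep("q", n), qstart = qs, qend = qs + len,
    strand = if (mixed_strands) sample(c("+", "-"), n, replace = TRUE)
             else rep("+", n),
    score = sample.int(10000L, n, replace = TRUE))
}

base_cols <- function(df) {
  df <- df[, c("target_name", "tstart", "tend", "query_name", "qstart",
               "qend", "strand", "score")]
  rownames(df) <- NULL
  df
}

rc_string <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# brute-force all-pairs k-mer matcher over both query orientations
brute_seeds <- function(target, query, k) {
  qrc <- rc_string(query)
  qlen <- nchar(query)
  hits <- list()
  for (i in 0:(nchar(target) - k)) {
    tk <- substr(target, i + 1, i + k)
    for (j in 0:(qlen - k)) {
      if (tk == substr(query, j + 1, j + k))
        hits[[length(hits) + 1L]] <- data.frame(tpos = i, qpos = j,
                                                strand = "+")
      if (tk == substr(qrc, j + 1, j + k))
        hits[[length(hits) + 1L]] <- data.frame(tpos = i,
                                                qpos = qlen - k - j,
                                                strand = "-")
    }
  }
  if (length(hits) == 0L)
    return(data.frame(tpos = integer(), qpos = integer(),
                      strand = character()))
  do.call(rbind, hits)
}

# full (unbanded, unpruned) affine-gap extension oracle: best score of any
# prefix alignment of t x q starting at the origin, floor 0
affine_extension_oracle <- function(t, q, model) {
  if (is.character(t)) t <- diagpart:::encode_dna(t)
  if (is.character(q)) q <- diagpart:::encode_dna(q)
  n <- length(t); m <- length(q)
  NEG <- -1e9
  go <- model$gap_open + model$gap_extend
  ge <- model$gap_extend
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (m > 0) for (j in 2:(m + 1)) X[1, j] <- max(M[1, j - 1] - go, X[1, j - 1] - ge)
  if (n > 0) for (i in 2:(n + 1)) {
    Y[i, 1] <- max(M[i - 1, 1] - go, Y[i - 1, 1] - ge)
    if (m > 0) for (j in 2:(m + 1)) {
      s <- model$matrix[t[i - 1] + 1, q[j - 1] + 1]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i, j - 1] - go, X[i, j - 1] - ge, Y[i, j - 1] - go)
      Y[i, j] <- max(M[i - 1, j] - go, X[i - 1, j] - go, Y[i - 1, j] - ge)
    }
  }
  max(0, M, X, Y)
}

# brute-force optimal makespan: enumerate all m^n assignments via base-m
# digit expansion (vectorised); feasible for n <= 10, m <= 3
opt_makespan <- function(lengths, m) {
  n <- length(lengths)
  if (m == 1L) return(sum(lengths))
  total <- m^n
  codes <- 0:(total - 1)
  loads <- matrix(0, total, m)
  for (item in seq_len(n)) {
    digit <- codes %% m
    codes <- codes %/% m
    for (b in 0:(m - 1))
      loads[, b + 1] <- loads[, b + 1] + (digit == b) * lengths[item]
  }
  min(apply(loads, 1, max))
}

# simple +1/-1 scoring used where hand-computable scores are wanted
unit_model <- function(x_drop = 5L, k = 4L, hsp_thresh = 1L) {
  m <- matrix(-1L, 4, 4); diag(m) <- 1L
  score_model(matrix = m, gap_open = 3L, gap_extend = 1L, x_drop = x_drop,
              y_drop = 20L, k = k, hsp_thresh = hsp_thresh)
}
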