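#' Scoring models for the toy aligner
#'
#' `score_model()` bundles everything the seeding/extension engine needs: a
#' nucleotide substitution matrix, affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_extend`), the x-drop and y-drop termination
#' thresholds for gap-free and gapped extension, the seed length `k`, and
#' the minimum score `hsp_thresh` an ungapped extension must reach to be
#' kept as an HSP. Defaults follow common practice for distant-vertebrate
#' alignment: the HOXD70 matrix with gap open 400 / extend 30, `k = 12`,
#' `x_drop = 300`, `y_drop = 3000`, `hsp_thresh = 3000`.
#'
#' @param matrix 4x4 integer substitution matrix (rows/cols A, C, G, T)
#'   with positive diagonal.
#' @param gap_open,gap_extend Non-negative affine gap penalties.
#' @param x_drop,y_drop Positive termination thresholds for ungapped and
#'   gapped extension.
#' @param k Seed length (>= 4).
#' @param hsp_thresh Minimum ungapped-extension score for a kept HSP.
#' @return A `score_model` list. The stored `$matrix` is a 5x5 matrix whose
#'   first row/column handle unknown characters (code 0) at a large
#'   penalty.
#' @examples
#' m <- score_model()
#' m$matrix[2:5, 2:5]  # HOXD70
#' @export
score_model <- function(matrix = hoxd70(), gap_open = 400L, gap_extend = 30L,
                        x_drop = 300L, y_drop = 3000L, k = 12L,
                        hsp_thresh = 3000L) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4L, ncol(matrix) == 4L)
  if (any(diag(matrix) <= 0)) stop("match scores (matrix diagonal) must be positive")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be non-negative")
  if (x_drop <= 0 || y_drop <= 0) stop("drop thresholds must be positive")
  if (k < 4) stop("seed length k must be >= 4")
  m5 <- matrix(-2000L, 5L, 5L)
  m5[2:5, 2:5] <- as.integer(matrix)
  structure(list(matrix = m5, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 x_drop = as.integer(x_drop), y_drop = as.integer(y_drop),
                 k = as.integer(k), hsp_thresh = as.integer(hsp_thresh)),
            class = "score_model")
}

#' @rdname score_model
#' @export
hoxd70 <- function() {
  m <- matrix(c(
     91, -114,  -31, -123,
   -114,  100, -125,  -31,
    -31, -125,  100, -114,
   -123,  -31, -114,   91), 4, 4, byrow = TRUE)
  dimnames(m) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  m
}

# --- sequence codes -------------------------------------------------------
# Sequences are handled internally as integer vectors: A=1 C=2 G=3 T=4,
# anything else 0. Complement of code c in 1..4 is 5-c.

encode_dna <- function(x) {
  if (length(x) == 1L && nchar(x) != 1L) x <- strsplit(x, "")[[1]]
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(paste(x, collapse = ""))]
}

decode_dna <- function(codes) {
  chars <- c("N", "A", "C", "G", "T")
  paste(chars[codes + 1L], collapse = "")
}

revcomp_codes <- function(codes) {
  out <- rev(codes)
  nz <- out > 0L
  out[nz] <- 5L - out[nz]
  out
}
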