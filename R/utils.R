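# Internal helpers: seed scoping, rounding, Hamming machinery.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a per-stage seed from a pipeline seed.
# Kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + h * 7919 + 1) %% 2147483647)
}

# round() in R rounds half to even; tabulated percentages use half-up.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Pairwise Hamming distance matrix for equal-length strings.
# Accumulates position-wise mismatch counts, so cost is L dense outer
# products rather than an n^2 string loop.
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(0L, 0L, 0L))
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) stop("hamming_matrix() requires equal-length strings")
  if (L == 0L) return(matrix(0L, n, n))
  m <- matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = L)
  d <- matrix(0L, n, n)
  for (j in seq_len(L)) {
    d <- d + outer(m[j, ], m[j, ], "!=")
  }
  storage.mode(d) <- "integer"
  d
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming() requires equal-length strings")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
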