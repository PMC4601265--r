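#' Build a synthetic germline segment database
#'
#' Creates the universe of V and J gene segments, per-isotype constant-region
#' nucleotide sequences, and isotype subclass sets used by the repertoire
#' simulator. Segment names follow IGHV/IGHJ-style labels.
#'
#' @param n_v Number of V gene segments (>= 1).
#' @param n_j Number of J gene segments (>= 1).
#' @param constant_length Length (nt) of each simulated constant region.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   database bit-for-bit.
#'
#' @return An object of class `germline_db`: a list with elements
#'   `v_genes` (data.frame: name, allele), `j_genes` (data.frame: name,
#'   allele), `constant_regions` (named character, one nucleotide sequence
#'   per isotype) and `subclass_sets` (named list of subclass labels per
#'   isotype).
#' @examples
#' db <- make_germline_db(10, 4, seed = 1)
#' db$v_genes$name
#' @export
make_germline_db <- function(n_v, n_j, constant_length = 300, seed = NULL) {
  if (!is.numeric(n_v) || length(n_v) != 1L || n_v < 1)
    stop("n_v must be a positive count")
  if (!is.numeric(n_j) || length(n_j) != 1L || n_j < 1)
    stop("n_j must be a positive count")
  n_v <- as.integer(n_v)
  n_j <- as.integer(n_j)
  with_seed(seed, {
    fam <- ((seq_len(n_v) - 1L) %% 7L) + 1L
    idx <- stats::ave(seq_len(n_v), fam, FUN = seq_along)
    v <- data.frame(
      name = sprintf("IGHV%d-%d", fam, idx),
      allele = sprintf("IGHV%d-%d*01", fam, idx),
      stringsAsFactors = FALSE
    )
    j <- data.frame(
      name = sprintf("IGHJ%d", seq_len(n_j)),
      allele = sprintf("IGHJ%d*01", seq_len(n_j)),
      stringsAsFactors = FALSE
    )
    isotypes <- c("IgA", "IgG", "IgM")
    cr <- vapply(isotypes, function(i) {
      paste(sample(c("A", "C", "G", "T"), constant_length, replace = TRUE),
            collapse = "")
    }, character(1))
    db <- list(
      v_genes = v,
      j_genes = j,
      constant_regions = cr,
      subclass_sets = list(
        IgA = c("IgA1", "IgA2"),
        IgG = c("IgG1", "IgG2", "IgG3", "IgG4"),
        IgM = "IgM"
      )
    )
    class(db) <- "germline_db"
    db
  })
}

#' @export
print.germline_db <- function(x, ...) {
  cat("Germline database:", nrow(x$v_genes), "V genes,",
      nrow(x$j_genes), "J genes\n")
  cat("Isotypes:", paste(names(x$constant_regions), collapse = ", "), "\n")
  invisible(x)
}
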