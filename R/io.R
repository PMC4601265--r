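# Readers/writers for the plain-text interchange formats: AIRR-style
# rearrangement TSV, FASTQ (via Biostrings), constant-region FASTA, and
# two-column antigen reference lists.

AIRR_COLUMNS <- c("sequence_id", "v_call", "j_call", "cdr3_aa",
                  "v_mutation_count", "isotype", "subclass",
                  "c_region_mismatches", "c_region_length")

#' Read an AIRR-style rearrangement table
#'
#' Tab-delimited, one row per sequence, with columns `sequence_id`, `v_call`,
#' `j_call`, `cdr3_aa`, `v_mutation_count`, `isotype`, `subclass`,
#' `c_region_mismatches`, `c_region_length`.
#'
#' @param path File path.
#' @param participant,day,isotype,replicate Optional sample labels; if
#'   missing they are left `NA` on the returned sample.
#' @return A [repertoire_sample()] data.frame.
#' @export
read_airr <- function(path, participant = NA, day = NA, isotype = NA,
                      replicate = NA) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(AIRR_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing AIRR columns: ", paste(missing_cols, collapse = ", "))
  repertoire_sample(df, participant = participant, day = day,
                    isotype = isotype, replicate = replicate)
}

#' Write a rearrangement table as AIRR-style TSV
#'
#' @param x A `repertoire_sample` data.frame or a `read_set` (its records
#'   are written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(x, path) {
  if (inherits(x, "read_set")) x <- x$records
  utils::write.table(as.data.frame(x)[, AIRR_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FASTQ reads with per-base qualities
#'
#' @param path FASTQ file (Sanger Phred+33).
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read germline constant-region sequences from FASTA
#'
#' @param path FASTA file with one record per isotype.
#' @return Named character vector of nucleotide sequences.
#' @export
read_constant_regions <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read an antigen reference CDR3 list
#'
#' Two-column TSV: `antigen` label and `cdr3_aa` amino-acid sequence, e.g.
#' published tetanus-toxoid- or influenza-specific CDR3s.
#'
#' @param path File path.
#' @return data.frame with columns `antigen`, `cdr3_aa` (uppercased).
#' @export
read_antigen_references <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("antigen", "cdr3_aa") %in% names(df)))
    stop("reference list needs columns 'antigen' and 'cdr3_aa'")
  if (nrow(df) == 0) stop("empty antigen reference list")
  df$cdr3_aa <- toupper(df$cdr3_aa)
  df
}
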