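# Quality filtering, fixed-depth subsampling and constant-region error-rate
# estimation.

#' Construct a repertoire sample
#'
#' A repertoire sample is a data.frame of annotated sequence records (one row
#' per sequence) with sample-level labels (participant, day, isotype,
#' replicate) attached as attributes.
#'
#' @param records data.frame with at least the columns `sequence_id`,
#'   `v_call`, `j_call`, `cdr3_aa`; analyses additionally use
#'   `v_mutation_count`, `subclass`, `c_region_mismatches`,
#'   `c_region_length`, `isotype` when present.
#' @param participant,day,isotype,replicate Sample labels.
#' @return The records data.frame with class `repertoire_sample` and label
#'   attributes.
#' @export
repertoire_sample <- function(records, participant = NA, day = NA,
                              isotype = NA, replicate = NA) {
  stopifnot(is.data.frame(records))
  need <- c("sequence_id", "v_call", "j_call", "cdr3_aa")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  structure(records,
            participant = participant, day = day, isotype = isotype,
            replicate = replicate,
            class = c("repertoire_sample", "data.frame"))
}

sample_label <- function(s) {
  paste(attr(s, "participant") %||% NA, attr(s, "day") %||% NA,
        attr(s, "isotype") %||% NA, attr(s, "replicate") %||% NA,
        sep = "|")
}

#' Quality-filter raw reads
#'
#' A read passes iff it contains no ambiguous base (`N`) and at most a
#' fraction `max_low_q_fraction` of its bases have Phred quality below
#' `q_threshold`. The boundary is inclusive: exactly 15% of bases below Q30
#' still passes (the rule rejects *more than* 15%), and a base at exactly
#' Q30 is a passing base.
#'
#' @param reads data.frame with columns `sequence`, `quality` (Sanger
#'   Phred+33 strings), e.g. from [read_fastq()] or [simulate_fastq()].
#' @param max_low_q_fraction Maximum tolerated fraction of low-quality bases.
#' @param q_threshold Phred score below which a base counts as low quality.
#' @return List with `passed` (the passing subset of `reads`) and `summary`
#'   (counts of input, passed, rejected for N, rejected for quality).
#' @examples
#' reads <- simulate_fastq(100, seed = 1)
#' quality_filter(reads)$summary
#' @export
quality_filter <- function(reads, max_low_q_fraction = 0.15,
                           q_threshold = 30) {
  stopifnot(is.data.frame(reads),
            all(c("sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence/quality length mismatch")
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  low_frac <- vapply(reads$quality, function(q) {
    phred <- utf8ToInt(q) - 33L
    mean(phred < q_threshold)
  }, numeric(1), USE.NAMES = FALSE)
  low_q <- low_frac > max_low_q_fraction
  pass <- !has_n & !low_q
  list(
    passed = reads[pass, , drop = FALSE],
    summary = c(input = nrow(reads), passed = sum(pass),
                rejected_ambiguous = sum(has_n),
                rejected_quality = sum(low_q & !has_n))
  )
}

#' Subsample a repertoire to fixed depth
#'
#' Uniform sampling without replacement to exactly `depth` sequences, so that
#' samples of different sequencing yield are comparable. Subsampling is done
#' per sample (per participant/isotype/replicate/day), never on pooled data.
#'
#' @param records A `repertoire_sample` or plain records data.frame.
#' @param depth Target depth (default 100,000 sequences).
#' @param seed Optional integer seed.
#' @return A `repertoire_sample` with exactly `depth` rows (labels carried
#'   over).
#' @export
subsample <- function(records, depth = 100000, seed = NULL) {
  n <- nrow(records)
  if (n < depth)
    stop("cannot subsample ", depth, " from ", n,
         " records (short by ", depth - n, ")")
  keep <- with_seed(seed, sample.int(n, depth))
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  repertoire_sample(as.data.frame(out),
                    participant = attr(records, "participant"),
                    day = attr(records, "day"),
                    isotype = attr(records, "isotype"),
                    replicate = attr(records, "replicate"))
}

#' Estimate sequencing error rate from constant-region mismatches
#'
#' The constant region is not subject to somatic hypermutation, so mismatches
#' against its germline sequence measure the PCR + sequencing error rate.
#' The estimate is total mismatches / total nucleotides (per group), not a
#' mean of per-read rates.
#'
#' @param records Records data.frame with `c_region_mismatches` and
#'   `c_region_length` columns.
#' @param by Grouping column (default `"isotype"`); `NULL` pools everything.
#' @return Named numeric vector of errors per nucleotide, one per group.
#' @examples
#' df <- data.frame(sequence_id = c("a", "b"), v_call = "V", j_call = "J",
#'                  cdr3_aa = "CARW", isotype = "IgG",
#'                  c_region_mismatches = c(1, 3), c_region_length = 100)
#' estimate_error_rate(df)
#' @export
estimate_error_rate <- function(records, by = "isotype") {
  stopifnot(all(c("c_region_mismatches", "c_region_length") %in% names(records)))
  grp <- if (is.null(by)) rep("all", nrow(records)) else records[[by]]
  mm <- tapply(records$c_region_mismatches, grp, sum)
  nt <- tapply(as.numeric(records$c_region_length), grp, sum)
  if (any(nt == 0)) stop("zero total constant-region length in a group")
  rate <- mm / nt
  setNames(as.numeric(rate), names(rate))
}
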