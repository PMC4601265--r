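# Cross-participant sharing: the public repertoire (clusters present in at
# least two participants), its structural comparison with the private
# repertoire, and antigen-specificity annotation against reference CDR3s.

# Wilcoxon signed-rank p-value on paired per-participant values; degenerate
# all-tied pairs carry no evidence against the null.
paired_signed_rank <- function(x, y) {
  if (all(x == y)) return(1)
  suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
}

#' Per-participant cluster table
#'
#' Expands a joint cluster set into one row per (cluster, participant in
#' which it is present), with the participant-level size, the cluster's
#' mean mutation and CDR3 length, the number of participants sharing the
#' cluster, and the public/private call (public = present in >= 2
#' participants).
#'
#' @param cs A joint `cluster_set` over all participants' samples.
#' @param sample_participants Named vector mapping sample label (see
#'   `cs$samples`) to participant id.
#' @return data.frame with columns `cluster_id`, `participant`, `size`,
#'   `mean_v_mutations` (NA if the set was not [annotate_clusters()]ed),
#'   `cdr3_length`, `n_participants`, `is_public`.
#' @export
participant_cluster_table <- function(cs, sample_participants) {
  stopifnot(inherits(cs, "cluster_set"))
  if (!all(cs$samples %in% names(sample_participants)))
    stop("sample_participants must name every sample in the cluster set")
  m <- cluster_size_matrix(cs)
  part <- sample_participants[colnames(m)]
  uparts <- sort(unique(part))
  by_part <- vapply(uparts, function(p) {
    rowSums(m[, part == p, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(by_part))) by_part <- matrix(by_part, nrow = nrow(m))
  n_participants <- rowSums(by_part > 0)
  info <- cs$clusters
  rows <- which(by_part > 0, arr.ind = TRUE)
  out <- data.frame(
    cluster_id = rownames(m)[rows[, 1]],
    participant = uparts[rows[, 2]],
    size = by_part[rows],
    mean_v_mutations = if (!is.null(info$mean_v_mutations))
      info$mean_v_mutations[rows[, 1]] else NA_real_,
    cdr3_length = info$cdr3_length[rows[, 1]],
    n_participants = n_participants[rows[, 1]],
    stringsAsFactors = FALSE
  )
  out$is_public <- out$n_participants >= 2
  out[order(out$cluster_id, out$participant), ]
}

#' Cross-participant sharing spectrum
#'
#' For each cluster, the number of participants in which it is present
#' (>= 1 member sequence), histogrammed over 1..P, with the percent of
#' total clusters at each sharing level. Public clusters are those shared
#' by at least two participants; private clusters belong to exactly one.
#'
#' @inheritParams participant_cluster_table
#' @return Object of class `sharing_spectrum`: list with `spectrum`
#'   (data.frame: n_participants, clusters, percent), `n_clusters`,
#'   `n_public`, `n_private`, `public_percent`.
#' @export
sharing_spectrum <- function(cs, sample_participants) {
  tab <- participant_cluster_table(cs, sample_participants)
  per_cluster <- tab[!duplicated(tab$cluster_id), ]
  n_parts <- length(unique(tab$participant))
  counts <- vapply(seq_len(n_parts), function(t) {
    sum(per_cluster$n_participants == t)
  }, numeric(1))
  total <- nrow(per_cluster)
  out <- list(
    spectrum = data.frame(n_participants = seq_len(n_parts),
                          clusters = counts,
                          percent = counts / total * 100),
    n_clusters = total,
    n_public = sum(counts[-1]),
    n_private = counts[1],
    public_percent = sum(counts[-1]) / total * 100
  )
  class(out) <- "sharing_spectrum"
  out
}

#' @export
print.sharing_spectrum <- function(x, ...) {
  cat("Sharing spectrum over", nrow(x$spectrum), "participants:",
      x$n_clusters, "clusters,", x$n_public, "public (",
      round(x$public_percent, 2), "% )\n")
  print(x$spectrum, row.names = FALSE)
  invisible(x)
}

#' Compare public and private clusters on a structural metric
#'
#' For each participant, the mean of `metric` over its public clusters and
#' over its private clusters; the per-participant pairs are then compared
#' with the Wilcoxon signed-rank test (the paired analogue of the
#' Mann-Whitney U test). Participants with no public (or no private)
#' clusters are excluded from the pairing with a warning.
#'
#' @param x A `cluster_set` (with `sample_participants` supplied) or a
#'   [participant_cluster_table()] data.frame.
#' @param metric `"size"`, `"mutation"` or `"cdr3_length"`.
#' @param sample_participants Required when `x` is a `cluster_set`.
#' @return Object of class `public_private_test`: list with `per_participant`
#'   (participant, public_mean, private_mean), `public_mean`, `private_mean`,
#'   `public_sem`, `private_sem`, `p_value`, `metric`.
#' @export
public_private_compare <- function(x, metric = c("size", "mutation",
                                                 "cdr3_length"),
                                   sample_participants = NULL) {
  metric <- match.arg(metric)
  tab <- if (inherits(x, "cluster_set")) {
    if (is.null(sample_participants))
      stop("sample_participants required with a cluster_set")
    participant_cluster_table(x, sample_participants)
  } else x
  col <- switch(metric, size = "size", mutation = "mean_v_mutations",
                cdr3_length = "cdr3_length")
  parts <- sort(unique(tab$participant))
  if (length(parts) < 2) stop("need at least 2 participants")
  pp <- do.call(rbind, lapply(parts, function(p) {
    sub <- tab[tab$participant == p, ]
    data.frame(participant = p,
               public_mean = mean(sub[[col]][sub$is_public]),
               private_mean = mean(sub[[col]][!sub$is_public]))
  }))
  bad <- is.nan(pp$public_mean) | is.nan(pp$private_mean) |
    is.na(pp$public_mean) | is.na(pp$private_mean)
  if (any(bad)) {
    warning(sum(bad), " participant(s) without both public and private ",
            "clusters excluded from pairing")
    pp <- pp[!bad, , drop = FALSE]
  }
  if (nrow(pp) < 2) stop("fewer than 2 participants with paired means")
  p_value <- paired_signed_rank(pp$public_mean, pp$private_mean)
  out <- list(
    per_participant = pp,
    public_mean = mean(pp$public_mean),
    private_mean = mean(pp$private_mean),
    public_sem = sd(pp$public_mean) / sqrt(nrow(pp)),
    private_sem = sd(pp$private_mean) / sqrt(nrow(pp)),
    p_value = p_value,
    metric = metric
  )
  class(out) <- "public_private_test"
  out
}

#' @export
print.public_private_test <- function(x, ...) {
  cat("Public vs private clusters on '", x$metric, "' (",
      nrow(x$per_participant), " participants)\n", sep = "")
  cat("  public mean ", signif(x$public_mean, 4), " +/- ",
      signif(x$public_sem, 3), ", private mean ",
      signif(x$private_mean, 4), " +/- ", signif(x$private_sem, 3), "\n",
      sep = "")
  cat("  Wilcoxon signed-rank p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Annotate clusters with putative antigen specificity
#'
#' A cluster is labelled for an antigen iff some reference CDR3 known to be
#' specific for that antigen would have fallen into the cluster during
#' clustering: same CDR3 length and Hamming distance at most
#' [allowed_mismatches()]`(L, k)` from the cluster center. Matching uses
#' CDR3 identity only (V/J are not required to agree). Set
#' `match_members = TRUE` to match against every member CDR3 instead of the
#' center.
#'
#' @param cs A `cluster_set`.
#' @param references data.frame with columns `antigen`, `cdr3_aa` (e.g. from
#'   [read_antigen_references()]).
#' @param k Amino acids per allowed mismatch (same threshold as clustering).
#' @param match_members Match member CDR3s rather than cluster centers.
#' @return data.frame with columns `cluster_id`, `antigen` (one row per
#'   label; zero rows when nothing matches).
#' @export
annotate_specificity <- function(cs, references, k = 12,
                                 match_members = FALSE) {
  stopifnot(inherits(cs, "cluster_set"))
  if (is.null(references) || nrow(references) == 0)
    stop("empty antigen reference list")
  targets <- if (match_members) {
    unique(data.frame(cluster_id = cs$membership$cluster_id,
                      cdr3 = cs$membership$cdr3_aa,
                      stringsAsFactors = FALSE))
  } else {
    data.frame(cluster_id = cs$clusters$cluster_id,
               cdr3 = cs$clusters$center_cdr3, stringsAsFactors = FALSE)
  }
  targets$len <- nchar(targets$cdr3)
  references$len <- nchar(references$cdr3_aa)
  hits <- list()
  for (L in intersect(unique(targets$len), unique(references$len))) {
    tt <- targets[targets$len == L, ]
    rr <- references[references$len == L, ]
    maxmm <- allowed_mismatches(L, k)
    for (i in seq_len(nrow(rr))) {
      ref <- utf8ToInt(rr$cdr3_aa[i])
      d <- vapply(tt$cdr3, function(s) sum(utf8ToInt(s) != ref), numeric(1))
      ok <- d <= maxmm
      if (any(ok)) {
        hits[[length(hits) + 1L]] <- data.frame(
          cluster_id = tt$cluster_id[ok], antigen = rr$antigen[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(cluster_id = character(0), antigen = character(0)))
  out <- unique(do.call(rbind, hits))
  out[order(out$cluster_id, out$antigen), ]
}

#' Specificity enrichment in the public vs private repertoire
#'
#' Per participant, the percent of its public and of its private clusters
#' carrying an antigen-specificity label, compared pairwise across
#' participants with the Wilcoxon signed-rank test.
#'
#' @param cs A `cluster_set`.
#' @param labels Result of [annotate_specificity()].
#' @param sample_participants Named vector mapping sample label to
#'   participant.
#' @return Object of class `public_private_test` where the per-participant
#'   values are labelled percentages (0-100).
#' @export
specificity_enrichment <- function(cs, labels, sample_participants) {
  tab <- participant_cluster_table(cs, sample_participants)
  tab$labelled <- tab$cluster_id %in% labels$cluster_id
  parts <- sort(unique(tab$participant))
  if (length(parts) < 2) stop("need at least 2 participants")
  pp <- do.call(rbind, lapply(parts, function(p) {
    sub <- tab[tab$participant == p, ]
    pub <- sub$is_public
    data.frame(
      participant = p,
      public_mean = if (any(pub)) 100 * mean(sub$labelled[pub]) else NA_real_,
      private_mean = if (any(!pub)) 100 * mean(sub$labelled[!pub]) else NA_real_
    )
  }))
  bad <- is.na(pp$public_mean) | is.na(pp$private_mean)
  if (any(bad)) {
    warning(sum(bad), " participant(s) without both public and private ",
            "clusters excluded from pairing")
    pp <- pp[!bad, , drop = FALSE]
  }
  if (nrow(pp) < 2) stop("fewer than 2 participants with paired percentages")
  p_value <- paired_signed_rank(pp$public_mean, pp$private_mean)
  out <- list(
    per_participant = pp,
    public_mean = mean(pp$public_mean),
    private_mean = mean(pp$private_mean),
    public_sem = sd(pp$public_mean) / sqrt(nrow(pp)),
    private_sem = sd(pp$private_mean) / sqrt(nrow(pp)),
    p_value = p_value,
    metric = "percent_labelled"
  )
  class(out) <- "public_private_test"
  out
}
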