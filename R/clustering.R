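# CDR3 clonal clustering and nearest-neighbour diagnostics.
#
# Sequences belong to the same cluster iff they share V gene, J gene and
# CDR3 length, and their CDR3 amino-acid sequences are connected through
# pairs differing by at most floor(L / k) mismatches (single-linkage
# connected components). k is the "one AA mismatch allowed per k AAs"
# similarity threshold; k = 12 by default.

#' Allowed CDR3 mismatches at a similarity threshold
#'
#' One amino-acid mismatch is allowed per `k` amino acids of CDR3 length:
#' `floor(L / k)`. CDR3s shorter than `k` therefore require exact identity
#' under the default rule; set `at_least_one = TRUE` to always allow one
#' mismatch.
#'
#' @param cdr3_length CDR3 length in amino acids (>= 1); vectorised.
#' @param k Amino acids per allowed mismatch (>= 1).
#' @param at_least_one If `TRUE`, use `max(1, floor(L / k))`.
#' @return Integer vector of allowed mismatch counts.
#' @examples
#' allowed_mismatches(12, 12) # 1
#' allowed_mismatches(24, 12) # 2
#' allowed_mismatches(11, 12) # 0
#' @export
allowed_mismatches <- function(cdr3_length, k = 12, at_least_one = FALSE) {
  if (any(cdr3_length < 1)) stop("cdr3_length must be >= 1")
  if (k < 1) stop("k must be >= 1")
  m <- as.integer(cdr3_length %/% k)
  if (at_least_one) m <- pmax(1L, m)
  m
}

# Row-wise nearest-neighbour distances within one equal-length group,
# block-wise to bound memory on large groups.
group_nn <- function(seqs, block = 512L) {
  g <- length(seqs)
  L <- nchar(seqs[1L])
  m <- matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = L)
  out <- integer(g)
  for (start in seq(1L, g, by = block)) {
    idx <- start:min(start + block - 1L, g)
    d <- matrix(0L, length(idx), g)
    for (j in seq_len(L)) {
      d <- d + outer(m[j, idx], m[j, ], "!=")
    }
    d[cbind(seq_along(idx), idx)] <- NA_integer_  # self
    out[idx] <- apply(d, 1L, min, na.rm = TRUE)
  }
  out
}

#' Nearest-neighbour CDR3 distance distribution
#'
#' For each sequence, the distance to its nearest neighbour: the sequence of
#' the same CDR3 amino-acid length with the fewest Hamming mismatches among
#' all other sequences in the set. Sequences with no same-length comparator
#' are excluded from the histogram and counted separately. On raw sequences
#' this distribution is typically bimodal (a 0-2 AA peak of clonally related
#' or error-derived neighbours, and a more distant peak from unrelated
#' clones); on cluster centers the first peak collapses.
#'
#' @param sequences Character vector of CDR3 amino-acid sequences.
#' @param level Label recording what was compared (`"sequence"` or
#'   `"cluster_center"`).
#' @return An object of class `nn_distribution`: list with `distances`
#'   (named integer, one per comparable sequence), `histogram` (table of
#'   distance -> count), `n_excluded`, `level`.
#' @examples
#' nn <- nn_distances(c("AAAA", "AAAB", "CCCC"))
#' nn$distances
#' @export
nn_distances <- function(sequences, level = "sequence") {
  if (length(sequences) == 0) stop("empty input")
  len <- nchar(sequences)
  groups <- split(seq_along(sequences), len)
  dist_out <- rep(NA_integer_, length(sequences))
  for (g in groups) {
    if (length(g) < 2L) next
    dist_out[g] <- group_nn(sequences[g])
  }
  comparable <- !is.na(dist_out)
  if (!any(comparable))
    stop("no two sequences share a CDR3 length")
  d <- setNames(dist_out[comparable], sequences[comparable])
  out <- list(distances = d,
              histogram = table(d),
              n_excluded = sum(!comparable),
              level = level)
  class(out) <- "nn_distribution"
  out
}

#' @export
print.nn_distribution <- function(x, ...) {
  cat("Nearest-neighbour distances (", x$level, " level): ",
      length(x$distances), " sequences, ", x$n_excluded, " excluded\n",
      sep = "")
  print(x$histogram)
  invisible(x)
}

#' Modal cluster-center CDR3
#'
#' The cluster center is the modal member CDR3 (highest sequence count);
#' ties are broken lexicographically.
#'
#' @param cdr3s Character vector of member CDR3 sequences (with repeats).
#' @return Single CDR3 string.
#' @examples
#' cluster_center(c("CARW", "CARW", "CTRW")) # "CARW"
#' @export
cluster_center <- function(cdr3s) {
  if (length(cdr3s) == 0) stop("empty cluster")
  counts <- table(cdr3s)
  top <- names(counts)[counts == max(counts)]
  sort(top)[1L]
}

# Connected components of a logical adjacency matrix (single linkage),
# via iterative BFS.
adjacency_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      if (length(nb)) {
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Cluster sequences into clonal groups
#'
#' Sequences from all supplied samples are clustered jointly: within each
#' (V gene, J gene, CDR3 length) partition, sequences whose CDR3s differ by
#' at most [allowed_mismatches()]`(L, k)` are linked, and clusters are the
#' connected components of that graph. Joint clustering makes cluster
#' identities directly comparable across samples, replicates, timepoints and
#' participants.
#'
#' @param samples A `repertoire_sample`, a `read_set`, or a list of either.
#' @param k Amino acids per allowed CDR3 mismatch (default 12).
#' @param at_least_one Passed to [allowed_mismatches()].
#' @return An object of class `cluster_set`: list with
#'   * `clusters`: data.frame (cluster_id, v_call, j_call, cdr3_length,
#'     center_cdr3, n_total),
#'   * `membership`: data.frame (sequence_id, sample, cluster_id),
#'   * `sizes`: data.frame (cluster_id, sample, size),
#'   * `samples`: sample labels, `k`.
#' @examples
#' s <- repertoire_sample(data.frame(
#'   sequence_id = c("a", "b", "c"), v_call = "IGHV1-1", j_call = "IGHJ4",
#'   cdr3_aa = c("CARDYWGQGTLV", "CARDYWGQGTLW", "CTTTTTTTTTTV")))
#' cluster_repertoire(s, k = 12)$clusters$center_cdr3
#' @export
cluster_repertoire <- function(samples, k = 12, at_least_one = FALSE) {
  samples <- as_sample_list(samples)
  labels <- vapply(samples, sample_label, character(1))
  if (anyDuplicated(labels))
    labels <- make.unique(labels)
  rec <- do.call(rbind, lapply(seq_along(samples), function(i) {
    s <- as.data.frame(samples[[i]])
    data.frame(sequence_id = s$sequence_id, sample = labels[i],
               v_call = s$v_call, j_call = s$j_call, cdr3_aa = s$cdr3_aa,
               stringsAsFactors = FALSE)
  }))
  empty <- is.na(rec$cdr3_aa) | rec$cdr3_aa == ""
  if (any(empty)) {
    warning(sum(empty), " record(s) with empty CDR3 skipped")
    rec <- rec[!empty, , drop = FALSE]
  }
  rec$cdr3_length <- nchar(rec$cdr3_aa)
  part_key <- paste(rec$v_call, rec$j_call, rec$cdr3_length, sep = "\r")
  parts <- split(seq_len(nrow(rec)), part_key)

  rec$cluster_key <- character(nrow(rec))
  for (p in parts) {
    L <- rec$cdr3_length[p[1L]]
    maxmm <- allowed_mismatches(L, k, at_least_one)
    uniq <- unique(rec$cdr3_aa[p])
    if (maxmm == 0L || length(uniq) == 1L) {
      comp_of <- setNames(match(rec$cdr3_aa[p], uniq), NULL)
      comp_center <- uniq
    } else {
      adj <- hamming_matrix(uniq) <= maxmm
      comp <- adjacency_components(adj)
      comp_of <- comp[match(rec$cdr3_aa[p], uniq)]
      comp_center <- vapply(split(uniq, comp), function(u) sort(u)[1L],
                            character(1))[as.character(seq_len(max(comp)))]
    }
    # deterministic, order-invariant key: partition + lexicographically
    # smallest member CDR3 of the component
    rec$cluster_key[p] <- paste(part_key[p[1L]], comp_center[comp_of],
                                sep = "\r")
  }

  keys <- sort(unique(rec$cluster_key))
  rec$cluster_id <- sprintf("CL%06d", match(rec$cluster_key, keys))

  by_cluster <- split(rec$cdr3_aa, rec$cluster_id)
  clusters <- data.frame(
    cluster_id = names(by_cluster),
    stringsAsFactors = FALSE
  )
  first <- rec[!duplicated(rec$cluster_id), ]
  first <- first[match(clusters$cluster_id, first$cluster_id), ]
  clusters$v_call <- first$v_call
  clusters$j_call <- first$j_call
  clusters$cdr3_length <- first$cdr3_length
  clusters$center_cdr3 <- vapply(by_cluster, cluster_center, character(1))
  clusters$n_total <- lengths(by_cluster)
  rownames(clusters) <- NULL

  sizes <- aggregate(list(size = rec$sequence_id),
                     by = list(cluster_id = rec$cluster_id,
                               sample = rec$sample),
                     FUN = length)

  out <- list(clusters = clusters,
              membership = rec[, c("sequence_id", "sample", "cluster_id",
                                   "cdr3_aa")],
              sizes = sizes,
              samples = labels,
              k = k)
  class(out) <- "cluster_set"
  out
}

as_sample_list <- function(samples) {
  if (inherits(samples, "read_set")) samples <- list(samples$records)
  if (inherits(samples, "repertoire_sample") || is.data.frame(samples))
    samples <- list(samples)
  lapply(samples, function(s) {
    if (inherits(s, "read_set")) s$records else s
  })
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Cluster set: ", nrow(x$clusters), " clusters from ",
      nrow(x$membership), " sequences across ", length(x$samples),
      " sample(s), k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Per-sample cluster size matrix
#'
#' @param cs A [cluster_repertoire()] result.
#' @return Integer matrix, clusters x samples, of per-sample sequence counts.
#' @export
cluster_size_matrix <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  m <- matrix(0L, nrow(cs$clusters), length(cs$samples),
              dimnames = list(cs$clusters$cluster_id, cs$samples))
  m[cbind(match(cs$sizes$cluster_id, rownames(m)),
          match(cs$sizes$sample, colnames(m)))] <- cs$sizes$size
  m
}

#' Classify clusters as abundant or rare
#'
#' A cluster is abundant in a sample if it holds at least `min_count`
#' sequences there; at the standard 100,000-sequence depth, 10 sequences
#' corresponds to 0.01% of the sequenced repertoire.
#'
#' @param size Numeric vector (or matrix) of per-sample cluster sizes.
#' @param min_count Abundance threshold (default 10 sequences).
#' @return Character vector/matrix of `"abundant"` / `"rare"`.
#' @examples
#' classify_abundance(c(9, 10, 250))
#' @export
classify_abundance <- function(size, min_count = 10) {
  out <- ifelse(size >= min_count, "abundant", "rare")
  if (is.matrix(size)) dim(out) <- dim(size)
  out
}

#' Annotate clusters with mutation and subclass composition
#'
#' Fills per-cluster mean V-gene mutation count (arithmetic mean over member
#' sequences) and subclass usage counts from the member records.
#'
#' @param cs A [cluster_repertoire()] result.
#' @param samples The same samples that were clustered.
#' @return `cs` with `clusters$mean_v_mutations` filled and a
#'   `subclass_counts` data.frame (cluster_id, subclass, count) attached.
#' @export
annotate_clusters <- function(cs, samples) {
  stopifnot(inherits(cs, "cluster_set"))
  samples <- as_sample_list(samples)
  rec <- do.call(rbind, lapply(samples, function(s) {
    s <- as.data.frame(s)
    cols <- intersect(c("sequence_id", "v_mutation_count", "subclass"),
                      names(s))
    s[, cols, drop = FALSE]
  }))
  idx <- match(cs$membership$sequence_id, rec$sequence_id)
  if (anyNA(idx)) stop("membership sequence_ids not resolvable to records")
  cid <- cs$membership$cluster_id
  if (!is.null(rec$v_mutation_count)) {
    mv <- tapply(rec$v_mutation_count[idx], cid, mean)
    cs$clusters$mean_v_mutations <-
      as.numeric(mv[cs$clusters$cluster_id])
  }
  if (!is.null(rec$subclass)) {
    sc <- aggregate(list(count = cs$membership$sequence_id),
                    by = list(cluster_id = cid,
                              subclass = rec$subclass[idx]),
                    FUN = length)
    cs$subclass_counts <- sc
  }
  cs
}

#' Scan clustering thresholds
#'
#' Re-clusters the samples at each `k` and reports, per threshold, the number
#' of clusters, the largest intra-cluster pairwise CDR3 distance, and the
#' smallest same-partition distance between sequences left in different
#' clusters. Coarser thresholds (smaller `k`) can only merge clusters, so
#' the cluster count is non-decreasing in `k`.
#'
#' @param samples As for [cluster_repertoire()].
#' @param k_values Integer vector of thresholds to scan (default 4..26).
#' @return data.frame with columns `k`, `n_clusters`,
#'   `max_intra_distance`, `min_unclustered_distance` (NA when no pair
#'   qualifies).
#' @export
threshold_scan <- function(samples, k_values = 4:26) {
  if (length(k_values) < 2) stop("need at least 2 k values")
  samples <- as_sample_list(samples)
  out <- lapply(sort(k_values), function(k) {
    cs <- cluster_repertoire(samples, k = k)
    stats <- scan_partition_stats(cs)
    data.frame(k = k, n_clusters = nrow(cs$clusters),
               max_intra_distance = stats[1], min_unclustered_distance = stats[2])
  })
  do.call(rbind, out)
}

# Max within-cluster and min between-cluster CDR3 distance, computed per
# (v, j, length) partition of the clustered sequences.
scan_partition_stats <- function(cs) {
  mem <- cs$membership
  info <- cs$clusters[match(mem$cluster_id, cs$clusters$cluster_id), ]
  cdr3 <- mem$cdr3_aa
  part <- paste(info$v_call, info$j_call, info$cdr3_length)
  max_intra <- -Inf
  min_between <- Inf
  for (p in split(seq_len(nrow(mem)), part)) {
    uniq <- unique(data.frame(cdr3 = cdr3[p], cl = mem$cluster_id[p],
                              stringsAsFactors = FALSE))
    if (nrow(uniq) < 2) next
    d <- hamming_matrix(uniq$cdr3)
    same <- outer(uniq$cl, uniq$cl, "==")
    diag(same) <- NA
    if (any(same, na.rm = TRUE))
      max_intra <- max(max_intra, max(d[which(same)]))
    if (any(!same, na.rm = TRUE))
      min_between <- min(min_between, min(d[which(!same)]))
  }
  c(if (is.finite(max_intra)) max_intra else NA_real_,
    if (is.finite(min_between)) min_between else NA_real_)
}
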