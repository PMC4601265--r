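# Global repertoire summaries: VJ usage, usage correlation and PCA, mean
# CDR3 length / mutation / subclass proportions, and temporal persistence of
# clusters.

#' VJ gene usage proportions
#'
#' Fraction of a sample's sequences using each observed (V, J) combination.
#'
#' @param sample A `repertoire_sample` (or records data.frame).
#' @return Named numeric vector (`"Vx J y"` keys) summing to 1; zero-usage
#'   combinations are omitted.
#' @export
vj_usage <- function(sample) {
  s <- as.data.frame(sample)
  if (nrow(s) == 0) stop("empty sample")
  counts <- table(paste(s$v_call, s$j_call))
  p <- as.numeric(counts) / sum(counts)
  setNames(p, names(counts))
}

#' Pearson correlation of two usage vectors
#'
#' Usage vectors are aligned on the union of their VJ keys (absent
#' combinations count as 0) before computing Pearson's r, so samples with
#' different observed combinations remain comparable.
#'
#' @param u1,u2 Named usage vectors from [vj_usage()].
#' @return Pearson correlation coefficient; `NA` (with a warning) when
#'   either aligned vector has zero variance.
#' @export
usage_correlation <- function(u1, u2) {
  keys <- union(names(u1), names(u2))
  x <- setNames(rep(0, length(keys)), keys)
  y <- x
  x[names(u1)] <- u1
  y[names(u2)] <- u2
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in usage vector; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' PCA of VJ usage across samples
#'
#' Principal component analysis of the samples-by-VJ-combination usage
#' matrix. Columns are centred but not scaled (all entries are proportions
#' on a common scale). The sign of each component is fixed by making its
#' largest-magnitude loading positive, so coordinates are reproducible
#' across sample orderings.
#'
#' @param usage_list Named list of [vj_usage()] vectors (>= 3 samples).
#' @return List with `scores` (samples x 2 matrix of PC1/PC2 coordinates),
#'   `explained` (fraction of variance per component, all components) and
#'   the full `prcomp` fit.
#' @export
vj_pca <- function(usage_list) {
  if (length(usage_list) < 3) stop("need at least 3 samples for PCA")
  keys <- sort(unique(unlist(lapply(usage_list, names))))
  m <- t(vapply(usage_list, function(u) {
    v <- setNames(rep(0, length(keys)), keys)
    v[names(u)] <- u
    v
  }, numeric(length(keys))))
  rownames(m) <- names(usage_list) %||% paste0("S", seq_along(usage_list))
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  tot <- sum(fit$sdev^2)
  explained <- if (tot <= 1e-20) rep(0, length(fit$sdev)) else fit$sdev^2 / tot
  n_pc <- min(2L, ncol(fit$x))
  list(scores = fit$x[, seq_len(n_pc), drop = FALSE],
       explained = explained, fit = fit)
}

#' Whole-sample summary metrics
#'
#' Mean CDR3 amino-acid length, mean V-gene mutation count (arithmetic means
#' over all sequences) and subclass usage proportions of a sample.
#'
#' @param sample A `repertoire_sample` (or records data.frame).
#' @return List with `mean_cdr3_length`, `mean_v_mutations`,
#'   `subclass_proportions` (named, sums to 1).
#' @export
summary_metrics <- function(sample) {
  s <- as.data.frame(sample)
  if (nrow(s) == 0) stop("empty sample")
  sp <- if (!is.null(s$subclass)) {
    tab <- table(s$subclass)
    setNames(as.numeric(tab) / sum(tab), names(tab))
  } else NULL
  list(
    mean_cdr3_length = mean(nchar(s$cdr3_aa)),
    mean_v_mutations = if (!is.null(s$v_mutation_count))
      mean(s$v_mutation_count) else NA_real_,
    subclass_proportions = sp
  )
}

#' Temporal persistence of clusters
#'
#' For samples collected on different days (clustered jointly), counts at
#' how many timepoints each cluster is detected (presence = at least one
#' sequence that day) and summarises the distribution. Also reports, per
#' pair of days, the shared clusters with their abundance class, as a
#' tabular replacement for circular sharing plots.
#'
#' @param cs A joint `cluster_set` over the timepoint samples.
#' @param sample_days Named vector mapping sample label (see `cs$samples`)
#'   to day; samples from the same day are pooled.
#' @param min_count Abundance threshold passed to [classify_abundance()].
#' @return Object of class `persistence_table`: list with
#'   * `per_cluster`: data.frame (cluster_id, n_timepoints, max_size,
#'     abundance_class),
#'   * `summary`: data.frame (n_timepoints, clusters) with counts summing
#'     to the total cluster number,
#'   * `pairs`: data.frame of day pairs and shared-cluster counts split by
#'     abundance class.
#' @export
persistence <- function(cs, sample_days, min_count = 10) {
  stopifnot(inherits(cs, "cluster_set"))
  if (!all(cs$samples %in% names(sample_days)))
    stop("sample_days must name every sample in the cluster set")
  m <- cluster_size_matrix(cs)
  days <- sample_days[colnames(m)]
  uday <- sort(unique(days))
  by_day <- vapply(uday, function(d) {
    rowSums(m[, days == d, drop = FALSE])
  }, numeric(nrow(m)))
  present <- by_day > 0
  n_tp <- rowSums(present)
  max_size <- apply(by_day, 1, max)
  per_cluster <- data.frame(
    cluster_id = rownames(m),
    n_timepoints = n_tp,
    max_size = max_size,
    abundance_class = classify_abundance(max_size, min_count),
    stringsAsFactors = FALSE
  )
  summary <- data.frame(
    n_timepoints = seq_along(uday),
    clusters = vapply(seq_along(uday), function(t) sum(n_tp == t), numeric(1))
  )
  pairs <- list()
  if (length(uday) >= 2) {
    for (i in seq_len(length(uday) - 1)) {
      for (j in (i + 1):length(uday)) {
        shared <- present[, i] & present[, j]
        pairs[[length(pairs) + 1L]] <- data.frame(
          day1 = uday[i], day2 = uday[j],
          shared_total = sum(shared),
          shared_abundant = sum(shared &
                                  per_cluster$abundance_class == "abundant"),
          shared_rare = sum(shared & per_cluster$abundance_class == "rare")
        )
      }
    }
  }
  out <- list(per_cluster = per_cluster, summary = summary,
              pairs = if (length(pairs)) do.call(rbind, pairs) else NULL)
  class(out) <- "persistence_table"
  out
}

#' @export
print.persistence_table <- function(x, ...) {
  cat("Cluster persistence over", nrow(x$summary), "timepoints\n")
  print(x$summary, row.names = FALSE)
  multi <- sum(x$summary$clusters[x$summary$n_timepoints > 1])
  cat(round(100 * multi / sum(x$summary$clusters), 1),
      "% of clusters detected on more than one day\n", sep = "")
  invisible(x)
}
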