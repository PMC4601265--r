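# Repertoire diversity: single indices (Shannon, Simpson, cross-replicate
# clonality) and Hill diversity profiles, with each cluster treated as a
# distinct species and cluster frequencies as relative abundances.

check_freqs <- function(p) {
  if (length(p) == 0) stop("empty frequency vector")
  if (any(p <= 0)) stop("frequencies must be strictly positive")
  if (abs(sum(p) - 1) > 1e-9) stop("frequencies must sum to 1")
  invisible(p)
}

#' Cluster relative frequencies of a sample
#'
#' @param sizes Per-cluster sequence counts (zeros dropped).
#' @return Normalised frequency vector.
#' @export
cluster_frequencies <- function(sizes) {
  sizes <- sizes[sizes > 0]
  if (length(sizes) == 0) stop("no non-empty clusters")
  sizes / sum(sizes)
}

#' Shannon entropy index
#'
#' `H = -sum(p_i log p_i)` (natural log). Weights rare clusters relatively
#' heavily.
#'
#' @param p Cluster frequency vector (positive, sums to 1).
#' @return Shannon entropy (nats).
#' @examples
#' shannon(rep(0.25, 4)) # log(4)
#' @export
shannon <- function(p) {
  check_freqs(p)
  -sum(p * log(p))
}

#' Simpson concentration index
#'
#' `C = sum(p_i^2)`, the probability that two sequences drawn from the same
#' sample fall in the same cluster. Weights abundant clusters heavily.
#'
#' @inheritParams shannon
#' @return Simpson concentration in (0, 1].
#' @export
simpson <- function(p) {
  check_freqs(p)
  sum(p^2)
}

#' Cross-replicate clonality index
#'
#' The probability that one sequence drawn from each of two (PCR) replicates
#' falls in the same cluster: `sum_c f1(c) f2(c)` over the shared cluster
#' space. Requires both replicates to have been clustered jointly (one
#' [cluster_repertoire()] call over both), so cluster ids are comparable.
#' For identical replicates this reduces to the Simpson index.
#'
#' @param cs A joint `cluster_set` containing both replicates.
#' @param sample1,sample2 Sample labels within `cs` (see `cs$samples`).
#' @return Coincidence probability in [0, 1].
#' @export
clonality <- function(cs, sample1, sample2) {
  stopifnot(inherits(cs, "cluster_set"))
  if (!all(c(sample1, sample2) %in% cs$samples))
    stop("samples not present in this cluster set; cluster them jointly")
  m <- cluster_size_matrix(cs)
  f1 <- m[, sample1] / sum(m[, sample1])
  f2 <- m[, sample2] / sum(m[, sample2])
  sum(f1 * f2)
}

#' Hill diversity profile
#'
#' The Hill number of order `alpha`,
#' `D_alpha = (sum p_i^alpha)^(1/(1-alpha))`, with the `alpha = 1` limit
#' `exp(H)` (exponential Shannon). `D_0` is cluster richness and
#' `D_2 = 1/Simpson`; increasing `alpha` down-weights rare clusters, so a
#' profile over a grid of `alpha` values characterises the whole abundance
#' structure of a repertoire.
#'
#' @inheritParams shannon
#' @param alphas Grid of orders (default 0 to 10 in steps of 0.5).
#' @return Object of class `diversity_profile`: list with `alphas`,
#'   `values`.
#' @examples
#' hill_profile(rep(0.2, 5))$values # flat at 5
#' @export
hill_profile <- function(p, alphas = seq(0, 10, by = 0.5)) {
  check_freqs(p)
  values <- vapply(alphas, function(a) {
    if (abs(a - 1) < 1e-9) exp(-sum(p * log(p)))
    else sum(p^a)^(1 / (1 - a))
  }, numeric(1))
  out <- list(alphas = alphas, values = values)
  class(out) <- "diversity_profile"
  out
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat("Hill diversity profile over alpha in [", min(x$alphas), ", ",
      max(x$alphas), "]: D_0 = ", round(x$values[1], 1),
      ", D_max = ", round(x$values[length(x$values)], 2), "\n", sep = "")
  invisible(x)
}

#' Cluster samples by their diversity profiles
#'
#' Computes pairwise Euclidean distances between Hill diversity profiles
#' (over their shared alpha grid) and agglomerates them with complete
#' linkage, so samples with similar abundance structure group together
#' irrespective of which specific clusters they contain.
#'
#' @param profiles Named list of [hill_profile()] objects on the same grid.
#' @return List with `dist` (the `stats::dist` matrix) and `hclust` (the
#'   complete-linkage dendrogram).
#' @export
profile_cluster <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  grids <- lapply(profiles, `[[`, "alphas")
  if (!all(vapply(grids, identical, logical(1), grids[[1]])))
    stop("profiles are on different alpha grids")
  m <- do.call(rbind, lapply(profiles, `[[`, "values"))
  rownames(m) <- names(profiles) %||% paste0("S", seq_along(profiles))
  d <- dist(m, method = "euclidean")
  list(dist = d, hclust = hclust(d, method = "complete"))
}
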