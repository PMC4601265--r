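# Sequencing-depth and sampling-depth estimation: rarefaction, Chao richness
# extrapolation, Chapman capture-recapture, and replicate overlap.

#' Rarefaction curve of cluster richness
#'
#' Subsamples the sequence-to-cluster labels without replacement at `step`
#' increments and records the mean number of distinct clusters observed at
#' each depth. Also tallies the singleton (`f1`) and doubleton (`f2`)
#' cluster counts of the full sample and the resulting Chao richness
#' estimate.
#'
#' @param labels Cluster label per sequence (character/factor vector).
#' @param step Depth increment (default 1,000 sequences).
#' @param repeats Number of random subsamples per depth (default 10).
#' @param exact If `TRUE`, skip Monte-Carlo and use the exact hypergeometric
#'   expectation `sum_i (1 - choose(N - n_i, d) / choose(N, d))`.
#' @param seed Optional integer seed.
#' @return Object of class `rarefaction_curve`: list with `depths`,
#'   `observed` (mean clusters at each depth), `n` (total sequences),
#'   `s_obs`, `f1`, `f2`, `chao`.
#' @examples
#' labels <- rep(paste0("c", 1:50), times = rpois(50, 20) + 1)
#' rc <- rarefy(labels, step = 100, seed = 1)
#' rc$chao >= rc$s_obs
#' @export
rarefy <- function(labels, step = 1000, repeats = 10, exact = FALSE,
                   seed = NULL) {
  n <- length(labels)
  if (step > n) stop("step (", step, ") exceeds sample size (", n, ")")
  depths <- unique(c(seq(step, n, by = step), n))
  counts <- table(labels)
  observed <- if (exact) {
    vapply(depths, function(d) expected_richness(as.integer(counts), d),
           numeric(1))
  } else {
    with_seed(seed, {
      vapply(depths, function(d) {
        mean(vapply(seq_len(repeats), function(i) {
          length(unique(labels[sample.int(n, d)]))
        }, numeric(1)))
      }, numeric(1))
    })
  }
  f1 <- sum(counts == 1L)
  f2 <- sum(counts == 2L)
  s_obs <- length(counts)
  out <- list(depths = depths, observed = observed, n = n,
              s_obs = s_obs, f1 = f1, f2 = f2,
              chao = chao_richness(s_obs, f1, f2))
  class(out) <- "rarefaction_curve"
  out
}

# Exact expected richness at depth d under sampling without replacement.
expected_richness <- function(counts, d) {
  n <- sum(counts)
  sum(1 - exp(lchoose(n - counts, d) - lchoose(n, d)))
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("Rarefaction: ", x$n, " sequences, ", x$s_obs, " clusters observed",
      " (f1 = ", x$f1, ", f2 = ", x$f2, "), Chao estimate ",
      round(x$chao, 1), "\n", sep = "")
  if (!is.null(x$extrapolated))
    cat("Extrapolated to depth ", max(x$extrapolated$depth), "\n", sep = "")
  invisible(x)
}

#' Chao richness estimate
#'
#' Nonparametric lower-bound estimate of total cluster richness from the
#' singleton and doubleton counts: `s_obs + f1^2 / (2 f2)`, with the
#' bias-corrected form `s_obs + f1 (f1 - 1) / (2 (f2 + 1))` when `f2 = 0`.
#'
#' @param s_obs Observed cluster count.
#' @param f1,f2 Number of clusters seen exactly once / exactly twice.
#' @return Estimated total richness (>= `s_obs`).
#' @examples
#' chao_richness(10, 4, 2) # 14
#' chao_richness(10, 3, 0) # 13
#' @export
chao_richness <- function(s_obs, f1, f2) {
  if (f1 < 0 || f2 < 0) stop("f1 and f2 must be non-negative")
  if (f2 == 0) s_obs + f1 * (f1 - 1) / 2 else s_obs + f1^2 / (2 * f2)
}

#' Extrapolate a rarefaction curve beyond the observed depth
#'
#' Extends the curve to `target_depth` using the Chao-based analytic form:
#' with `f0 = chao - s_obs` undetected clusters, the expected richness after
#' `m` additional sequences is
#' `s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^m)`.
#' The extension is monotone non-decreasing with asymptote at the Chao
#' estimate. Extrapolations beyond roughly twice the observed depth should
#' be treated as rough lower-bound guidance only.
#'
#' @param curve A [rarefy()] result.
#' @param target_depth Extrapolation endpoint (default 500,000 sequences).
#' @param step Depth increment of the extension grid.
#' @return `curve` with an `extrapolated` data.frame (`depth`, `richness`)
#'   attached.
#' @export
extrapolate <- function(curve, target_depth = 500000, step = 1000) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  if (target_depth <= curve$n) stop("target_depth must exceed observed depth")
  step <- min(step, target_depth - curve$n)
  m <- unique(c(seq(step, target_depth - curve$n, by = step),
                target_depth - curve$n))
  f0 <- curve$chao - curve$s_obs
  richness <- if (curve$f1 == 0 || f0 <= 0) {
    rep(curve$s_obs, length(m))
  } else {
    curve$s_obs + f0 * (1 - (1 - curve$f1 / (curve$n * f0 + curve$f1))^m)
  }
  curve$extrapolated <- data.frame(depth = curve$n + m, richness = richness)
  curve
}

#' Depth required to capture a fraction of total richness
#'
#' Smallest sequencing depth at which the (extrapolated) expected cluster
#' richness reaches `fraction` of the Chao total-richness estimate. Returns
#' `Inf` when the asymptote never reaches the target (e.g. `fraction = 1`),
#' meaning the target is unreachable at finite depth.
#'
#' @param curve An [extrapolate()]d rarefaction curve.
#' @param fraction Target fraction of the Chao estimate, in (0, 1].
#' @return Required depth (sequences), possibly `Inf`.
#' @export
depth_for_fraction <- function(curve, fraction = 0.9) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(curve$extrapolated)) stop("extrapolate() the curve first")
  target <- fraction * curve$chao
  hit <- which(curve$observed >= target)
  if (length(hit)) return(curve$depths[hit[1L]])
  # the asymptote itself is approached but never attained at finite depth
  if (fraction == 1 && curve$chao > curve$s_obs) return(Inf)
  hit <- which(curve$extrapolated$richness >= target)
  if (length(hit)) return(curve$extrapolated$depth[hit[1L]])
  # beyond the grid: closed-form inversion of the extension formula
  f0 <- curve$chao - curve$s_obs
  if (f0 <= 0 || curve$f1 == 0) return(Inf)
  q <- (target - curve$s_obs) / f0
  if (q >= 1) return(Inf)
  r <- curve$f1 / (curve$n * f0 + curve$f1)
  curve$n + ceiling(log(1 - q) / log(1 - r))
}

#' Chapman capture-recapture estimate of repertoire size
#'
#' Bias-corrected Lincoln-Petersen estimator of the number of clusters in
#' the population from two replicate samples: with `n1` and `n2` clusters
#' observed and `m` shared, the estimate is
#' `(n1 + 1) (n2 + 1) / (m + 1) - 1`. Unequal clone abundances violate the
#' equal-catchability assumption and deflate the estimate, so results are
#' lower bounds for real repertoires.
#'
#' @param n1,n2 Cluster counts in the two replicates.
#' @param m Number of clusters observed in both.
#' @return Estimated total cluster count.
#' @examples
#' chapman(100, 100, 50) # 101 * 101 / 51 - 1
#' @export
chapman <- function(n1, n2, m) {
  if (m > min(n1, n2)) stop("m cannot exceed min(n1, n2)")
  (n1 + 1) * (n2 + 1) / (m + 1) - 1
}

#' Replicate overlap normalised by the smaller set
#'
#' `|A intersect B| / min(|A|, |B|) x 100`, the percent of the smaller
#' replicate's clusters that are recovered in the other replicate.
#'
#' @param a,b Cluster id sets (character vectors; duplicates ignored).
#' @return Percent overlap in [0, 100].
#' @examples
#' overlap_min(c("a", "b", "c"), c("b", "c", "d", "e")) # 66.67
#' @export
overlap_min <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0) stop("empty cluster set")
  length(intersect(a, b)) / min(length(a), length(b)) * 100
}

#' Percent of the estimated repertoire that was sampled
#'
#' @param observed Observed cluster count.
#' @param estimate Estimated total cluster count (> 0).
#' @return `observed / estimate * 100`, rounded half-up to 1 decimal.
#' @examples
#' percent_sampled(12152, 132841) # 9.1
#' @export
percent_sampled <- function(observed, estimate) {
  if (any(estimate <= 0)) stop("estimate must be positive")
  round_half_up(observed / estimate * 100, 1)
}

#' Summarise a capture-recapture table
#'
#' Takes per-timepoint observed cluster counts and capture-recapture size
#' estimates for the total and abundant repertoire, and adds the derived
#' quantities: percent sampled per day, column means, and the max/min ratio
#' of the size estimates across days (how much the estimates fluctuate).
#'
#' @param tab data.frame with columns `day`, `total_clusters`,
#'   `abundant_clusters`, `total_estimate`, `abundant_estimate`.
#' @return List with `table` (input plus `total_pct` and `abundant_pct`
#'   columns), `means` (named vector of column means, percents averaged over
#'   the per-day percents and rounded half-up to 1 decimal), and `ratios`
#'   (max/min of the total and abundant size estimates, rounded half-up to
#'   1 decimal).
#' @export
capture_recapture_summary <- function(tab) {
  need <- c("day", "total_clusters", "abundant_clusters",
            "total_estimate", "abundant_estimate")
  stopifnot(all(need %in% names(tab)))
  tab$total_pct <- percent_sampled(tab$total_clusters, tab$total_estimate)
  tab$abundant_pct <- percent_sampled(tab$abundant_clusters,
                                      tab$abundant_estimate)
  means <- c(
    total_clusters = mean(tab$total_clusters),
    abundant_clusters = mean(tab$abundant_clusters),
    total_estimate = mean(tab$total_estimate),
    abundant_estimate = mean(tab$abundant_estimate),
    total_pct = round_half_up(mean(tab$total_pct), 1),
    abundant_pct = round_half_up(mean(tab$abundant_pct), 1)
  )
  ratios <- c(
    total_estimate = round_half_up(max(tab$total_estimate) /
                                     min(tab$total_estimate), 1),
    abundant_estimate = round_half_up(max(tab$abundant_estimate) /
                                        min(tab$abundant_estimate), 1)
  )
  list(table = tab, means = means, ratios = ratios)
}
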