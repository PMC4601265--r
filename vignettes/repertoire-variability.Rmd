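---
title: "Methods: quantifying within- and between-individual BCR repertoire variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying within- and between-individual BCR repertoire variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrep)
```

## The analysis problem

High-throughput sequencing of the B cell receptor (BCR) heavy chain yields,
after annotation, a table with one row per sequence: the germline V and J
gene calls, the CDR3 amino-acid sequence, the V-gene mutation count, the
isotype subclass, and the number of mismatches against the germline constant
region. Because only a small blood sample of a much larger B cell population
is ever sequenced, and because PCR and sequencing inject errors, every
downstream question — how diverse is the repertoire, how repeatable is the
assay, how much of the repertoire was captured, which clones persist over
time, and which are shared between people — requires explicit statistical
treatment. `bcrep` implements that treatment end to end, together with a
simulator that generates data with known ground truth so each estimator can
be validated.

## Clonal clustering

Raw sequences are grouped into *clusters* intended to capture sequences of
common clonal origin or common specificity, and to absorb PCR/sequencing
error. Two sequences belong to the same cluster iff they have

1. the same V gene and J gene call,
2. the same CDR3 amino-acid length \(L\), and
3. CDR3s connected through pairs differing by at most
   \(\lfloor L/k \rfloor\) amino acids,

with \(k = 12\) by default ("one mismatch allowed per 12 AAs", i.e. at least
92% CDR3 identity). Clusters are the single-linkage connected components of
the pairwise mismatch graph inside each (V, J, L) stratum. Two choices here
deserve comment:

* **Single linkage.** The clustering literature this rule descends from
  specifies only that "sufficiently similar" sequences group together;
  single linkage is the minimal rule consistent with asking whether a
  sequence *would have fallen into* a cluster, and it is what
  `cluster_repertoire()` implements. This is an assumption, not a theorem;
  it is stated here so users know which variant they are getting.
* **Short CDR3s.** With `floor(L / k)`, CDR3s shorter than `k` amino acids
  must match exactly. The alternative reading (always allow one mismatch)
  is available via `allowed_mismatches(..., at_least_one = TRUE)`.

The threshold itself is a tunable. `threshold_scan()` re-clusters over a
grid of `k` (default 4..26) and reports cluster counts plus the largest
clustered and smallest unclustered distances; on bimodally separated data
the cluster count plateaus over a band of thresholds (roughly one mismatch
per 8–12 AAs) and collapses when the threshold becomes permissive enough to
bridge unrelated clones.

The diagnostic that justifies clustering at all is the nearest-neighbour
(NN) distance distribution (`nn_distances()`): for each CDR3, the Hamming
distance to the closest other same-length CDR3 in the sample. On real and
simulated repertoires this is bimodal — a 0–2 AA peak (clonal relatives and
error copies) and a ≥3 AA peak (unrelated clones). After clustering, the NN
distribution of cluster *centers* (the modal member CDR3, ties broken
lexicographically) loses most of its first peak; the package treats that
first-peak collapse as the qualitative success criterion of clustering.
Centers at distance 0 arise only from clusters sharing a CDR3 but differing
in V/J; such clusters are deliberately kept distinct.

A cluster is *abundant* in a sample when it holds ≥ 10 sequences, which at
the standard fixed depth of 100,000 sequences per sample equals 0.01% of
the sequenced repertoire.

## Preprocessing

`quality_filter()` drops reads containing any ambiguous base, or with more
than 15% of bases under Phred 30. Both boundaries are deliberate: *exactly*
15% low-quality bases passes (the rule is "more than 15%"), and a base at
exactly Q30 counts as good (the rule is "< 30"). `subsample()` reduces each
sample — always per sample, never pooled — to a fixed depth without
replacement so that richness and diversity are comparable across samples.
`estimate_error_rate()` divides total constant-region mismatches by total
constant-region nucleotides per isotype; the constant region is untouched
by somatic hypermutation, so this ratio isolates the PCR + sequencing error
rate. Totals, not per-read means, are used, since the quantity of interest
is errors per nucleotide.

## Depth and size estimation

* **Rarefaction** (`rarefy()`): mean distinct-cluster count in random
  subsamples at 1,000-sequence increments; default 10 Monte-Carlo repeats
  per depth. The exact hypergeometric expectation
  \(\sum_i \bigl(1 - \binom{N-n_i}{d}/\binom{N}{d}\bigr)\) is available via
  `exact = TRUE` and doubles as the test oracle for the Monte-Carlo mode.
* **Chao richness** (`chao_richness()`): \(S_{obs} + f_1^2/(2f_2)\) from
  singleton/doubleton cluster counts, with the bias-corrected
  \(f_1(f_1-1)/2\) fallback when \(f_2 = 0\) to avoid division by zero.
* **Extrapolation** (`extrapolate()`): the analytic extension
  \(S(n+m) = S_{obs} + \hat f_0\,[1 - (1 - f_1/(n\hat f_0 + f_1))^m]\) with
  \(\hat f_0\) the Chao estimate of undetected clusters; monotone, with the
  Chao estimate as asymptote. Values beyond about twice the observed depth
  are flagged as rough guidance only. `depth_for_fraction()` inverts the
  curve to answer "how deep must I sequence to see 90% of clusters"; the
  asymptote itself is unreachable at finite depth, so `fraction = 1`
  returns `Inf` whenever undetected clusters remain.
* **Capture-recapture** (`chapman()`): the bias-corrected two-sample
  estimator \((n_1+1)(n_2+1)/(m+1) - 1\) applied to the cluster sets of two
  biological replicates. Unequal clone abundances violate equal
  catchability and *deflate* the estimate — the package documents all
  repertoire-size estimates as lower bounds, and the test suite verifies
  the deflation direction under power-law abundance.
* **Overlap** (`overlap_min()`): \(|A\cap B|/\min(|A|,|B|)\times 100\),
  the recovery rate of the smaller replicate's clusters.

Tabulated percent-sampled values (`percent_sampled()`,
`capture_recapture_summary()`) are rounded half-up to one decimal to match
how such tables are conventionally printed; column means of percentages are
means of the per-day percents, not ratios of column means.

## Diversity

With each cluster a species and per-sample cluster frequencies \(p_i\):
Shannon entropy \(-\sum p_i \ln p_i\), Simpson concentration
\(\sum p_i^2\), and the Hill family
\(D_\alpha = (\sum p_i^\alpha)^{1/(1-\alpha)}\) over the default grid
\(\alpha = 0, 0.5, \dots, 10\), with \(D_1 = e^H\) taken by the limit
(orders within \(10^{-9}\) of 1 are routed to it). The identities
\(D_0 = S\), \(D_1 = e^H\), \(D_2 = 1/\text{Simpson}\) hold to \(10^{-9}\)
and are asserted in the tests. Profiles are compared by Euclidean distance
over the grid and clustered with complete linkage (`profile_cluster()`,
via `stats::hclust`).

The *clonality* index is described in its source only verbally, as the
probability that sequences drawn from different PCR replicates belong to
the same cluster. `clonality()` implements the natural reading, the
cross-replicate coincidence probability \(\sum_c f_1(c) f_2(c)\); for
identical replicates it reduces to the Simpson index. This formula is an
interpretation, and is documented as such.

## Repertoire metrics and persistence

VJ usage vectors are proportions over observed (V, J) combinations;
correlations and PCA align samples on the union of keys with zeros for
absent combinations, since proportions are only comparable on a common
basis. PCA (`vj_pca()`, via `stats::prcomp`) centres but does not scale —
the inputs are already proportions on one scale — and fixes each
component's sign by making its largest-magnitude loading positive so
results do not depend on sample order. Whether scaling to unit variance
was intended in the original procedure is unstated; centring-only is this
package's documented choice, and scaling can be applied upstream by the
user if desired.

`persistence()` counts, per cluster, the number of timepoints with at least
one member sequence (presence threshold: ≥ 1 sequence), histograms the
result, and emits per-day-pair shared-cluster tables with abundance classes
— a tabular replacement for circular sharing plots.

## The public repertoire

Because all samples are clustered jointly, cluster identity is global and
sharing reduces to per-participant presence. `sharing_spectrum()`
histograms clusters by the number of participants carrying them; *public*
means ≥ 2 participants. `public_private_compare()` contrasts public and
private clusters on size, mutation or CDR3 length: per participant, the
means over its public and its private clusters form one pair, and pairs are
compared with the Wilcoxon signed-rank test. The source procedure names a
"paired Mann-Whitney U test"; a literal Mann-Whitney is unpaired, so the
signed-rank test — its standard paired analogue — is used and documented
prominently.

`annotate_specificity()` labels a cluster for an antigen when a reference
CDR3 known to bind that antigen would have fallen into the cluster during
clustering: same length and within \(\lfloor L/k\rfloor\) mismatches of the
cluster *center*, matching on CDR3 identity only (V/J are not required to
agree). Whether matching should use centers or every member is ambiguous in
the source; center matching is the default and member-level matching is
available with `match_members = TRUE`. The shipped reference list
(`synthetic_antigen_references.tsv`) is synthetic, for demonstration and
testing; users supply their own curated lists.

## The simulator: what it emulates, and what it does not

`make_germline_db()`, `simulate_repertoire()`, `sample_reads()` and
`make_replicates()` generate ground-truth repertoires and annotated reads
with the features the analyses rely on:

* **Clone-size law.** Frequencies follow a discrete power law (Zipf) with
  exponent `abundance_shape` (default 1.5), reproducing the small abundant
  head and long rare tail with one parameter. No quantitative clone-size
  law is established for real repertoires; the exponent is exposed as
  configuration, and `abundance_shape = 0` gives the uniform-abundance
  repertoires needed to validate estimators under their stated assumptions.
* **CDR3 geometry.** CDR3s are a conserved C...W motif around a random
  20-letter amino-acid core, lengths discretised around a mean of 15 AAs;
  random cores make distinct clones almost surely ≥ 3 AAs apart, while
  `within_clone_diversification` (default 0.01 per position) scatters
  intra-clone copies 0–2 AAs from the clone sequence. Together these yield
  the bimodal NN distribution the clustering threshold relies on.
* **Noise.** Constant-region mismatches are binomial per nucleotide at
  `error_rate` (the validation target is the observed per-isotype scale of
  roughly 0.002 for IgA/IgM and 0.008 for IgG); V-mutation counts are
  Poisson around per-clone means (isotype-dependent defaults: IgM
  near-unmutated, IgA/IgG mutated); per-cell read amplification is
  lognormal (`amplification_sd = 1`), standing in for PCR efficiency
  differences.
* **Designs.** PCR replicates share one cell draw and differ in
  amplification and error noise; biological replicates redraw cells;
  temporal replicates evolve the truth between draws by multiplicative
  lognormal drift plus clone birth/death (dying clones hand their frequency
  to fresh clones, keeping the clone count and normalisation).
* **Public clones.** A `public_pool` of clones can be injected verbatim
  into several participants at chosen frequency ranks, giving planted
  truth for sharing and enrichment analyses.

The simulator does **not** model nucleotide-level VDJ junctions, somatic
hypermutation hotspots, indels, light chains or chimera formation. Passing
tests therefore demonstrate that the estimators recover truth under the
stated statistical structure — not that real repertoires have that
structure. In particular, real within-clone variation is phylogenetic, not
iid; real clone-size laws may be heavier- or lighter-tailed than Zipf; and
real public sharing includes convergent recombination that the simulator
only represents through explicit injection.

Every stochastic operation takes an explicit `seed` and is bit-reproducible
given one; pipeline-level seeds derive per-stage seeds deterministically.

## Numerical choices and degenerate inputs

* Frequencies are validated to sum to 1 within \(10^{-9}\).
* Cluster-center ties break lexicographically; cluster ids are assigned
  from sorted (V, J, L, smallest-member-CDR3) keys, making clustering
  invariant to input order.
* Sequences with no same-length comparator are excluded from NN histograms
  but counted; empty CDR3s are skipped with a warning during clustering.
* `chao_richness()` switches to the bias-corrected branch only at
  \(f_2 = 0\); `extrapolate()` with \(f_1 = 0\) returns a flat extension.
* In the paired public/private test, participants lacking either class are
  excluded from the pairing with a warning, and all-tied pairs yield
  \(p = 1\).
* Percent columns use half-up rounding to one decimal (R's `round()`
  rounds half to even, which breaks agreement with printed tables).

## Problem sizes used in validation

The shipped tests and the reproduction script validate at desk scale:
germline databases of 15–40 V and 4–6 J genes, repertoires of 150–5,000
clones, samples of 600–25,000 reads, 10–20 simulation repeats for
directional and recovery checks, and 500 null datasets for the calibration
of the paired test (rejection rate at the 0.05 level within 0.03–0.07).
Chapman recovery is checked to within two standard errors of the truth on
uniform repertoires; the Chao extrapolation plateau to within 15% of a
5,000-clone truth; Monte-Carlo rarefaction against the hypergeometric
closed form; and the clustering partition against a brute-force
connected-components oracle at 1,000 sequences.

## Known limitations

* Single-linkage clustering can chain through dense intermediate variants;
  at very high mutation loads the first NN peak bleeds into the second and
  no threshold separates them cleanly.
* Chao and Chapman are lower-bound estimators under abundance
  heterogeneity; the package reports them as such and does not attempt
  abundance-model-based corrections.
* No confidence intervals are provided for richness or size estimates, and
  diversity indices are not coverage-standardised.
* The quality filter assumes Sanger Phred+33 encoding.
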