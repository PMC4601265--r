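# Synthetic repertoire simulator.
#
# The simulator produces ground-truth clonal repertoires and sampled,
# annotated reads with the statistical structure the downstream analyses
# assume: a power-law clone-size distribution (a small abundant head and a
# large rare tail), CDR3s that are mutually distant between clones but close
# within clones (bimodal nearest-neighbour distances), per-isotype
# constant-region error rates, and PCR / biological / temporal replicate
# designs.

DEFAULT_SHM_MEAN <- c(IgA = 6, IgG = 8, IgM = 0.5)
DEFAULT_SUBCLASS_PROPS <- list(
  IgA = c(IgA1 = 0.8, IgA2 = 0.2),
  IgG = c(IgG1 = 0.6, IgG2 = 0.25, IgG3 = 0.1, IgG4 = 0.05),
  IgM = c(IgM = 1)
)

# Random CDR3s: conserved C...W motif flanking a random amino-acid core.
# Lengths are drawn from a discretised normal centred at `length_mean`.
random_cdr3 <- function(n, length_mean = 15, length_sd = 2,
                        min_length = 8, max_length = 26) {
  len <- pmin(max_length, pmax(min_length, round(rnorm(n, length_mean, length_sd))))
  vapply(len, function(L) {
    paste0("C", paste(sample(AA_ALPHABET, L - 2L, replace = TRUE),
                      collapse = ""), "W")
  }, character(1))
}

#' Simulate a ground-truth clonal repertoire
#'
#' Draws a set of B cell clones with V/J assignments, mutually distant CDR3
#' amino-acid sequences (random core flanked by the conserved C...W motif, so
#' that distinct clones are almost surely >= 3 AAs apart), true frequencies
#' following a discrete power law (Zipf) with exponent `abundance_shape`,
#' per-clone mean somatic hypermutation loads, and subclass assignments.
#'
#' @param db A [make_germline_db()] database.
#' @param n_clones Number of clones (>= 1).
#' @param abundance_shape Power-law exponent for clone frequencies
#'   (frequency of the i-th ranked clone is proportional to `i^-abundance_shape`).
#'   `0` gives a uniform-abundance repertoire; negative values are rejected.
#' @param isotype One of "IgA", "IgG", "IgM".
#' @param shm_mean Mean V-gene mutation count per clone; defaults to an
#'   isotype-dependent value (IgM near-unmutated, IgA/IgG mutated).
#' @param subclass_props Named probabilities for the isotype's subclasses.
#' @param public_pool Optional data.frame of clones (columns `v_gene`,
#'   `j_gene`, `cdr3_aa`, optionally `mean_mutations`) inserted verbatim as
#'   public clones, e.g. to share clones across simulated participants.
#'   Private clones colliding with the pool are replaced (with a warning).
#' @param public_ranks Frequency ranks at which public clones are placed
#'   (default: evenly spread across the rank range).
#' @param cdr3_length_mean,cdr3_length_sd Centre and spread of the CDR3
#'   length distribution (AAs).
#' @param participant,day Sample labels carried into sampled reads.
#' @param seed Optional integer seed.
#'
#' @return An object of class `true_repertoire`: list with `participant`,
#'   `day`, `isotype`, `seed`, and `clones` (data.frame: clone_id, v_gene,
#'   j_gene, cdr3_aa, true_frequency, mean_mutations, subclass, is_public).
#'   Frequencies sum to 1.
#' @examples
#' db <- make_germline_db(20, 4, seed = 1)
#' rep <- simulate_repertoire(db, n_clones = 100, seed = 2)
#' sum(rep$clones$true_frequency)
#' @export
simulate_repertoire <- function(db, n_clones, abundance_shape = 1.5,
                                isotype = "IgG",
                                shm_mean = NULL,
                                subclass_props = NULL,
                                public_pool = NULL,
                                public_ranks = NULL,
                                cdr3_length_mean = 15, cdr3_length_sd = 2,
                                participant = "P01", day = 0,
                                seed = NULL) {
  stopifnot(inherits(db, "germline_db"))
  if (!is.numeric(n_clones) || n_clones < 1) stop("n_clones must be >= 1")
  if (abundance_shape < 0) stop("abundance_shape must be non-negative")
  if (!isotype %in% names(db$subclass_sets)) stop("unknown isotype: ", isotype)
  n_clones <- as.integer(n_clones)
  shm_mean <- shm_mean %||% unname(DEFAULT_SHM_MEAN[isotype])
  subclass_props <- subclass_props %||% DEFAULT_SUBCLASS_PROPS[[isotype]]

  with_seed(seed, {
    freq <- seq_len(n_clones)^(-abundance_shape)
    freq <- freq / sum(freq)

    cdr3 <- random_cdr3(n_clones, cdr3_length_mean, cdr3_length_sd)
    v <- sample(db$v_genes$name, n_clones, replace = TRUE,
                prob = rlnorm(nrow(db$v_genes), 0, 1))
    j <- sample(db$j_genes$name, n_clones, replace = TRUE,
                prob = rlnorm(nrow(db$j_genes), 0, 1))

    # enforce unique (v, j, cdr3) triples
    key <- paste(v, j, cdr3)
    while (anyDuplicated(key)) {
      dup <- which(duplicated(key))
      cdr3[dup] <- random_cdr3(length(dup), cdr3_length_mean, cdr3_length_sd)
      key <- paste(v, j, cdr3)
    }

    mut <- rpois(n_clones, shm_mean)
    subclass <- sample(names(subclass_props), n_clones, replace = TRUE,
                       prob = subclass_props)
    is_public <- rep(FALSE, n_clones)

    if (!is.null(public_pool) && nrow(public_pool) > 0) {
      np <- nrow(public_pool)
      if (np > n_clones) stop("public_pool larger than n_clones")
      collide <- key %in% paste(public_pool$v_gene, public_pool$j_gene,
                                public_pool$cdr3_aa)
      if (any(collide)) {
        warning(sum(collide), " private clone(s) collided with public_pool; replaced")
      }
      ranks <- public_ranks %||%
        unique(round(seq(1, n_clones, length.out = np)))
      if (length(ranks) < np)
        ranks <- seq_len(np)
      ranks <- ranks[seq_len(np)]
      # clear collisions by regenerating those private CDR3s first
      if (any(collide & !(seq_len(n_clones) %in% ranks))) {
        redo <- which(collide & !(seq_len(n_clones) %in% ranks))
        cdr3[redo] <- random_cdr3(length(redo), cdr3_length_mean, cdr3_length_sd)
      }
      v[ranks] <- public_pool$v_gene
      j[ranks] <- public_pool$j_gene
      cdr3[ranks] <- public_pool$cdr3_aa
      if (!is.null(public_pool$mean_mutations))
        mut[ranks] <- public_pool$mean_mutations
      is_public[ranks] <- TRUE
    }

    clones <- data.frame(
      clone_id = sprintf("CL%05d", seq_len(n_clones)),
      v_gene = v, j_gene = j, cdr3_aa = cdr3,
      true_frequency = freq,
      mean_mutations = mut,
      subclass = subclass,
      is_public = is_public,
      stringsAsFactors = FALSE
    )
    out <- list(participant = participant, day = day, isotype = isotype,
                clones = clones, db = db, seed = seed)
    class(out) <- "true_repertoire"
    out
  })
}

#' @export
print.true_repertoire <- function(x, ...) {
  cat("True repertoire:", nrow(x$clones), "clones |", x$isotype,
      "| participant", x$participant, "| day", x$day, "\n")
  cat("Top clone frequency:", signif(max(x$clones$true_frequency), 3),
      "| public clones:", sum(x$clones$is_public), "\n")
  invisible(x)
}

# Multinomial cell draw from the true clone frequencies; returns one clone
# index per cell plus a lognormal per-cell amplification weight.
draw_cells <- function(rep, n_cells, amplification_sd = 1, seed = NULL) {
  with_seed(seed, {
    counts <- as.vector(rmultinom(1, n_cells, rep$clones$true_frequency))
    clone_idx <- rep.int(seq_along(counts), counts)
    data.frame(
      cell_id = seq_along(clone_idx),
      clone_idx = clone_idx,
      weight = rlnorm(length(clone_idx), 0, amplification_sd)
    )
  })
}

# Draw reads from a fixed cell pool: amplification-weighted resampling of
# cells, then per-read noise (CDR3 AA substitutions, Poisson V mutations,
# binomial constant-region mismatches).
amplify_reads <- function(rep, cells, n_reads, error_rate,
                          within_clone_diversification,
                          replicate = "R1", seed = NULL) {
  clones <- rep$clones
  cr_len <- nchar(rep$db$constant_regions[[rep$isotype]])
  with_seed(seed, {
    ridx <- sample(nrow(cells), n_reads, replace = TRUE, prob = cells$weight)
    ci <- cells$clone_idx[ridx]
    cdr3 <- clones$cdr3_aa[ci]
    if (within_clone_diversification > 0) {
      n_sub <- rbinom(n_reads, nchar(cdr3), within_clone_diversification)
      for (i in which(n_sub > 0L)) {
        ch <- strsplit(cdr3[i], "", fixed = TRUE)[[1L]]
        pos <- sample(length(ch), min(n_sub[i], length(ch)))
        ch[pos] <- sample(AA_ALPHABET, length(pos), replace = TRUE)
        cdr3[i] <- paste(ch, collapse = "")
      }
    }
    records <- data.frame(
      sequence_id = sprintf("%s_d%s_%s_%s_%06d", rep$participant, rep$day,
                            rep$isotype, replicate, seq_len(n_reads)),
      v_call = clones$v_gene[ci],
      j_call = clones$j_gene[ci],
      cdr3_aa = cdr3,
      v_mutation_count = rpois(n_reads, clones$mean_mutations[ci]),
      isotype = rep$isotype,
      subclass = clones$subclass[ci],
      c_region_mismatches = rbinom(n_reads, cr_len, error_rate),
      c_region_length = cr_len,
      stringsAsFactors = FALSE
    )
    truth_map <- setNames(clones$clone_id[ci], records$sequence_id)
    new_read_set(records, truth_map, design = "single",
                 participant = rep$participant, day = rep$day,
                 isotype = rep$isotype, replicate = replicate)
  })
}

new_read_set <- function(records, truth_map, design, participant, day,
                         isotype, replicate) {
  out <- list(records = repertoire_sample(records, participant = participant,
                                          day = day, isotype = isotype,
                                          replicate = replicate),
              truth_map = truth_map, design = design,
              participant = participant, day = day, isotype = isotype,
              replicate = replicate)
  class(out) <- "read_set"
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat("Read set:", nrow(x$records), "records |", x$isotype,
      "| participant", x$participant, "| day", x$day,
      "| replicate", x$replicate, "| design", x$design, "\n")
  invisible(x)
}

#' Sample annotated reads from a true repertoire
#'
#' Emulates the sequencing process: cells are drawn multinomially from the
#' clone frequencies, reads are drawn from cells with lognormal amplification
#' noise, constant-region mismatches are added binomially at `error_rate`
#' (per nucleotide), and CDR3 amino-acid substitutions are applied at rate
#' `within_clone_diversification` (per position) so that intra-clone
#' nearest-neighbour distances fall mostly in 0-2 AAs.
#'
#' @param rep A [simulate_repertoire()] object.
#' @param n_cells Number of cells drawn from the repertoire.
#' @param n_reads Number of reads (>= 1) drawn from those cells.
#' @param error_rate Per-nucleotide constant-region error probability in [0, 1).
#' @param within_clone_diversification Per-position CDR3 AA substitution
#'   probability.
#' @param amplification_sd sdlog of the lognormal per-cell read multiplier.
#' @param replicate Replicate label stored on the sample.
#' @param seed Optional integer seed.
#'
#' @return An object of class `read_set`: list with `records` (a
#'   [repertoire_sample()] data.frame), `truth_map` (named character,
#'   sequence_id -> true clone_id) and the design/sample labels.
#' @examples
#' db <- make_germline_db(10, 3, seed = 1)
#' rep <- simulate_repertoire(db, 50, seed = 2)
#' rs <- sample_reads(rep, n_cells = 200, n_reads = 300, seed = 3)
#' nrow(rs$records)
#' @export
sample_reads <- function(rep, n_cells = 1000, n_reads = 1000,
                         error_rate = 0.002,
                         within_clone_diversification = 0.01,
                         amplification_sd = 1,
                         replicate = "R1", seed = NULL) {
  stopifnot(inherits(rep, "true_repertoire"))
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  cells <- draw_cells(rep, n_cells, amplification_sd,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, "cells"))
  amplify_reads(rep, cells, n_reads, error_rate,
                within_clone_diversification, replicate = replicate,
                seed = if (is.null(seed)) NULL else derive_seed(seed, "reads"))
}

# One temporal step: multiplicative frequency drift plus clone birth/death.
# Dying clones are replaced by fresh clones inheriting their frequency mass,
# so frequencies stay normalised and the clone count is constant.
perturb_repertoire <- function(rep, drift, turnover, seed = NULL) {
  with_seed(seed, {
    cl <- rep$clones
    f <- cl$true_frequency
    if (drift > 0) f <- f * exp(rnorm(length(f), 0, drift))
    if (turnover > 0) {
      die <- which(runif(nrow(cl)) < turnover)
      if (length(die)) {
        cl$cdr3_aa[die] <- random_cdr3(length(die))
        cl$clone_id[die] <- sprintf("%s_n", cl$clone_id[die])
        cl$is_public[die] <- FALSE
      }
    }
    cl$true_frequency <- f / sum(f)
    rep$clones <- cl
    rep
  })
}

#' Generate replicate read sets under a sampling design
#'
#' @description
#' Produces replicate samples from one ground-truth repertoire under three
#' designs:
#' * `"pcr"` — one shared cell draw, independent amplification and error
#'   noise per replicate (technical PCR replicates);
#' * `"biological"` — independent cell draws from the same repertoire
#'   (separate cell aliquots);
#' * `"temporal"` — the repertoire evolves between draws: clone frequencies
#'   get multiplicative lognormal drift of magnitude `drift`, and a fraction
#'   `turnover` of clones die and are replaced by new clones.
#'
#' @param rep A [simulate_repertoire()] object.
#' @param design `"pcr"`, `"biological"` or `"temporal"`.
#' @param n_replicates Number of replicates (>= 2).
#' @param drift Lognormal sdlog of per-clone frequency perturbation
#'   (temporal design only).
#' @param turnover Per-step clone death/birth probability (temporal only).
#' @param day_step Days between consecutive temporal replicates.
#' @param seed Optional integer seed.
#' @inheritParams sample_reads
#'
#' @return List of `read_set` objects, one per replicate, with design and
#'   replicate labels filled (`R1`, `R2`, ... for pcr/biological; day labels
#'   advance by `day_step` for temporal).
#' @examples
#' db <- make_germline_db(10, 3, seed = 1)
#' rep <- simulate_repertoire(db, 50, seed = 2)
#' reps <- make_replicates(rep, "pcr", n_cells = 200, n_reads = 300, seed = 3)
#' length(reps)
#' @export
make_replicates <- function(rep, design = c("pcr", "biological", "temporal"),
                            n_replicates = 2, drift = 0.5, turnover = 0.05,
                            n_cells = 1000, n_reads = 1000,
                            error_rate = 0.002,
                            within_clone_diversification = 0.01,
                            amplification_sd = 1, day_step = 7,
                            seed = NULL) {
  stopifnot(inherits(rep, "true_repertoire"))
  if (!is.character(design) || !design[1] %in% c("pcr", "biological", "temporal"))
    stop("unknown design: ", design[1])
  design <- match.arg(design)
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  seeds <- if (is.null(seed)) vector("list", 3 * n_replicates) else
    lapply(seq_len(3 * n_replicates), function(i) derive_seed(seed, paste0("rep", i)))

  out <- vector("list", n_replicates)
  if (design == "pcr") {
    cells <- draw_cells(rep, n_cells, amplification_sd = 1, seed = seeds[[1]])
    for (r in seq_len(n_replicates)) {
      # fresh lognormal amplification weights per PCR reaction
      cells_r <- cells
      cells_r$weight <- with_seed(seeds[[n_replicates + r]],
                                  rlnorm(nrow(cells), 0, amplification_sd))
      out[[r]] <- amplify_reads(rep, cells_r, n_reads, error_rate,
                                within_clone_diversification,
                                replicate = paste0("R", r),
                                seed = seeds[[2 * n_replicates + r]])
      out[[r]]$design <- "pcr_replicate"
    }
  } else if (design == "biological") {
    for (r in seq_len(n_replicates)) {
      out[[r]] <- sample_reads(rep, n_cells, n_reads, error_rate,
                               within_clone_diversification,
                               amplification_sd,
                               replicate = paste0("R", r), seed = seeds[[r]])
      out[[r]]$design <- "biological_replicate"
    }
  } else {
    cur <- rep
    for (r in seq_len(n_replicates)) {
      if (r > 1) {
        cur <- perturb_repertoire(cur, drift, turnover,
                                  seed = seeds[[n_replicates + r]])
        cur$day <- rep$day + (r - 1) * day_step
      }
      out[[r]] <- sample_reads(cur, n_cells, n_reads, error_rate,
                               within_clone_diversification,
                               amplification_sd, replicate = "R1",
                               seed = seeds[[r]])
      out[[r]]$design <- "temporal"
    }
  }
  out
}

#' Simulate raw FASTQ-style reads with per-base qualities
#'
#' Generates joined reads for exercising the quality filter: most bases are
#' high quality, a configurable fraction of reads carries an excess of
#' low-quality bases, and a configurable fraction contains an ambiguous `N`.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length (bases).
#' @param low_q_read_fraction Fraction of reads whose low-quality base count
#'   is drawn above the filter threshold.
#' @param n_read_fraction Fraction of reads given one `N` base.
#' @param q_high,q_low Phred scores used for good and bad bases.
#' @param seed Optional integer seed.
#'
#' @return data.frame with columns `id`, `sequence`, `quality`
#'   (Sanger Phred+33 encoded).
#' @export
simulate_fastq <- function(n_reads, read_length = 250,
                           low_q_read_fraction = 0.2,
                           n_read_fraction = 0.05,
                           q_high = 37, q_low = 20, seed = NULL) {
  with_seed(seed, {
    bad <- runif(n_reads) < low_q_read_fraction
    with_n <- runif(n_reads) < n_read_fraction
    seqs <- character(n_reads)
    quals <- character(n_reads)
    for (i in seq_len(n_reads)) {
      s <- sample(c("A", "C", "G", "T"), read_length, replace = TRUE)
      if (with_n[i]) s[sample(read_length, 1)] <- "N"
      n_low <- if (bad[i]) {
        round(read_length * runif(1, 0.16, 0.5))
      } else {
        round(read_length * runif(1, 0, 0.14))
      }
      q <- rep(q_high, read_length)
      if (n_low > 0) q[sample(read_length, n_low)] <- q_low
      seqs[i] <- paste(s, collapse = "")
      quals[i] <- intToUtf8(q + 33L)
    }
    data.frame(id = sprintf("read%06d", seq_len(n_reads)),
               sequence = seqs, quality = quals, stringsAsFactors = FALSE)
  })
}
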