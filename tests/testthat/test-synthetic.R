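# The repertoire simulator: germline database, ground-truth clones,
# read sampling and replicate designs.

test_that("germline database respects counts, naming and determinism", {
  db <- make_germline_db(2, 1, seed = 1)
  expect_s3_class(db, "germline_db")
  expect_equal(nrow(db$v_genes), 2)
  expect_equal(nrow(db$j_genes), 1)
  expect_true(all(grepl("^IGHV", db$v_genes$name)))
  expect_true(all(grepl("^IGHJ", db$j_genes$name)))

  big <- make_germline_db(50, 6, seed = 7)
  expect_equal(nrow(big$v_genes) * nrow(big$j_genes), 300)
  expect_false(anyDuplicated(big$v_genes$name) > 0)
  expect_false(anyDuplicated(big$j_genes$name) > 0)

  expect_identical(make_germline_db(10, 3, seed = 5),
                   make_germline_db(10, 3, seed = 5))
  expect_error(make_germline_db(0, 3), "positive")
  expect_error(make_germline_db(3, -1), "positive")

  # every isotype has a non-empty constant region and >= 1 subclass
  expect_true(all(nchar(db$constant_regions) > 0))
  expect_true(all(lengths(db$subclass_sets) >= 1))
})

test_that("simulated repertoires are normalised, unique and power-law skewed", {
  db <- make_germline_db(20, 5, seed = 1)

  one <- simulate_repertoire(db, 1, seed = 2)
  expect_equal(one$clones$true_frequency, 1)

  rep <- simulate_repertoire(db, 1000, abundance_shape = 1.5, seed = 3)
  f <- rep$clones$true_frequency
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_false(anyDuplicated(with(rep$clones, paste(v_gene, j_gene, cdr3_aa))) > 0)
  expect_true(all(nchar(rep$clones$cdr3_aa) >= 4))
  # abundant head: the top-10 clones each hold far more than the mean
  expect_gt(mean(sort(f, decreasing = TRUE)[1:10]), 10 * mean(f))

  # uniform-abundance mode
  uni <- simulate_repertoire(db, 50, abundance_shape = 0, seed = 4)
  expect_equal(unique(uni$clones$true_frequency), 1 / 50)

  expect_error(simulate_repertoire(db, 10, abundance_shape = -1), "non-negative")
  expect_identical(simulate_repertoire(db, 100, seed = 9)$clones,
                   simulate_repertoire(db, 100, seed = 9)$clones)
})

test_that("public pool clones are inserted verbatim in every participant", {
  db <- make_germline_db(20, 5, seed = 1)
  pool <- data.frame(
    v_gene = db$v_genes$name[1:5], j_gene = db$j_genes$name[1],
    cdr3_aa = c("CAAAAAAAAAAAAW", "CCCCCCCCCCCCCW", "CDDDDDDDDDDDDW",
                "CEEEEEEEEEEEEW", "CFFFFFFFFFFFFW"),
    stringsAsFactors = FALSE
  )
  reps <- lapply(1:3, function(i) {
    simulate_repertoire(db, 200, public_pool = pool,
                        participant = paste0("P", i), seed = 10 + i)
  })
  for (r in reps) {
    key <- with(r$clones, paste(v_gene, j_gene, cdr3_aa))
    expect_true(all(with(pool, paste(v_gene, j_gene, cdr3_aa)) %in% key))
    expect_equal(sum(r$clones$is_public), 5)
    expect_equal(sum(r$clones$true_frequency), 1, tolerance = 1e-9)
  }
})

test_that("read sampling honours depth, noise and truth-map contracts", {
  db <- make_germline_db(15, 4, seed = 1)
  rep <- simulate_repertoire(db, 100, seed = 2)

  clean <- sample_reads(rep, n_cells = 300, n_reads = 500, error_rate = 0,
                        seed = 3)
  expect_equal(nrow(clean$records), 500)
  expect_true(all(clean$records$c_region_mismatches == 0))
  expect_true(all(names(clean$truth_map) == clean$records$sequence_id))
  expect_true(all(clean$truth_map %in% rep$clones$clone_id))

  single <- simulate_repertoire(db, 1, seed = 4)
  rs <- sample_reads(single, n_cells = 50, n_reads = 100,
                     within_clone_diversification = 0, seed = 5)
  expect_equal(unique(rs$records$cdr3_aa), single$clones$cdr3_aa)

  expect_error(sample_reads(rep, n_reads = 0), "n_reads")
  expect_error(sample_reads(rep, error_rate = 1), "error_rate")

  a <- sample_reads(rep, n_cells = 100, n_reads = 200, seed = 11)
  b <- sample_reads(rep, n_cells = 100, n_reads = 200, seed = 11)
  expect_identical(as.data.frame(a$records), as.data.frame(b$records))
})

test_that("constant-region error rate is recovered from simulated reads", {
  db <- make_germline_db(10, 3, constant_length = 300, seed = 1)
  rep <- simulate_repertoire(db, 50, isotype = "IgG", seed = 2)
  # 4,000 reads x 300 nt = 1.2e6 constant nucleotides
  rs <- sample_reads(rep, n_cells = 1000, n_reads = 4000,
                     error_rate = 0.0079, seed = 3)
  est <- estimate_error_rate(rs$records)
  expect_equal(unname(est["IgG"]), 0.0079, tolerance = 0.1)
})

test_that("replicate designs behave as specified at their degenerate limits", {
  db <- make_germline_db(10, 3, seed = 1)
  rep <- simulate_repertoire(db, 20, abundance_shape = 0.5, seed = 2)

  # biological design with n_cells >> clones: every clone in every replicate
  bio <- make_replicates(rep, "biological", n_cells = 5000, n_reads = 5000,
                         within_clone_diversification = 0, seed = 3)
  for (b in bio) {
    expect_setequal(unique(b$truth_map), rep$clones$clone_id)
  }

  # temporal design with no drift and no turnover leaves the truth unchanged
  tmp <- make_replicates(rep, "temporal", drift = 0, turnover = 0,
                         n_cells = 500, n_reads = 500, seed = 4)
  expect_equal(length(tmp), 2)
  expect_true(all(unique(tmp[[2]]$truth_map) %in% rep$clones$clone_id))

  expect_error(make_replicates(rep, "nonsense"), "unknown design")
  expect_error(make_replicates(rep, "pcr", n_replicates = 1), "n_replicates")
})

test_that("abundant clusters overlap more than rare ones in PCR replicates", {
  db <- make_germline_db(15, 4, seed = 1)
  rep <- simulate_repertoire(db, 400, abundance_shape = 1.2, seed = 2)
  pcr <- make_replicates(rep, "pcr", n_cells = 800, n_reads = 1500, seed = 3)
  cs <- cluster_repertoire(pcr)
  m <- cluster_size_matrix(cs)
  ab <- classify_abundance(m) == "abundant"
  ab_ids <- rownames(m)[rowSums(ab) > 0]
  a1 <- rownames(m)[m[, 1] > 0]
  a2 <- rownames(m)[m[, 2] > 0]
  ov_all <- overlap_min(a1, a2)
  ov_ab <- overlap_min(intersect(a1, ab_ids), intersect(a2, ab_ids))
  expect_gt(ov_ab, ov_all)
})

test_that("nearest-neighbour distances of simulated reads are bimodal", {
  db <- make_germline_db(15, 4, seed = 1)
  rep <- simulate_repertoire(db, 500, abundance_shape = 1.2, seed = 2)
  rs <- sample_reads(rep, n_cells = 1000, n_reads = 1500,
                     within_clone_diversification = 0.02, seed = 3)
  nn <- nn_distances(rs$records$cdr3_aa)
  d <- as.integer(names(nn$histogram))
  counts <- as.integer(nn$histogram)
  near <- sum(counts[d <= 2])
  far <- sum(counts[d >= 3])
  expect_gt(near, 0)
  expect_gt(far, 0)
  # first mode within 0-2, second mode at >= 3
  expect_lte(d[which.max(counts)], 2)
  far_counts <- counts[d >= 3]
  expect_gte(d[d >= 3][which.max(far_counts)], 3)
})

test_that("simulated FASTQ reads carry consistent qualities", {
  reads <- simulate_fastq(50, read_length = 100, seed = 1)
  expect_equal(nchar(reads$sequence), nchar(reads$quality))
  expect_identical(simulate_fastq(20, seed = 3), simulate_fastq(20, seed = 3))
})
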