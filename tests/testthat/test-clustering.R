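# Nearest-neighbour distances, the clustering rule, thresholds and
# cluster-level annotation.

test_that("nearest-neighbour distances match hand and brute-force oracles", {
  nn <- nn_distances(c("AAAA", "AAAB", "CCCC"))
  expect_equal(unname(nn$distances[c("AAAA", "AAAB", "CCCC")]), c(1, 1, 4))

  same <- nn_distances(rep("CARW", 5))
  expect_true(all(same$distances == 0))

  # sequences with no same-length comparator are excluded but counted
  mix <- nn_distances(c("AAAA", "AAAB", "CCCCCC"))
  expect_equal(length(mix$distances), 2)
  expect_equal(mix$n_excluded, 1)

  expect_error(nn_distances(character(0)), "empty")

  # random set against the O(n^2) oracle
  withr::with_seed(11, {
    seqs <- replicate(300, paste(sample(LETTERS[1:5], sample(4:7, 1),
                                        replace = TRUE), collapse = ""))
  })
  nn <- nn_distances(seqs)
  oracle <- oracle_nn(seqs)
  expect_equal(unname(nn$distances), oracle[!is.na(oracle)])
  expect_equal(sum(as.integer(nn$histogram)), sum(!is.na(oracle)))
})

test_that("allowed mismatch budget is the floor of L / k", {
  expect_equal(allowed_mismatches(12, 12), 1)
  expect_equal(allowed_mismatches(24, 12), 2)
  expect_equal(allowed_mismatches(11, 12), 0)
  expect_equal(allowed_mismatches(11, 12, at_least_one = TRUE), 1)
  expect_equal(allowed_mismatches(c(4, 8, 26), 4), c(1, 2, 6))
  expect_error(allowed_mismatches(0, 12), "cdr3_length")
})

test_that("clustering requires shared V/J/length and links similar CDR3s", {
  s <- repertoire_sample(data.frame(
    sequence_id = c("a", "b", "c"),
    v_call = "IGHV1-1", j_call = "IGHJ4",
    cdr3_aa = c("CARDYWGQGTLV", "CARDYWGQGTLW", "CTTTTTTTTTTV"),
    stringsAsFactors = FALSE))
  cs <- cluster_repertoire(s, k = 12)
  expect_equal(nrow(cs$clusters), 2)
  two <- cs$membership$cluster_id
  expect_equal(two[1], two[2])
  expect_false(two[1] == two[3])

  # identical CDR3s on different V genes stay apart
  s2 <- repertoire_sample(data.frame(
    sequence_id = c("a", "b"),
    v_call = c("IGHV1-1", "IGHV2-1"), j_call = "IGHJ4",
    cdr3_aa = "CARDYWGQGTLV", stringsAsFactors = FALSE))
  expect_equal(nrow(cluster_repertoire(s2)$clusters), 2)

  # empty CDR3s are skipped with a warning
  s3 <- repertoire_sample(data.frame(
    sequence_id = c("a", "b"), v_call = "V", j_call = "J",
    cdr3_aa = c("CARW", ""), stringsAsFactors = FALSE))
  expect_warning(cs3 <- cluster_repertoire(s3), "empty CDR3")
  expect_equal(nrow(cs3$membership), 1)
})

test_that("clustering equals the brute-force graph oracle and is order-invariant", {
  fx <- make_fixture(seed = 21, n_clones = 80, n_cells = 300, n_reads = 500)
  rec <- fx$rs$records

  cs <- cluster_repertoire(fx$rs, k = 12)
  expect_equal(nrow(cs$membership), nrow(rec))          # partition: all once
  expect_false(anyDuplicated(cs$membership$sequence_id) > 0)

  oracle <- oracle_partition(rec$v_call, rec$j_call, rec$cdr3_aa, k = 12)
  got <- cs$membership$cluster_id[match(rec$sequence_id,
                                        cs$membership$sequence_id)]
  expect_true(same_partition(got, as.character(oracle)))

  # shuffling the input rows leaves the partition unchanged
  perm <- withr::with_seed(5, sample(nrow(rec)))
  shuffled <- repertoire_sample(rec[perm, ],
                                participant = attr(rec, "participant"))
  cs2 <- cluster_repertoire(shuffled, k = 12)
  got2 <- cs2$membership$cluster_id[match(rec$sequence_id,
                                          cs2$membership$sequence_id)]
  expect_identical(got, got2)
})

test_that("threshold scan is monotone and strict thresholds fail 2-AA pairs", {
  fx <- make_fixture(seed = 31, n_clones = 60, n_cells = 200, n_reads = 300)
  tab <- threshold_scan(fx$rs, k_values = c(4, 8, 12, 26))
  expect_equal(tab$k, c(4, 8, 12, 26))
  expect_true(all(diff(tab$n_clusters) >= 0))   # coarser k merges clusters

  # at k = 26 a 2-AA-separated pair of length < 52 is never clustered
  pair <- repertoire_sample(data.frame(
    sequence_id = c("a", "b"), v_call = "V", j_call = "J",
    cdr3_aa = c("CARDYWGQGTLV", "CARDYWGQGTAA"), stringsAsFactors = FALSE))
  expect_equal(nrow(cluster_repertoire(pair, k = 26)$clusters), 2)
  expect_equal(nrow(cluster_repertoire(pair, k = 6)$clusters), 1)
})

test_that("cluster centers are modal with lexicographic ties", {
  expect_equal(cluster_center(c(rep("X", 5), rep("Y", 2))), "X")
  expect_equal(cluster_center(c("Y", "X", "Y", "X", "Z", "Z")), "X")
  expect_equal(cluster_center("CARW"), "CARW")
  expect_error(cluster_center(character(0)), "empty")
})

test_that("abundance classification uses the 10-sequence threshold", {
  expect_equal(classify_abundance(c(9, 10, 11)),
               c("rare", "abundant", "abundant"))
  # 10 sequences of a 100,000-deep sample is 0.01% relative abundance
  expect_equal(10 / 100000 * 100, 0.01)
})

test_that("cluster annotations match direct recomputation", {
  fx <- make_fixture(seed = 41, n_clones = 50, n_cells = 200, n_reads = 400)
  cs <- annotate_clusters(cluster_repertoire(fx$rs), fx$rs)
  rec <- as.data.frame(fx$rs$records)

  for (cid in utils::head(cs$clusters$cluster_id, 10)) {
    ids <- cs$membership$sequence_id[cs$membership$cluster_id == cid]
    members <- rec[rec$sequence_id %in% ids, ]
    expect_equal(cs$clusters$mean_v_mutations[cs$clusters$cluster_id == cid],
                 mean(members$v_mutation_count))
    sc <- cs$subclass_counts[cs$subclass_counts$cluster_id == cid, ]
    expect_equal(sum(sc$count), nrow(members))
    expect_equal(sort(setNames(sc$count, sc$subclass)),
                 sort(table(members$subclass), method = "radix"),
                 ignore_attr = TRUE)
  }

  # hand fixture: mutations {2, 4} average to 3
  s <- repertoire_sample(data.frame(
    sequence_id = c("a", "b"), v_call = "V", j_call = "J",
    cdr3_aa = "CARW", v_mutation_count = c(2, 4), subclass = "IgG1",
    stringsAsFactors = FALSE))
  cs2 <- annotate_clusters(cluster_repertoire(s), s)
  expect_equal(cs2$clusters$mean_v_mutations, 3)
  expect_equal(cs2$subclass_counts$count, 2)
})

test_that("clustering collapses the first nearest-neighbour peak", {
  db <- make_germline_db(15, 4, seed = 1)
  rep <- simulate_repertoire(db, 400, abundance_shape = 1.2, seed = 2)
  rs <- sample_reads(rep, n_cells = 800, n_reads = 1200,
                     within_clone_diversification = 0.02, seed = 3)
  cs <- cluster_repertoire(rs)

  before <- nn_distances(rs$records$cdr3_aa)
  after <- nn_distances(cs$clusters$center_cdr3, level = "cluster_center")
  peak1 <- function(nn) {
    d <- as.integer(names(nn$histogram))
    sum(as.integer(nn$histogram)[d <= 2]) / sum(as.integer(nn$histogram))
  }
  expect_lt(peak1(after), peak1(before))
})
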