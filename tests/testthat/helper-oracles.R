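# Independent oracles used to cross-check the package implementations.
# These deliberately use naive character-level loops (and igraph for graph
# components) rather than the package's own machinery.

# Naive Hamming distance via character splitting.
oracle_hamming <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(x != y)
}

# O(n^2) nearest-neighbour distances: same-length comparators only,
# NA when a sequence has no comparator.
oracle_nn <- function(seqs) {
  n <- length(seqs)
  len <- nchar(seqs)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- NA_integer_
    for (j in seq_len(n)) {
      if (i == j || len[i] != len[j]) next
      d <- oracle_hamming(seqs[i], seqs[j])
      if (is.na(best) || d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Brute-force clonal partition: full pairwise graph within each
# (v, j, length) stratum, components via igraph.
oracle_partition <- function(v, j, cdr3, k) {
  n <- length(cdr3)
  len <- nchar(cdr3)
  edges <- integer(0)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (v[a] != v[b] || j[a] != j[b] || len[a] != len[b]) next
      if (oracle_hamming(cdr3[a], cdr3[b]) <= len[a] %/% k)
        edges <- c(edges, a, b)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# Two labelings induce the same partition iff their canonical forms
# (labels renumbered by first occurrence) coincide.
same_partition <- function(l1, l2) {
  identical(match(l1, unique(l1)), match(l2, unique(l2)))
}

# Small standard pipeline fixture shared across tests.
make_fixture <- function(seed = 42, n_clones = 120, n_v = 15, n_j = 4,
                         n_cells = 400, n_reads = 600,
                         abundance_shape = 1.5, error_rate = 0.002) {
  db <- make_germline_db(n_v, n_j, seed = seed)
  rep <- simulate_repertoire(db, n_clones, abundance_shape = abundance_shape,
                             seed = seed + 1)
  rs <- sample_reads(rep, n_cells = n_cells, n_reads = n_reads,
                     error_rate = error_rate, seed = seed + 2)
  list(db = db, rep = rep, rs = rs)
}
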