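# Shared fixtures and independent oracles for the test suite.

# one table for the whole suite; it is an immutable constant
TBL <- build_weight_table()

# brute-force tally: count occurrences of each canonical triplet by direct
# string comparison (independent of match()/tabulate() in the package)
brute_tally <- function(triplets) {
  vapply(TBL$canonical_order,
         function(t) sum(triplets == t), integer(1))
}

# random raw sequence with the kinds of noise clean_sequence must handle
random_messy <- function(n) {
  chars <- sample(c("a", "c", "g", "t", "A", "C", "G", "T", "u", "U",
                    " ", "\n", "\t", "1", "7"), n, replace = TRUE)
  paste(chars, collapse = "")
}

# random profile as a bare count vector in canonical order
random_profile <- function(lambda = 3) {
  counts <- stats::rpois(64, lambda)
  triplet_counts(rep(TBL$canonical_order, counts), TBL)
}

# all root-to-leaf path lengths of a rooted tree
leaf_depths <- function(tree) {
  d <- ape::dist.nodes(tree)
  root <- ape::Ntip(tree) + 1L
  d[root, seq_len(ape::Ntip(tree))]
}
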