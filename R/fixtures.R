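# The packaged 11-species beta-globin benchmark and a seeded random
# coding-sequence generator for property tests.

#' Load the 11-species beta-globin benchmark sequences
#'
#' The complete coding sequences of the beta-globin genes of human,
#' chimpanzee, gorilla, black lemur, Norway rat, house mouse, goat, bovine,
#' rabbit, opossum and Gallus (chicken), as printed in the published
#' benchmark, in that order. These are the standard test bed for
#' alignment-free DNA comparison methods. No network access is needed; the
#' same records ship as a FASTA file under
#' `system.file("extdata", "betaglobin.fasta", package = "tripletWD")`.
#'
#' The Gallus record is transcribed exactly as printed, although the
#' published distance matrix is only consistent with a variant of it in
#' which one AGG codon reads GAT; see the vignette for the reconciliation
#' analysis.
#'
#' @return named character vector of 11 coding sequences (ids use
#'   underscores: `Black_lemur`, `Norway_rat`, `House_mouse`).
#' @examples
#' seqs <- load_betaglobin()
#' nchar(seqs["Human"])  # 444
#' @export
load_betaglobin <- function() {
  .wd_betaglobin
}

#' Published reference weight-deviation matrix for the benchmark
#'
#' The published pairwise weight-deviation values for the 11-species
#' beta-globin benchmark, as a full symmetric matrix. Used by
#' [reproduce()] to report the agreement between recomputed and published
#' values; it is reference data, not a computation.
#'
#' @return an 11 x 11 symmetric numeric matrix, labels as in
#'   [load_betaglobin()].
#' @export
reference_matrix <- function() {
  labs <- names(.wd_betaglobin)
  upper <- list(
    c(5.2500, 4.3359, 8.5891, 10.670, 9.7047, 8.2219, 8.1438, 7.8281,
      15.6078, 16.7109),
    c(1.1266, 8.0297, 10.645, 9.6016, 8.4375, 9.3219, 9.6000, 14.2578,
      15.8734),
    c(7.8688, 9.9625, 8.6063, 7.6734, 8.5578, 8.5547, 13.9719, 14.8781),
    c(8.7219, 9.5500, 7.1328, 9.3891, 5.6891, 12.9281, 15.2000),
    c(6.0750, 7.0484, 9.3641, 9.6578, 13.5906, 14.1219),
    c(9.4953, 9.2641, 10.7984, 12.3406, 12.3688),
    c(5.2625, 8.7219, 11.9703, 14.5359),
    c(9.2906, 12.5922, 15.0234),
    c(14.8984, 15.6953),
    c(14.2750)
  )
  m <- matrix(0, 11, 11, dimnames = list(labs, labs))
  for (i in 1:10) {
    m[i, (i + 1):11] <- upper[[i]]
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Generate a random coding sequence
#'
#' Samples `n_codons` triplets uniformly and independently from the 64
#' possible triplets, deterministically for a given seed. Intended for
#' property tests; it emulates only the alphabet and frame structure of
#' coding sequences, not codon-usage bias, start/stop placement, or GC
#' content.
#'
#' @param n_codons positive integer, number of triplets.
#' @param seed integer seed; the generator does not disturb the caller's
#'   random-number state.
#' @param id identifier for the record (default `"random"`).
#' @return named character vector of length 1: a sequence of
#'   `3 * n_codons` bases.
#' @examples
#' random_cds(5, seed = 42)
#' @export
random_cds <- function(n_codons, seed, id = "random") {
  if (!is.numeric(n_codons) || length(n_codons) != 1L || n_codons < 1)
    stop("n_codons must be a positive integer", call. = FALSE)
  n_codons <- as.integer(n_codons)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  trips <- sample(.wd_canonical_order, n_codons, replace = TRUE)
  out <- paste(trips, collapse = "")
  names(out) <- id
  out
}
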