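# Canonical triplet weight table.
#
# Each of the 64 DNA triplets gets a distinct positive weight. The integer
# part of a weight identifies the amino-acid group (alanine = 1, arginine = 2,
# ..., stop = 21); the fractional part distinguishes synonymous triplets
# within a group. The table is a transcribed constant, not derived from a
# construction rule: a few groups start their fractional parts at .3 rather
# than .1 (aspartic acid, lysine, threonine, tryptophan), and the table is
# kept exactly as published because all downstream distances depend on it.
#
# Weights are stored internally in tenths (exact integers) so equality and
# arithmetic on them are exact; the user-facing value is tenths / 10.

# triplet, weight-in-tenths, amino-acid group --- grouped by amino acid
.wd_table_raw <- list(
  alanine       = c(GCT = 11L,  GCC = 12L,  GCA = 13L,  GCG = 14L),
  arginine      = c(CGT = 21L,  CGC = 22L,  CGA = 23L,  CGG = 24L,
                    AGA = 25L,  AGG = 26L),
  aspartic_acid = c(GAT = 33L,  GAC = 34L),
  asparagine    = c(AAT = 41L,  AAC = 42L),
  cysteine      = c(TGT = 51L,  TGC = 52L),
  glutamic_acid = c(GAA = 61L,  GAG = 62L),
  glutamine     = c(CAA = 71L,  CAG = 72L),
  glycine       = c(GGT = 81L,  GGC = 82L,  GGA = 83L,  GGG = 84L),
  histidine     = c(CAT = 91L,  CAC = 92L),
  isoleucine    = c(ATT = 101L, ATC = 102L, ATA = 103L),
  leucine       = c(CTT = 111L, CTC = 112L, CTA = 113L, CTG = 114L,
                    TTA = 115L, TTG = 116L),
  lysine        = c(AAA = 123L, AAG = 124L),
  methionine    = c(ATG = 201L),
  phenylalanine = c(TTT = 131L, TTC = 132L),
  proline       = c(CCT = 141L, CCC = 142L, CCA = 143L, CCG = 144L),
  serine        = c(TCT = 151L, TCC = 152L, TCA = 153L, TCG = 154L,
                    AGT = 155L, AGC = 156L),
  threonine     = c(ACT = 163L, ACC = 164L, ACA = 165L, ACG = 166L),
  tryptophan    = c(TGG = 173L),
  tyrosine      = c(TAT = 181L, TAC = 182L),
  valine        = c(GTT = 191L, GTC = 192L, GTA = 193L, GTG = 194L),
  stop          = c(TAA = 211L, TAG = 212L, TGA = 213L)
)

# T1 = GCT ... T64 = TGA: the enumeration every 64-long profile vector and
# the weight-deviation sum are indexed by.
.wd_canonical_order <- c(
  "GCT", "GCC", "GCA", "GCG", "CGT", "CGC", "CGA", "CGG", "AGA", "AGG",
  "GAT", "GAC", "AAT", "AAC", "TGT", "TGC", "GAA", "GAG", "CAA", "CAG",
  "GGT", "GGC", "GGA", "GGG", "CAT", "CAC", "ATT", "ATC", "ATA", "CTT",
  "CTC", "CTA", "CTG", "TTA", "TTG", "AAA", "AAG", "TTT", "TTC", "CCT",
  "CCC", "CCA", "CCG", "TCT", "TCC", "TCA", "TCG", "AGT", "AGC", "ACT",
  "ACC", "ACA", "ACG", "TGG", "TAT", "TAC", "GTT", "GTC", "GTA", "GTG",
  "ATG", "TAA", "TAG", "TGA"
)

#' Build the canonical 64-triplet weight table
#'
#' Returns the full triplet-to-weight mapping together with its amino-acid
#' group metadata and the canonical triplet enumeration \eqn{T_1 =
#' \mathrm{GCT}, \ldots, T_{64} = \mathrm{TGA}} used to index profile
#' vectors. The integer part of a weight is the amino-acid group index
#' (1--21, where 21 is the stop group); the fractional part separates
#' synonymous triplets, so weight gaps within an amino-acid group are always
#' smaller than gaps across groups (see [verify_ordering_rule()]).
#'
#' @return An object of class `wd_weight_table`: a list with
#'   \describe{
#'     \item{weights}{named numeric vector of length 64, names in canonical
#'       order, values the triplet weights (dimensionless, one decimal).}
#'     \item{tenths}{the same weights as exact integers in tenths.}
#'     \item{amino_acid}{named character vector mapping each triplet to its
#'       amino-acid group label (one of the 20 amino acids or `"stop"`).}
#'     \item{groups}{data.frame with one row per amino-acid group:
#'       `name`, `integer_part`, `n_triplets`.}
#'     \item{canonical_order}{character vector, the 64 triplets in
#'       enumeration order.}
#'   }
#' @examples
#' tbl <- build_weight_table()
#' weight_of(tbl, c("GCT", "ATG"))
#' @export
build_weight_table <- function() {
  tenths <- unlist(unname(.wd_table_raw))
  amino <- rep(names(.wd_table_raw),
               lengths(.wd_table_raw))
  names(amino) <- names(tenths)
  # reindex everything to canonical enumeration order
  tenths <- tenths[.wd_canonical_order]
  amino <- amino[.wd_canonical_order]
  groups <- data.frame(
    name = names(.wd_table_raw),
    integer_part = vapply(.wd_table_raw, function(x) x[[1]] %/% 10L,
                          integer(1)),
    n_triplets = lengths(.wd_table_raw),
    row.names = NULL
  )
  structure(
    list(
      weights = tenths / 10,
      tenths = tenths,
      amino_acid = amino,
      groups = groups,
      canonical_order = .wd_canonical_order
    ),
    class = "wd_weight_table"
  )
}

#' @export
print.wd_weight_table <- function(x, ...) {
  cat("Triplet weight table: 64 triplets,",
      nrow(x$groups), "amino-acid groups\n")
  cat("  canonical order:", x$canonical_order[1], "...",
      x$canonical_order[64], "\n")
  cat("  weights:", format(x$weights[1], nsmall = 1), "...",
      format(x$weights[64], nsmall = 1), "\n")
  invisible(x)
}

# Validate triplets and canonicalise (uppercase, U -> T). Errors name the
# first offending string.
.wd_check_triplets <- function(t, strict = TRUE) {
  t <- chartr("u", "U", toupper(as.character(t)))
  t <- chartr("U", "T", t)
  bad <- nchar(t) != 3L | grepl("[^ACGT]", t)
  if (any(bad) && strict) {
    stop("invalid triplet: '", t[which(bad)[1]],
         "' (must be 3 characters over A/C/G/T)", call. = FALSE)
  }
  attr(t, "invalid") <- bad
  t
}

#' Look up triplet weights
#'
#' Vectorised lookup of the weight of one or more triplets. RNA codons
#' (containing U) are accepted and transliterated U to T; lowercase input is
#' uppercased.
#'
#' @param table a `wd_weight_table` from [build_weight_table()].
#' @param t character vector of triplets.
#' @return numeric vector of weights, same length as `t`.
#' @examples
#' tbl <- build_weight_table()
#' weight_of(tbl, "GCT")  # 1.1
#' weight_of(tbl, "AUG")  # 20.1 (RNA codon accepted)
#' @export
weight_of <- function(table, t) {
  stopifnot(inherits(table, "wd_weight_table"))
  t <- .wd_check_triplets(t, strict = TRUE)
  unname(table$weights[t])
}

#' Look up the amino acid encoded by a triplet
#'
#' @inheritParams weight_of
#' @return character vector of amino-acid group labels (`"stop"` for the
#'   three termination triplets), consistent with the integer part of
#'   [weight_of()].
#' @examples
#' tbl <- build_weight_table()
#' amino_acid_of(tbl, c("GCT", "TGA"))
#' @export
amino_acid_of <- function(table, t) {
  stopifnot(inherits(table, "wd_weight_table"))
  t <- .wd_check_triplets(t, strict = TRUE)
  unname(table$amino_acid[t])
}

#' Verify the weight ordering rule
#'
#' The weighting scheme is meant to guarantee that any two synonymous
#' triplets are closer in weight than any two triplets encoding different
#' amino acids. This checks the property by exhaustive enumeration of all
#' 2016 unordered triplet pairs and reports both extremes.
#'
#' @param table a `wd_weight_table` (possibly modified, e.g. in tests).
#' @return list with `max_within` (largest same-group weight gap),
#'   `min_between` (smallest cross-group gap), `pass` (`max_within <
#'   min_between`), and `degenerate` (`TRUE` if there are no cross-group
#'   pairs to compare, in which case `pass` is vacuously `TRUE`).
#' @examples
#' verify_ordering_rule(build_weight_table())
#' @export
verify_ordering_rule <- function(table) {
  stopifnot(inherits(table, "wd_weight_table"))
  n <- length(table$tenths)
  pairs <- utils::combn(n, 2)
  gap <- abs(table$tenths[pairs[1, ]] - table$tenths[pairs[2, ]])
  same <- table$amino_acid[pairs[1, ]] == table$amino_acid[pairs[2, ]]
  degenerate <- !any(!same)
  max_within <- if (any(same)) max(gap[same]) / 10 else 0
  min_between <- if (degenerate) Inf else min(gap[!same]) / 10
  list(
    max_within = max_within,
    min_between = min_between,
    pass = max_within < min_between,
    degenerate = degenerate
  )
}

#' Export the weight table as TSV
#'
#' Writes a two-column tab-separated file (`triplet`, `weight`) with the 64
#' triplets in canonical enumeration order, weights formatted with one
#' decimal digit.
#'
#' @param table a `wd_weight_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(table, path) {
  stopifnot(inherits(table, "wd_weight_table"))
  df <- data.frame(
    triplet = table$canonical_order,
    weight = sprintf("%.1f", table$weights)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
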