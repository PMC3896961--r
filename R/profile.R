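# Triplet occurrence profiles.
#
# The profile of a sequence is the 64-long vector of occurrence counts of
# each canonical triplet T1..T64 among the sequence's frame-0 triplets;
# triplets absent from the sequence count 0. Profiles are the inputs to the
# weight-deviation distance.

#' Count triplet occurrences
#'
#' Tallies a list of triplets against the canonical 64-triplet enumeration.
#' In permissive mode, entries that are not valid ACGT triplets are excluded
#' from the tally (and from `m`).
#'
#' @param triplets character vector of triplets (e.g. from
#'   [to_triplets()]).
#' @param table a `wd_weight_table`; built internally if omitted.
#' @param id optional source-sequence identifier stored on the result.
#' @param strict logical; error on invalid triplets (default) or drop them.
#' @return an integer vector of class `wd_profile`, length 64, named by the
#'   canonical triplets, with attributes `source_id` and `m` (number of
#'   triplets tallied; equals `sum(counts)`).
#' @examples
#' triplet_counts(c("GCT", "GCT", "GCC"))
#' @export
triplet_counts <- function(triplets, table = build_weight_table(),
                           id = NULL, strict = TRUE) {
  stopifnot(inherits(table, "wd_weight_table"))
  trips <- .wd_check_triplets(triplets, strict = strict)
  trips <- trips[!attr(trips, "invalid")]
  idx <- match(trips, table$canonical_order)
  counts <- tabulate(idx, nbins = 64L)
  names(counts) <- table$canonical_order
  structure(counts, source_id = id, m = length(trips),
            class = "wd_profile")
}

#' Profile a sequence record
#'
#' Convenience composition: cleans the sequence, splits it into frame-0
#' triplets, and tallies them. Equivalent to
#' `triplet_counts(to_triplets(clean_sequence(seq)))`.
#'
#' @param seq a nucleotide string, possibly raw; may be named (the name is
#'   used as the profile's source id).
#' @inheritParams triplet_counts
#' @return a `wd_profile`.
#' @examples
#' triplet_profile(c(x = "GCTGCTG"))  # GCT counted twice, trailing G dropped
#' @export
triplet_profile <- function(seq, table = build_weight_table(), id = NULL,
                            strict = TRUE) {
  stopifnot(length(seq) == 1L)
  if (is.null(id)) id <- names(seq)[1]
  cleaned <- clean_sequence(unname(seq), strict = strict)
  triplet_counts(to_triplets(cleaned), table = table, id = id,
                 strict = strict)
}

#' @export
print.wd_profile <- function(x, ...) {
  cat("Triplet profile",
      if (!is.null(attr(x, "source_id")))
        paste0("'", attr(x, "source_id"), "'") else "",
      "- m =", attr(x, "m"), "triplets\n")
  nz <- x[x > 0]
  if (length(nz)) print(unclass(nz)) else cat("(all counts zero)\n")
  invisible(x)
}

#' Write profiles as a TSV table
#'
#' One row per profile: a `source_id` column followed by the 64 counts,
#' with the canonical triplet names as the count-column header.
#'
#' @param profiles a `wd_profile` or list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "wd_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "wd_profile"))
    id <- attr(p, "source_id")
    c(source_id = if (is.null(id)) "" else id,
      as.character(as.integer(p)))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("source_id", names(profiles[[1]]))
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
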