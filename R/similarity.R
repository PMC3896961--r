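# Weight deviation: the similarity measure.
#
# For two sequences with triplet count vectors X and Y (length 64, canonical
# order), the weight deviation is
#
#   WD(A, B) = sum_i |X_i - Y_i| * weight(T_i) / 64
#
# i.e. a weighted L1 (Manhattan) distance on count vectors, scaled by 1/64.
# Counts are absolute, not frequencies: sequences of different lengths
# accumulate length-driven deviation by construction. WD is a metric on
# profile space (identity, symmetry, triangle inequality).
#
# The sum is accumulated in exact integer tenths and divided once at the
# end (sum-then-divide), so no intermediate rounding occurs.

#' Weight deviation between two triplet profiles
#'
#' @param a,b `wd_profile` vectors aligned to the same canonical order
#'   (both length 64).
#' @param table a `wd_weight_table`; built internally if omitted.
#' @return a single nonnegative number (dimensionless weight-deviation
#'   units); 0 iff the profiles are identical.
#' @examples
#' tbl <- build_weight_table()
#' weight_deviation(triplet_profile("GCTGCT"), triplet_profile("GCT"), tbl)
#' @export
weight_deviation <- function(a, b, table = build_weight_table()) {
  stopifnot(inherits(table, "wd_weight_table"))
  if (length(a) != length(b) || length(a) != 64L) {
    stop("profiles must both be 64-long vectors aligned to the canonical ",
         "triplet order (got lengths ", length(a), " and ", length(b), ")",
         call. = FALSE)
  }
  if (!is.null(names(a)) && !identical(names(a), table$canonical_order)) {
    stop("profile 'a' is not in canonical triplet order", call. = FALSE)
  }
  if (!is.null(names(b)) && !identical(names(b), table$canonical_order)) {
    stop("profile 'b' is not in canonical triplet order", call. = FALSE)
  }
  sum(abs(as.numeric(a) - as.numeric(b)) * table$tenths) / 640
}

#' Pairwise weight-deviation matrix
#'
#' Profiles every sequence and computes all pairwise weight deviations.
#'
#' @param seqs named character vector of nucleotide sequences (>= 2, unique
#'   non-empty names); raw sequences are cleaned first.
#' @param table a `wd_weight_table`; built internally if omitted.
#' @param strict logical, passed to the cleaning/counting steps.
#' @return a symmetric numeric matrix with zero diagonal, dimnames the
#'   sequence names in input order.
#' @examples
#' pairwise_matrix(c(a = "GCTGCT", b = "GCT"))
#' @export
pairwise_matrix <- function(seqs, table = build_weight_table(),
                            strict = TRUE) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  profs <- lapply(seq_along(seqs), function(i)
    triplet_profile(seqs[i], table = table, id = ids[i], strict = strict))
  n <- length(profs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- weight_deviation(profs[[i]], profs[[j]], table)
    }
  }
  m
}

# round half away from zero at k decimals (display convention; base round()
# uses round-half-even, which disagrees on exact .5 ties such as x.x5625)
round_half_up <- function(x, k) {
  sign(x) * floor(abs(x) * 10^k + 0.5) / 10^k
}

#' Write a distance matrix
#'
#' @param m symmetric numeric matrix with dimnames, e.g. from
#'   [pairwise_matrix()].
#' @param path output file path.
#' @param format one of
#'   \describe{
#'     \item{`"csv"`}{full square matrix, label header row and first
#'       column, entries to 4 decimals.}
#'     \item{`"phylip"`}{standard square PHYLIP distance matrix (taxon
#'       count on the first line).}
#'     \item{`"triangle"`}{upper-triangle layout with a zero diagonal, as
#'       similarity tables are conventionally printed.}
#'   }
#' @return `path`, invisibly.
#' @seealso [read_matrix()] for reading `csv`/`phylip` back.
#' @export
write_matrix <- function(m, path, format = c("csv", "phylip", "triangle")) {
  format <- match.arg(format)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  labs <- rownames(m)
  fm <- matrix(sprintf("%.4f", round_half_up(m, 4)), nrow(m),
               dimnames = dimnames(m))
  out <- tryCatch(switch(format,
    csv = {
      df <- data.frame(id = labs, fm, check.names = FALSE)
      utils::write.table(df, path, sep = ",", quote = FALSE,
                         row.names = FALSE)
    },
    phylip = {
      lines <- c(format(nrow(m)),
                 vapply(seq_len(nrow(m)), function(i) {
                   paste(c(formatC(labs[i], width = -10), fm[i, ]),
                         collapse = "  ")
                 }, character(1)))
      writeLines(lines, path)
    },
    triangle = {
      lines <- vapply(seq_len(nrow(m)), function(i) {
        cells <- c(rep("", i - 1L), "0", fm[i, seq_len(ncol(m)) > i])
        paste(c(labs[i], cells), collapse = "\t")
      }, character(1))
      writeLines(c(paste(c("", labs), collapse = "\t"), lines), path)
    }),
    error = function(e) stop("cannot write matrix to '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a distance matrix written by [write_matrix()]
#'
#' Accepts the `csv` and `phylip` formats.
#'
#' @param path input file path.
#' @param format `"csv"` or `"phylip"`; guessed from the extension when
#'   omitted (`.csv` vs anything else).
#' @return symmetric numeric matrix with dimnames.
#' @export
read_matrix <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv"
              else "phylip"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  } else {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1]))
    parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
    labs <- vapply(parts, `[`, character(1), 1)
    m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
    dimnames(m) <- list(labs, labs)
  }
  storage.mode(m) <- "double"
  m
}
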