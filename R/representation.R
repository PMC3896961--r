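# Sequence handling and the 2D plot-set representation.
#
# A coding sequence G = g1..gN is read in frame 0 as M = floor(N/3)
# consecutive non-overlapping triplets t1..tM; the plot set is the ordered
# pairs (i, weight(t_i)) for i = 1..M (1-based). Sequences are modelled as
# named character vectors: names are record ids, values are the nucleotide
# strings.

#' Clean a raw nucleotide string
#'
#' Uppercases, transliterates U to T, and strips whitespace and digits
#' (tolerating sequences pasted with line numbers). In strict mode (the
#' default) any remaining non-ACGT character is an error reporting the first
#' offending character and its 1-based position in the stripped string; in
#' permissive mode such characters are kept (so downstream triplet counting
#' can exclude the triplets containing them) and reported via a warning.
#'
#' Cleaning is idempotent: `clean_sequence(clean_sequence(x))` equals
#' `clean_sequence(x)`.
#'
#' @param raw a character scalar (or vector, cleaned element-wise).
#' @param strict logical; error on non-ACGT characters (default `TRUE`).
#' @return cleaned character vector, names preserved.
#' @examples
#' clean_sequence("atg gug\ncac")  # "ATGGTGCAC"
#' @export
clean_sequence <- function(raw, strict = TRUE) {
  out <- vapply(raw, function(x) {
    x <- toupper(as.character(x))
    x <- gsub("[[:space:][:digit:]]", "", x)
    x <- chartr("U", "T", x)
    if (nzchar(x)) {
      chars <- strsplit(x, "", fixed = TRUE)[[1]]
      bad <- which(!chars %in% c("A", "C", "G", "T"))
      if (length(bad)) {
        msg <- paste0("non-ACGT character '", chars[bad[1]],
                      "' at position ", bad[1])
        if (strict) stop(msg, call. = FALSE)
        warning(msg, " (kept; containing triplet will be excluded ",
                "from counting)", call. = FALSE)
      }
    }
    x
  }, character(1))
  names(out) <- names(raw)
  out
}

#' Split a cleaned sequence into frame-0 triplets
#'
#' Reads consecutive non-overlapping triplets from position 1; a trailing
#' partial codon of 1--2 bases is dropped (the triplet count is
#' `floor(nchar(seq) / 3)`).
#'
#' @param seq a single cleaned nucleotide string.
#' @return character vector of triplets (length 0 for sequences shorter
#'   than 3).
#' @examples
#' to_triplets("ATGGTGCACC")  # "ATG" "GTG" "CAC"; trailing C dropped
#' @export
to_triplets <- function(seq) {
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  m <- n %/% 3L
  if (m == 0L) return(character(0))
  dropped <- n - 3L * m
  if (dropped > 0L) {
    message("dropping ", dropped, " trailing base(s) (incomplete codon)")
  }
  substring(seq, 3L * seq_len(m) - 2L, 3L * seq_len(m))
}

#' Map a sequence to its 2D plot set
#'
#' The plot set of a sequence with triplets \eqn{t_1 \ldots t_M} is the
#' ordered pairs \eqn{(i, \Psi(t_i))}, \eqn{i = 1..M}, where \eqn{\Psi} is
#' the triplet weight. Plotting index against weight gives the sequence's
#' 2D graphical representation.
#'
#' @param seq a nucleotide string (cleaned with [clean_sequence()] first if
#'   raw); may be named, in which case the name becomes the plot-set id.
#' @param table a `wd_weight_table`; built internally if omitted.
#' @param id optional id overriding the name of `seq`.
#' @return a data.frame of class `wd_plot_set` with integer column `index`
#'   (1-based) and numeric column `weight`, plus an `id` attribute.
#' @examples
#' to_plot_set(c(demo = "GCTGCC"))
#' @export
to_plot_set <- function(seq, table = build_weight_table(), id = NULL) {
  trips <- to_triplets(unname(seq))
  w <- if (length(trips)) weight_of(table, trips) else numeric(0)
  ps <- data.frame(index = seq_along(w), weight = w)
  class(ps) <- c("wd_plot_set", "data.frame")
  attr(ps, "id") <- if (!is.null(id)) id else names(seq)[1]
  ps
}

#' @export
print.wd_plot_set <- function(x, ...) {
  id <- attr(x, "id")
  cat("Plot set", if (!is.null(id)) paste0("'", id, "'") else "",
      "with", nrow(x), "points\n")
  if (nrow(x)) print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write a plot set to TSV
#'
#' Two columns `index` and `weight`, tab-separated with a header row;
#' weights are written with one decimal digit (their exact precision).
#'
#' @param ps a `wd_plot_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_plot_set()] for the inverse.
#' @export
write_plot_set <- function(ps, path) {
  df <- data.frame(index = ps$index, weight = sprintf("%.1f", ps$weight))
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop("cannot write plot set to '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Read a plot set written by [write_plot_set()]
#'
#' @param path TSV file path.
#' @return a `wd_plot_set` data.frame.
#' @export
read_plot_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "numeric"))
  class(df) <- c("wd_plot_set", "data.frame")
  df
}

#' Render a plot set as a figure file
#'
#' Draws the 2D graphical representation (triplet index on the horizontal
#' axis, weight on the vertical axis) to a PNG or SVG file chosen by the
#' file extension. Points are joined by thin lines by default, which makes
#' the weight trajectory easier to follow for long sequences; set
#' `type = "p"` for markers only.
#'
#' @param ps a `wd_plot_set`.
#' @param path output figure path ending in `.png` or `.svg`.
#' @param title plot title (defaults to the plot-set id, if any).
#' @param type base-graphics plot type, `"o"` (default), `"p"` or `"l"`.
#' @return `path`, invisibly.
#' @export
render_plot <- function(ps, path, title = attr(ps, "id"), type = "o") {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
    png = function(p) grDevices::png(p, width = 900, height = 450),
    svg = function(p) grDevices::svg(p, width = 9, height = 4.5),
    stop("unsupported figure format '", ext, "' for '", path,
         "' (use .png or .svg)", call. = FALSE)
  )
  dev(path)
  on.exit(grDevices::dev.off())
  if (nrow(ps)) {
    graphics::plot(ps$index, ps$weight, type = type, pch = 20, cex = 0.5,
                   xlab = "triplet index", ylab = "weight",
                   main = if (is.null(title)) "" else title)
  } else {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 22),
                   xlab = "triplet index", ylab = "weight",
                   main = if (is.null(title)) "" else title)
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Standard single- or multi-record FASTA; the record id is the header up
#' to the first whitespace. Sequences are returned cleaned (uppercase,
#' U transliterated to T).
#'
#' @param path FASTA file path.
#' @param strict logical, passed to [clean_sequence()].
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, strict = TRUE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  clean_sequence(seqs, strict = strict)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = 60L)
  invisible(path)
}
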