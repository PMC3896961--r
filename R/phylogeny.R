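# Tree construction from a weight-deviation matrix.
#
# Weight deviations form a distance matrix suitable for the standard
# distance-based tree methods. UPGMA (average-linkage agglomeration,
# producing a rooted ultrametric tree) is the default; Saitou-Nei
# neighbor joining is available for an unrooted alternative.

#' Build a phylogenetic tree from a distance matrix
#'
#' @param m symmetric numeric matrix with dimnames (e.g. from
#'   [pairwise_matrix()] or [read_matrix()]).
#' @param method `"upgma"` (default; average-linkage clustering, rooted
#'   ultrametric tree) or `"nj"` (neighbor joining, unrooted; requires at
#'   least 3 taxa). NJ branch lengths that come out marginally negative are
#'   clamped to zero.
#' @return an [ape::phylo] tree whose tip labels are the matrix labels.
#' @examples
#' m <- pairwise_matrix(c(a = "GCTGCT", b = "GCT", c = "ATGATG"))
#' build_tree(m)
#' @export
build_tree <- function(m, method = c("upgma", "nj")) {
  method <- match.arg(method)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  n <- nrow(m)
  if (method == "upgma" && n < 2L)
    stop("UPGMA needs at least 2 taxa", call. = FALSE)
  if (method == "nj" && n < 3L)
    stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  d <- stats::as.dist(m)
  tree <- if (method == "upgma") {
    ape::as.phylo(stats::hclust(d, method = "average"))
  } else {
    ape::nj(d)
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Serialize a tree to Newick
#'
#' Standard parenthesized Newick with branch lengths (6 significant
#' digits), terminated by a semicolon. Tip labels containing spaces are
#' quoted per the Newick convention.
#'
#' @param tree an [ape::phylo] object.
#' @param path optional file path; when given the string is also written
#'   there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$tip.label
  needs_quote <- grepl("[][(),:; \t]", lab)
  # write.tree rewrites awkward labels, so emit placeholders and restore
  # them quoted afterwards
  token <- sprintf("wdTIP%06d", seq_along(lab))
  tree$tip.label[needs_quote] <- token[needs_quote]
  nwk <- ape::write.tree(tree, digits = 10)
  for (i in which(needs_quote)) {
    nwk <- sub(token[i], paste0("'", lab[i], "'"), nwk, fixed = TRUE)
  }
  # fixed 6-decimal branch lengths
  mt <- gregexpr(":[0-9]+\\.?[0-9]*(e[+-]?[0-9]+)?", nwk)
  regmatches(nwk, mt) <- list(sprintf(
    ":%.6f", as.numeric(sub("^:", "", regmatches(nwk, mt)[[1]]))))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
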