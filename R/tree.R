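#' Read a phylogenetic tree from a Newick file
#'
#' A thin wrapper around [ape::read.tree()] that additionally checks that
#' every edge carries a finite, non-negative branch length (in expected
#' substitutions per site).  Trees may be rooted or unrooted; the likelihood
#' is invariant to root placement under a reversible model.
#'
#' @param path path to a Newick file (or use `text`).
#' @param text Newick string, as an alternative to `path`.
#' @param default_branch_length optional length substituted for edges that
#'   have none; by default missing lengths are an error.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path = NULL, text = NULL, default_branch_length = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop("newick format error: ", conditionMessage(e)),
    warning = function(w) stop("newick format error: ", conditionMessage(w)))
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("newick format error: could not parse tree")
  if (is.null(tr$edge.length)) {
    if (is.null(default_branch_length))
      stop("newick format error: tree has no branch lengths")
    tr$edge.length <- rep(default_branch_length, nrow(tr$edge))
  }
  bad <- !is.finite(tr$edge.length) | tr$edge.length < 0
  if (any(bad)) {
    if (is.null(default_branch_length))
      stop("newick format error: ", sum(bad),
           " edge(s) with missing or negative branch lengths")
    tr$edge.length[bad] <- default_branch_length
  }
  tr
}

#' The canonical four-taxon simulation tree
#'
#' A balanced quartet of four sequences in which every branch is 0.2
#' expected substitutions per site, so the total tree length is exactly 1:
#' on average a site experiences a single substitution, which makes
#' single-site rate estimation deliberately hard.
#'
#' @return An [ape::phylo] object with taxa `t1`..`t4`.
#' @examples
#' sum(simulation_tree()$edge.length)  # 1
#' @export
simulation_tree <- function() {
  read_newick(text = "((t1:0.2,t2:0.2):0.2,t3:0.2,t4:0.2);")
}
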