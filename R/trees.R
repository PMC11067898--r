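#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] adding the checks the niche
#' pipeline relies on: unique tip labels, branch lengths present and
#' non-negative.
#'
#' @param path Newick file path.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  validate_tree(tree)
}

#' @rdname read_newick
#' @param text Newick string (alternative to a file).
#' @export
read_newick_text <- function(text) {
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("branch lengths required")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  tree
}

#' Write a phylogeny to a Newick file
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Graft a missing taxon onto a tree as sister to an existing tip
#'
#' Inserts a new tip as sister to `sister`, attaching it at the midpoint of
#' the sister's terminal branch: the new internal node sits halfway between
#' the sister tip and its parent node, and the new tip's branch length
#' equals the remaining half. This is the usual way to add a taxon known
#' from independent evidence to form a sister pair when it is missing from
#' a molecular tree.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param new_tip label for the grafted taxon.
#' @param sister label of the existing tip it is sister to.
#' @return A `phylo` object with one more tip; all other pairwise tip path
#'   lengths are unchanged.
#' @export
graft_taxon <- function(tree, new_tip, sister) {
  validate_tree(tree)
  if (new_tip %in% tree$tip.label)
    stop("tip `", new_tip, "` already present")
  wh <- match(sister, tree$tip.label)
  if (is.na(wh)) stop("sister tip `", sister, "` not found")
  edge_len <- tree$edge.length[tree$edge[, 2] == wh]
  if (edge_len == 0)
    warning("grafting onto a zero-length branch; both new branches have length 0")
  half <- edge_len / 2
  phytools::bind.tip(tree, new_tip, edge.length = half, where = wh,
                     position = half)
}
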