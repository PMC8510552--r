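#' Simulate a phylogeny for synthetic OTUs
#'
#' Birth-death tree conditioned on the number of tips.  The default is a
#' pure-birth (Yule) process with rate 1, which yields an ultrametric tree
#' whose patristic distances feed the phylogenetic null models.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed optional integer seed; fixed seed gives an identical tree.
#' @param birth,death birth and death rates of the generating process.
#' @return an [ape::rphylo] `phylo` object with tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, birth = 1, death = 0) {
  if (!is.numeric(n_taxa) || n_taxa < 2)
    stop_invalid("n_taxa must be >= 2")
  with_seed(seed, {
    tree <- ape::rphylo(as.integer(n_taxa), birth = birth, death = death)
    tree$tip.label <- paste0("t", seq_len(as.integer(n_taxa)))
    tree
  })
}

#' Evolve a continuous niche trait on a tree by Brownian motion
#'
#' Standard Brownian evolution: along every branch the trait accrues a
#' Gaussian increment with variance `sigma2 * branch length`, so the tip
#' covariance equals `sigma2` times shared branch length.  This makes the
#' phylogenetic niche signal assumed by betaNTI true by construction in
#' synthetic data.
#'
#' @param tree a `phylo` object.
#' @param sigma2 Brownian rate (variance per unit branch length, >= 0).
#' @param seed optional integer seed.
#' @param root_value trait value at the root.
#' @return named numeric vector of tip trait values.
#' @export
evolve_traits <- function(tree, sigma2 = 1, seed = NULL, root_value = 0) {
  if (!inherits(tree, "phylo")) stop_invalid("tree must be a phylo object")
  if (!is.numeric(sigma2) || sigma2 < 0) stop_invalid("sigma2 must be >= 0")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  with_seed(seed, {
    vals <- numeric(n_tip + n_node)
    root <- n_tip + 1L
    vals[root] <- root_value
    # preorder traversal: parents before children
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    el <- ape::reorder.phylo(tree, "cladewise")$edge.length
    inc <- stats::rnorm(nrow(edges), 0, sqrt(sigma2 * el))
    for (k in seq_len(nrow(edges)))
      vals[edges[k, 2L]] <- vals[edges[k, 1L]] + inc[k]
    stats::setNames(vals[seq_len(n_tip)], tree$tip.label)
  })
}

#' Patristic distance matrix of a tree
#'
#' @param tree a `phylo` object.
#' @return symmetric tip x tip matrix of path-length distances.
#' @export
patristic_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}
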