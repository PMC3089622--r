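# Tree ingestion and community phylogenetic metrics.
#
# The PD used throughout is the branch-length sum of the minimal subtree
# spanning a community, rooted at the community's most recent common
# ancestor: the path from that ancestor up to the tree root is NOT counted.
# This differs from Faith's PD measured against a rooted regional tree, and
# it forces PD of a monoculture to 0 (the ancestor of one tip is the tip).

#' Read and validate a phylogeny from Newick
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream analyses rely on: unique non-empty tip labels, branch lengths
#' present on every edge, and no negative lengths. Outgroup taxa used only
#' for rooting can be pruned at load via `prune`.
#'
#' @param file Path to a Newick file, or `NULL` when `text` is given.
#' @param text Newick string (alternative to `file`).
#' @param prune Character vector of tip labels to drop after reading
#'   (e.g. outgroups); labels absent from the tree are an error.
#' @param allow_missing_lengths If `TRUE`, edges without a branch length are
#'   set to 0 instead of being rejected. Default `FALSE`: fail loudly.
#' @return An object of class `"phylo"` (ape) passing [validate_phylogeny()].
#' @examples
#' tr <- read_phylogeny(text = "((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_phylogeny <- function(file = NULL, text = NULL, prune = NULL,
                           allow_missing_lengths = FALSE) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of `file` or `text`")
  tree <- if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tree))
    stop("Newick parse error: no tree could be read")
  if (inherits(tree, "multiPhylo"))
    stop("input contains more than one tree; exactly one expected")
  if (!is.null(prune)) {
    missing <- setdiff(prune, tree$tip.label)
    if (length(missing))
      stop("prune labels not in tree: ", paste(missing, collapse = ", "))
    if (length(prune) >= length(tree$tip.label) - 1L)
      stop("pruning would leave fewer than 2 tips")
    tree <- ape::drop.tip(tree, prune)
  }
  if (is.null(tree$edge.length)) {
    if (!allow_missing_lengths)
      stop("tree has no branch lengths (set allow_missing_lengths = TRUE to impute 0)")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!allow_missing_lengths)
      stop("tree has ", sum(is.na(tree$edge.length)), " missing branch length(s)")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  validate_phylogeny(tree)
  tree
}

#' Validate phylogeny invariants
#'
#' Checks the structural invariants assumed by every metric in the package:
#' unique, non-empty tip labels; all branch lengths present and non-negative;
#' a single root (every non-root node with exactly one parent).
#'
#' @param tree A `"phylo"` object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  labs <- tree$tip.label
  if (any(!nzchar(labs)) || anyNA(labs)) stop("empty or missing tip labels")
  if (anyDuplicated(labs)) {
    dup <- unique(labs[duplicated(labs)])
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  # each node is the child of at most one edge, and only the root of none
  child_counts <- tabulate(tree$edge[, 2],
                           nbins = length(labs) + tree$Nnode)
  n_root <- sum(child_counts == 0L)
  if (any(child_counts > 1L)) stop("node with more than one parent")
  if (n_root != 1L) stop("tree must have exactly one root, found ", n_root)
  invisible(tree)
}

#' Patristic distance matrix
#'
#' Tip-to-tip path-length (patristic) distances for every pair of tips, in
#' the branch-length units of the tree.
#'
#' @param tree A validated `"phylo"` object.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = tip
#'   labels.
#' @examples
#' tr <- read_phylogeny(text = "((A:1,B:1):1,C:2);")
#' patristic_matrix(tr)["A", "C"]  # 4
#' @export
patristic_matrix <- function(tree) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) == 1L) {
    d <- matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    return(d)
  }
  ape::cophenetic.phylo(tree)
}

# parent/edge-length lookup vectors indexed by child node id
.parent_table <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  parent <- integer(n_node)
  elen <- numeric(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  list(parent = parent, elen = elen)
}

.match_tips <- function(tree, species) {
  species <- unique(as.character(species))
  idx <- match(species, tree$tip.label)
  if (anyNA(idx))
    stop("species not in tree: ", paste(species[is.na(idx)], collapse = ", "))
  idx
}

#' Community phylogenetic diversity (PD, unrooted variant)
#'
#' Sum of branch lengths of the minimal spanning subtree connecting the
#' community's tips, rooted at the community's most recent common ancestor.
#' The path from that ancestor toward the tree root is excluded, so a
#' single-species community has PD = 0.
#'
#' @param tree A validated `"phylo"` object.
#' @param community Character vector of tip labels (duplicates ignored).
#' @return PD in branch-length units.
#' @examples
#' tr <- read_phylogeny(text = "((A:1,B:1):1,C:2);")
#' community_pd(tr, c("A", "B"))       # 2: internal edge to root excluded
#' community_pd(tr, c("A", "B", "C"))  # 5
#' @export
community_pd <- function(tree, community) {
  idx <- .match_tips(tree, community)
  if (length(idx) == 0L) stop("empty community")
  if (length(idx) == 1L) return(0)
  mrca <- ape::getMRCA(tree, idx)
  pt <- .parent_table(tree)
  seen <- logical(length(pt$parent))
  total <- 0
  for (tip in idx) {
    v <- tip
    while (v != mrca && !seen[v]) {
      seen[v] <- TRUE
      total <- total + pt$elen[v]
      v <- pt$parent[v]
    }
  }
  total
}

.community_submatrix <- function(dist, community) {
  community <- unique(as.character(community))
  bad <- setdiff(community, rownames(dist))
  if (length(bad))
    stop("species not in distance matrix: ", paste(bad, collapse = ", "))
  dist[community, community, drop = FALSE]
}

#' Mean nearest neighbor distance (MNND) of a community
#'
#' Mean, over community members, of the patristic distance to the closest
#' other member. Small values indicate phylogenetic clustering. Undefined
#' for fewer than two species: such communities are an error and must be
#' excluded by the caller (monocultures are excluded, not scored 0).
#'
#' @param dist Patristic matrix from [patristic_matrix()].
#' @param community Character vector of >= 2 tip labels.
#' @return MNND in branch-length units.
#' @export
community_mnnd <- function(dist, community) {
  sub <- .community_submatrix(dist, community)
  if (nrow(sub) < 2L)
    stop("MNND undefined for fewer than 2 species")
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

#' Mean pairwise distance (MPD) of a community
#'
#' Mean patristic distance over all unordered pairs of community members.
#' Undefined for fewer than two species (error, as for [community_mnnd()]).
#'
#' @inheritParams community_mnnd
#' @return MPD in branch-length units.
#' @export
community_mpd <- function(dist, community) {
  sub <- .community_submatrix(dist, community)
  if (nrow(sub) < 2L)
    stop("MPD undefined for fewer than 2 species")
  mean(sub[upper.tri(sub)])
}

# metric dispatch used by the null-model machinery; PD works on the tree,
# MNND/MPD on the precomputed patristic matrix
.community_metric <- function(metric, tree, dist, community) {
  switch(metric,
         PD   = community_pd(tree, community),
         MNND = community_mnnd(dist, community),
         MPD  = community_mpd(dist, community),
         stop("unknown metric: ", metric))
}
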