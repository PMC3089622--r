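# Independent brute-force oracles used to check the metric implementations.
# These deliberately share no code with the package internals: paths are
# enumerated as explicit node sets and reduced with set algebra.

# node path from a tip to the root, as a vector of node ids (tip first)
.oracle_root_path <- function(tree, node) {
  parent <- integer(length(tree$tip.label) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- node
  while (parent[node] != 0L) {
    node <- parent[node]
    path <- c(path, node)
  }
  path
}

# patristic distance by explicit path enumeration: edges on the symmetric
# difference of the two root paths
oracle_patristic <- function(tree, a, b) {
  elen <- numeric(length(tree$tip.label) + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  pa <- .oracle_root_path(tree, match(a, tree$tip.label))
  pb <- .oracle_root_path(tree, match(b, tree$tip.label))
  sum(elen[setdiff(pa, pb)]) + sum(elen[setdiff(pb, pa)])
}

# PD as union of root-path edge sets minus the shared MRCA-to-root path
oracle_pd <- function(tree, community) {
  community <- unique(community)
  if (length(community) < 2L) return(0)
  elen <- numeric(length(tree$tip.label) + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  paths <- lapply(match(community, tree$tip.label),
                  function(t) .oracle_root_path(tree, t))
  shared <- Reduce(intersect, paths)        # MRCA and its ancestors
  sum(elen[setdiff(unique(unlist(paths)), shared)])
}

oracle_mnnd <- function(tree, community) {
  community <- unique(community)
  mean(vapply(community, function(a) {
    min(vapply(setdiff(community, a),
               function(b) oracle_patristic(tree, a, b), numeric(1)))
  }, numeric(1)))
}

oracle_mpd <- function(tree, community) {
  community <- unique(community)
  pairs <- utils::combn(community, 2)
  mean(apply(pairs, 2, function(p) oracle_patristic(tree, p[1], p[2])))
}

# focal-to-reference mean nearest-neighbor distance by exhaustive scan
oracle_cross_mnnd <- function(dist, focal, reference) {
  mean(vapply(focal, function(f) {
    min(vapply(reference, function(r) dist[f, r], numeric(1)))
  }, numeric(1)))
}

cherry_tree <- function() read_phylogeny(text = "((A:1,B:1):1,C:2);")

# small tagged fixture tree: 3 close resident/colonist pairs plus a
# distant 12-species clade at pairwise distance >= 2 from everything else
clustered_fixture_tree <- function() {
  near <- paste(sprintf("(r%d:0.01,c%d:0.01):1", 1:3, 1:3), collapse = ",")
  far <- paste(sprintf("d%02d:0.5", 1:12), collapse = ",")
  read_phylogeny(text = sprintf("((%s):0.5,(%s):1);", near, far))
}
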