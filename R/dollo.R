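#' Read a rooted species tree from Newick
#'
#' Thin wrapper over [ape::read.tree()] that validates the properties the
#' Dollo machinery relies on: unique leaf labels and a designated root (the
#' top-level Newick node). Multifurcations, including a multifurcating
#' root, are handled natively. Because Newick cannot distinguish a rooted
#' tree with a basal polytomy from an unrooted tree, the top-level node is
#' taken as the root as written; trees produced by unrooted inference
#' should be explicitly rooted (outgroup or midpoint) before use, since the
#' rooting changes every Dollo reconstruction.
#'
#' @param text Newick string, or a file path when `file = TRUE`.
#' @param file Read `text` as a path.
#' @return An [ape] `phylo` object.
#' @export
read_species_tree <- function(text, file = FALSE) {
  tree <- tryCatch(
    suppressWarnings(
      if (file) ape::read.tree(file = text) else ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tree)) stop("could not parse Newick input")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  tree
}

# Children lists indexed by node id, and a postorder over internal nodes.
tree_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  children <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    children[[p]] <- c(children[[p]], tree$edge[e, 2L])
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  list(n_tip = n_tip, n_node = n_node, children = children, root = root)
}

#' Dollo parsimony state reconstruction
#'
#' Reconstructs the minimum-loss single-gain (Dollo) ancestral states of a
#' presence/absence character on a rooted tree. The gain is placed at the
#' most recent common ancestor of all presence leaves; a node has state 1
#' exactly when it is the gain node or a descendant of it whose subtree
#' still contains at least one presence leaf. If no leaf carries the
#' character there is no gain and every node is 0.
#'
#' @param tree A rooted `phylo` tree.
#' @param leaf_states Named 0/1 vector covering every leaf label.
#' @return List with `state` (0/1 vector over all node ids, tips first in
#'   ape numbering) and `gain_node` (node id or `NA`).
#' @export
dollo_reconstruct <- function(tree, leaf_states) {
  idx <- tree_index(tree)
  missing <- setdiff(tree$tip.label, names(leaf_states))
  if (length(missing) > 0L) {
    stop("missing leaf state(s): ", paste(missing, collapse = ", "))
  }
  tip_state <- as.integer(leaf_states[tree$tip.label])
  stopifnot(all(tip_state %in% c(0L, 1L)))

  below <- presence_below(tree, idx, tip_state)

  present_tips <- which(tip_state == 1L)
  state <- integer(idx$n_node)
  if (length(present_tips) == 0L) {
    return(list(state = state, gain_node = NA_integer_))
  }
  gain <- if (length(present_tips) == 1L) {
    present_tips
  } else {
    ape::getMRCA(tree, present_tips)
  }
  # descendants of the gain node with presence below are 1
  in_gain_subtree <- logical(idx$n_node)
  in_gain_subtree[gain] <- TRUE
  stack <- gain
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (child in idx$children[[v]]) {
      in_gain_subtree[child] <- TRUE
      stack <- c(stack, child)
    }
  }
  state[in_gain_subtree & below > 0L] <- 1L
  list(state = state, gain_node = gain)
}

# presence counts below every node; postorder guarantees children are
# finalized before their parent edge is visited
presence_below <- function(tree, idx, tip_state) {
  below <- integer(idx$n_node)
  below[seq_len(idx$n_tip)] <- tip_state
  for (e in ape::postorder(tree)) {
    below[tree$edge[e, 1L]] <- below[tree$edge[e, 1L]] + below[tree$edge[e, 2L]]
  }
  below
}

#' Dollo parsimony distance between two reconstructions
#'
#' Branch-wise disagreement of the gain/loss dynamics of two characters on
#' the same tree: the sum over branches of
#' \eqn{|(anc(x) - desc(x)) - (anc(y) - desc(y))|}, where anc/desc are the
#' reconstructed parent and child states on the branch. Identical profiles
#' give 0; the distance is symmetric.
#'
#' @param sx,sy Reconstructions from [dollo_reconstruct()] on `tree`.
#' @param tree The shared rooted `phylo` tree.
#' @return Non-negative integer distance.
#' @export
dollo_distance <- function(sx, sy, tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  if (length(sx$state) != n_node || length(sy$state) != n_node) {
    stop("state reconstructions do not match the tree")
  }
  dx <- sx$state[tree$edge[, 1L]] - sx$state[tree$edge[, 2L]]
  dy <- sy$state[tree$edge[, 1L]] - sy$state[tree$edge[, 2L]]
  sum(abs(dx - dy))
}

#' Pairwise Dollo distances over a binary profile
#'
#' Restricts the profile to the species present as tree leaves (dropped
#' species are reported via message), reconstructs Dollo states per
#' protein, and returns the pairwise branch-disagreement distance matrix.
#'
#' @param profile A [binary_profile()].
#' @param tree Rooted `phylo` species tree.
#' @return A [measure_matrix()] with orientation `"distance"` (consumers
#'   rank by similarity = -distance).
#' @export
dollo_pairwise <- function(profile, tree) {
  shared <- intersect(colnames(profile), tree$tip.label)
  if (length(shared) < 2L) stop("fewer than 2 profile species appear in the tree")
  dropped <- ncol(profile) - length(shared)
  if (dropped > 0L) {
    message(dropped, " profile species absent from the tree were dropped")
  }
  extra <- setdiff(tree$tip.label, shared)
  sub <- if (length(extra) > 0L) ape::drop.tip(tree, extra) else tree
  X <- unclass(profile)[, sub$tip.label, drop = FALSE]
  recs <- lapply(seq_len(nrow(X)), function(i) {
    dollo_reconstruct(sub, stats::setNames(X[i, ], colnames(X)))
  })
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      D[i, j] <- D[j, i] <- dollo_distance(recs[[i]], recs[[j]], sub)
    }
  }
  measure_matrix(D, measure = "dollo", orientation = "distance")
}
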