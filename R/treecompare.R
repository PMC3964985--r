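# Robinson-Foulds comparison of tree versions and conservation of
# orthology sets between releases.

#' Non-trivial bipartitions of a tree
#'
#' Treats the tree as unrooted: every internal edge induces a split of
#' the leaf universe; splits with 0, 1, n-1 or n leaves on a side are
#' trivial and excluded.  Each split is stored canonically as its
#' lexicographically smaller side.
#'
#' @param tree a `phylome_tree`
#' @return character vector of canonical split keys (sorted leaf labels
#'   joined by `"|"`)
#' @export
bipartitions <- function(tree) {
  lv <- leaf_nodes(tree)
  universe <- sort(tree$label[lv])
  n <- length(universe)
  if (tree$n < 2L) return(character(0))
  leafsets <- subtree_leaf_sets(tree)
  keys <- character(0)
  for (i in 2:tree$n) {
    if (is_leaf(tree, i)) next
    side <- sort(tree$label[leafsets[[i]]])
    if (length(side) < 2L || length(side) > n - 2L) next
    other <- sort(setdiff(universe, side))
    k1 <- paste(side, collapse = "|")
    k2 <- paste(other, collapse = "|")
    keys <- c(keys, if (k1 < k2) k1 else k2)
  }
  unique(keys)
}

# drop leaves not in `keep` (labels) and suppress resulting unary nodes
prune_to_leaves <- function(tree, keep) {
  pr <- function(i) {
    if (is_leaf(tree, i)) {
      if (tree$label[i] %in% keep) return(to_nested(tree, i)) else return(NULL)
    }
    kids <- Filter(Negate(is.null), lapply(tree$children[[i]], pr))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) {
      node <- kids[[1]]
      node$length <- na_sum(node$length, tree$length[i])
      return(node)
    }
    node <- to_nested(tree, i)
    node$children <- kids
    node
  }
  root <- pr(1L)
  if (is.null(root)) stop("no leaves left after pruning", call. = FALSE)
  flatten_tree(root, kind = tree$kind)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of unrooted non-trivial bipartitions,
#' normalized by the total number of non-trivial splits in both trees
#' (for two binary trees on n leaves this denominator is 2(n-3)).
#' `strict` mode requires identical leaf sets; `prune_to_shared`
#' restricts both trees to their shared leaves first (at least 4
#' required).
#'
#' @param t1,t2 `phylome_tree`s
#' @param mode `"strict"` (default) or `"prune_to_shared"`
#' @return list with `raw` (integer), `normalized` (in `[0, 1]`; 0 when
#'   neither tree has a non-trivial split) and `nshared_leaves`
#' @examples
#' a <- parse_newick("((a_A,b_B),(c_C,d_D));")
#' b <- parse_newick("((a_A,c_C),(b_B,d_D));")
#' rf_distance(a, b)  # raw 2, normalized 1
#' @export
rf_distance <- function(t1, t2, mode = c("strict", "prune_to_shared")) {
  mode <- match.arg(mode)
  l1 <- t1$label[leaf_nodes(t1)]
  l2 <- t2$label[leaf_nodes(t2)]
  shared <- intersect(l1, l2)
  if (mode == "strict") {
    if (!setequal(l1, l2))
      stop("leaf sets differ (", length(setdiff(l1, l2)), " only in t1, ",
           length(setdiff(l2, l1)), " only in t2); use prune_to_shared",
           call. = FALSE)
  } else {
    if (length(shared) < 4L)
      stop("fewer than 4 shared leaves (", length(shared), ")",
           call. = FALSE)
    t1 <- prune_to_leaves(t1, shared)
    t2 <- prune_to_leaves(t2, shared)
  }
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  raw <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  denom <- length(b1) + length(b2)
  list(raw = as.integer(raw),
       normalized = if (denom == 0L) 0 else raw / denom,
       nshared_leaves = length(shared))
}

canonical_pair_keys <- function(pairs) {
  if (is.data.frame(pairs)) {
    a <- gene_key(pairs$seq_a, pairs$species_a)
    b <- gene_key(pairs$seq_b, pairs$species_b)
  } else if (is.matrix(pairs)) {
    a <- pairs[, 1]; b <- pairs[, 2]
  } else {
    stop("pairs must be a calls data.frame or a 2-column matrix",
         call. = FALSE)
  }
  unique(paste(pmin(a, b), pmax(a, b), sep = "\t"))
}

#' Fraction of ortholog pairs conserved between two releases
#'
#' Pairs are keyed on unordered gene identities; any ID mapping between
#' releases must be applied by the caller beforehand.
#'
#' @param calls_v1,calls_v2 ortholog pair sets: calls data.frames (only
#'   rows with `relation == "ortholog"` are used) or 2-column matrices
#'   of gene keys
#' @param denominator `"v1"` (fraction of the first release's pairs,
#'   default) or `"union"`
#' @return fraction in `[0, 1]`
#' @export
ortholog_conservation <- function(calls_v1, calls_v2,
                                  denominator = c("v1", "union")) {
  denominator <- match.arg(denominator)
  take <- function(x) {
    if (is.data.frame(x) && "relation" %in% names(x))
      x <- x[x$relation == "ortholog", , drop = FALSE]
    canonical_pair_keys(x)
  }
  p1 <- take(calls_v1)
  p2 <- take(calls_v2)
  den <- if (denominator == "v1") p1 else union(p1, p2)
  if (length(den) == 0L)
    stop("empty denominator pair set", call. = FALSE)
  length(intersect(p1, p2)) / length(den)
}
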