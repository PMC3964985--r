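# Seed-relative rooting, species-overlap event labeling and
# phylostratigraphic relative ages.

na_sum <- function(a, b) {
  if (is.na(a) && is.na(b)) return(NA_real_)
  sum(c(a, b), na.rm = TRUE)
}

# rootward view of node u approached from child `from_child`; the edge
# being reversed contributes `carry_len`/`carry_sup` above the new node
up_view <- function(tree, u, from_child, carry_len, carry_sup) {
  kids <- lapply(setdiff(tree$children[[u]], from_child),
                 function(c) to_nested(tree, c))
  if (u != 1L)
    kids <- c(kids, list(up_view(tree, tree$parent[u], u,
                                 tree$length[u], tree$support[u])))
  if (u == 1L && length(kids) == 1L) {
    # old binary root vanishes when unrooted; merge the two half-edges
    node <- kids[[1]]
    node$length <- na_sum(node$length, carry_len)
    return(node)
  }
  node <- to_nested(tree, u)
  node$children <- kids
  node$length <- carry_len
  node$support <- carry_sup
  node
}

# reroot on the edge above node v; the new root sits `below_len` from v
reroot_at_edge <- function(tree, v, below_len = NULL) {
  if (v == 1L) stop("cannot reroot on the root itself", call. = FALSE)
  Lv <- tree$length[v]
  if (is.null(below_len)) below_len <- if (is.na(Lv)) NA_real_ else Lv / 2
  above_len <- if (is.na(Lv)) NA_real_ else Lv - below_len
  below <- to_nested(tree, v)
  below$length <- below_len
  above <- up_view(tree, tree$parent[v], v, above_len, tree$support[v])
  root <- nested_node(children = list(below, above))
  flatten_tree(root, kind = tree$kind)
}

# lca of a species set in the species tree, as a node id
species_lca <- function(species_tree, species, depth = node_depths(species_tree)) {
  lv <- leaf_nodes(species_tree)
  ids <- lv[match(species, species_tree$label[lv])]
  if (anyNA(ids))
    stop("species not in species tree: ",
         paste(species[is.na(ids)], collapse = ", "), call. = FALSE)
  Reduce(function(i, j) lca_node(species_tree, i, j, depth), ids)
}

#' Root a gene tree relative to a seed sequence
#'
#' `farthest_taxon` (the default for gene-centric trees) roots on the
#' edge separating the seed-free clade whose species are taxonomically
#' most distant from the seed's species: the clade whose species-set LCA
#' with the seed species lies deepest (closest to the root) in the
#' reference species tree.  Ties are broken by larger clade size, then
#' by the lexicographically smallest leaf label.  `midpoint` roots at
#' the midpoint of the longest leaf-to-leaf path and requires branch
#' lengths.  A tree whose leaves all belong to the seed species cannot
#' be rooted taxonomically and falls back to midpoint with a notice.
#'
#' @param tree a gene `phylome_tree` (rooted or with a basal
#'   multifurcation)
#' @param species_tree reference `phylome_tree` of kind `"species"`
#'   (required for `farthest_taxon`)
#' @param seed_leaf seed leaf reference (full label or seq_id)
#' @param strategy `"farthest_taxon"` or `"midpoint"`
#' @return a rooted `phylome_tree` with a binary root
#' @export
root_tree <- function(tree, species_tree = NULL, seed_leaf = NULL,
                      strategy = c("farthest_taxon", "midpoint")) {
  strategy <- match.arg(strategy)
  if (n_leaves(tree) <= 2L) return(tree)
  if (strategy == "farthest_taxon") {
    if (length(tree_species(tree)) == 1L) {
      message("all leaves belong to one species; falling back to midpoint rooting")
      return(root_tree(tree, strategy = "midpoint"))
    }
    if (is.null(species_tree) || is.null(seed_leaf))
      stop("farthest_taxon rooting needs a species tree and a seed leaf",
           call. = FALSE)
    seed <- find_leaf(tree, seed_leaf)
    seed_sp <- tree$species[seed]
    sp_depth <- node_depths(species_tree)
    leafsets <- subtree_leaf_sets(tree)
    spsets <- species_sets(tree)
    missing <- setdiff(tree_species(tree), tree_species(species_tree))
    if (length(missing))
      stop("species not in species tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    best <- NULL
    for (v in 2:tree$n) {
      if (seed %in% leafsets[[v]]) next
      anc <- species_lca(species_tree, unique(c(spsets[[v]], seed_sp)), sp_depth)
      cand <- list(v = v, depth = sp_depth[anc],
                   size = length(leafsets[[v]]),
                   minlab = min(tree$label[leafsets[[v]]]))
      if (is.null(best) ||
          cand$depth < best$depth ||
          (cand$depth == best$depth && cand$size > best$size) ||
          (cand$depth == best$depth && cand$size == best$size &&
           cand$minlab < best$minlab))
        best <- cand
    }
    return(reroot_at_edge(tree, best$v))
  }
  # midpoint
  if (anyNA(tree$length[2:tree$n]))
    stop("midpoint rooting requires branch lengths on all edges",
         call. = FALSE)
  dlen <- node_depths_len(tree)
  depth <- node_depths(tree)
  lv <- leaf_nodes(tree)
  best <- list(d = -1)
  for (ai in seq_along(lv)) for (bi in seq_len(ai - 1L)) {
    a <- lv[ai]; b <- lv[bi]
    l <- lca_node(tree, a, b, depth)
    d <- dlen[a] + dlen[b] - 2 * dlen[l]
    if (d > best$d) best <- list(d = d, a = a, b = b, l = l)
  }
  half <- best$d / 2
  # walk from the farther endpoint toward the LCA until `half` is consumed
  start <- if (dlen[best$a] - dlen[best$l] >= half) best$a else best$b
  node <- start
  acc <- 0
  while (acc + tree$length[node] < half && tree$parent[node] != 0L) {
    acc <- acc + tree$length[node]
    node <- tree$parent[node]
  }
  reroot_at_edge(tree, node, below_len = half - acc)
}

#' Label duplication and speciation nodes by species overlap
#'
#' Every internal node receives an overlap score: for binary nodes the
#' Jaccard index |A \strong{intersect} B| / |A \strong{union} B| of the
#' two children's species sets; for multifurcations the maximum of that
#' ratio over all child pairs.  A node is a duplication when its score
#' strictly exceeds `threshold`, a speciation otherwise; the default
#' threshold 0 calls a duplication on any shared species.
#'
#' @param tree a rooted gene `phylome_tree` (binary root; internal
#'   multifurcations allowed)
#' @param threshold species-overlap threshold in `[0, 1)`
#' @return the tree with `event` and `sos` filled on internal nodes
#' @examples
#' tr <- parse_newick("((H1_HUMAN,M1_MOUSE),(H2_HUMAN,M2_MOUSE));")
#' tr <- label_events(tr)
#' tr$event[1]   # root is a duplication (score 1)
#' @export
label_events <- function(tree, threshold = 0.0) {
  if (threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)", call. = FALSE)
  if (n_leaves(tree) > 1L && length(tree$children[[1L]]) != 2L)
    stop("tree has a multifurcating root and appears unrooted; ",
         "call root_tree() first", call. = FALSE)
  spsets <- species_sets(tree)
  for (i in which(lengths(tree$children) > 0L)) {
    ch <- tree$children[[i]]
    score <- 0
    for (a in seq_along(ch)) for (b in seq_len(a - 1L)) {
      A <- spsets[[ch[a]]]; B <- spsets[[ch[b]]]
      score <- max(score, length(intersect(A, B)) / length(union(A, B)))
    }
    tree$sos[i] <- score
    tree$event[i] <- if (score > threshold) "duplication" else "speciation"
  }
  tree
}

#' Nodal distance between two leaves
#'
#' Number of edges on the unique path between two leaves, ignoring
#' branch lengths.  A metric on leaves: zero only for a leaf against
#' itself, symmetric, and obeying the triangle inequality.
#'
#' @param tree a `phylome_tree`
#' @param leaf_a,leaf_b leaf references (label or seq_id)
#' @return integer edge count
#' @export
nodal_distance <- function(tree, leaf_a, leaf_b) {
  a <- find_leaf(tree, leaf_a)
  b <- find_leaf(tree, leaf_b)
  if (a == b) return(0L)
  depth <- node_depths(tree)
  l <- lca_node(tree, a, b, depth)
  as.integer(depth[a] + depth[b] - 2L * depth[l])
}

#' Phylostratigraphic lineage of a seed species
#'
#' Orders the named ancestor clades of the seed species from the species
#' itself (level 0) up to the root of the reference species tree; each
#' level carries its species set.  Used to date gene-tree nodes by the
#' smallest taxonomic level containing all their species.
#'
#' @param species_tree a `phylome_tree` of kind `"species"`
#' @param seed_species species mnemonic present as a leaf
#' @return a `lineage_map` object: list with `seed_species` and
#'   `levels`, a list of `list(name, species)` from tip to root
#' @examples
#' sp <- parse_newick("(((HUMAN,PANTR)Primates,MOUSE)Mammalia,YEAST)Eukaryota;",
#'                    naming = "none")
#' lineage_map(sp, "HUMAN")
#' @export
lineage_map <- function(species_tree, seed_species) {
  lv <- leaf_nodes(species_tree)
  leaf <- lv[match(seed_species, species_tree$label[lv])]
  if (is.na(leaf))
    stop("seed species '", seed_species, "' not in species tree",
         call. = FALSE)
  spsets <- species_sets(species_tree)
  path <- leaf
  while (species_tree$parent[path[length(path)]] != 0L)
    path <- c(path, species_tree$parent[path[length(path)]])
  levels <- lapply(seq_along(path), function(k) {
    i <- path[k]
    name <- if (k == 1L) species_tree$label[i]
            else if (!is.na(species_tree$clade[i])) species_tree$clade[i]
            else sprintf("level%d", k - 1L)
    list(name = name, species = spsets[[i]])
  })
  structure(list(seed_species = seed_species, levels = levels),
            class = "lineage_map")
}

#' @export
print.lineage_map <- function(x, ...) {
  cat("<lineage_map for", x$seed_species, ">\n")
  for (k in seq_along(x$levels))
    cat(sprintf("  [%d] %s (%d species)\n", k - 1L, x$levels[[k]]$name,
                length(x$levels[[k]]$species)))
  invisible(x)
}

#' Assign relative ages to tree nodes (phylostratigraphy)
#'
#' Each node is dated by the smallest lineage level (taxonomic clade of
#' the seed species) whose species set contains every species under the
#' node.  Ages are therefore non-decreasing from any leaf toward the
#' root.
#'
#' @param tree a gene `phylome_tree`
#' @param lineage a [lineage_map()]
#' @return the tree with `age` filled on every node
#' @export
assign_relative_ages <- function(tree, lineage) {
  spsets <- species_sets(tree)
  universe <- lineage$levels[[length(lineage$levels)]]$species
  missing <- setdiff(spsets[[1L]], universe)
  if (length(missing))
    stop("species outside every lineage level: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (i in seq_len(tree$n)) {
    for (k in seq_along(lineage$levels)) {
      if (all(spsets[[i]] %in% lineage$levels[[k]]$species)) {
        tree$age[i] <- k - 1L
        break
      }
    }
  }
  tree
}
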