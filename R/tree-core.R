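# Flat tree representation shared by gene trees and species trees.
#
# A `phylome_tree` is a list of parallel vectors indexed by node id.
# Node 1 is the root and every parent index is smaller than its
# children's, so `2:n` is a valid preorder and `n:1` a valid postorder.
# Gene-tree leaves carry (seq_id, species); species-tree leaves carry the
# species mnemonic in `label` and internal nodes may carry a clade name.

new_phylome_tree <- function(parent, children, label,
                             length = NULL, support = NULL,
                             seq_id = NULL, species = NULL,
                             event = NULL, sos = NULL, age = NULL,
                             clade = NULL, kind = "gene") {
  n <- length(parent)
  blank_num <- rep(NA_real_, n)
  blank_chr <- rep(NA_character_, n)
  tr <- list(
    n        = n,
    parent   = as.integer(parent),
    children = children,
    label    = label,
    length   = if (is.null(length))  blank_num else as.numeric(length),
    support  = if (is.null(support)) blank_num else as.numeric(support),
    seq_id   = if (is.null(seq_id))  blank_chr else seq_id,
    species  = if (is.null(species)) blank_chr else species,
    event    = if (is.null(event))   blank_chr else event,
    sos      = if (is.null(sos))     blank_num else as.numeric(sos),
    age      = if (is.null(age))     rep(NA_integer_, n) else as.integer(age),
    clade    = if (is.null(clade))   blank_chr else clade,
    kind     = kind
  )
  class(tr) <- "phylome_tree"
  tr
}

is_leaf <- function(tree, i) lengths(tree$children)[i] == 0L

#' Indices of leaf nodes
#' @param tree a `phylome_tree`
#' @return integer vector of node ids
#' @keywords internal
leaf_nodes <- function(tree) which(lengths(tree$children) == 0L)

#' Number of leaves in a tree
#' @param tree a `phylome_tree`
#' @return integer count
#' @export
n_leaves <- function(tree) sum(lengths(tree$children) == 0L)

#' Leaf table of a gene or species tree
#'
#' @param tree a `phylome_tree`
#' @return data.frame with columns `node`, `label`, `seq_id`, `species`
#' @export
tree_leaves <- function(tree) {
  i <- leaf_nodes(tree)
  data.frame(node = i, label = tree$label[i],
             seq_id = tree$seq_id[i], species = tree$species[i],
             stringsAsFactors = FALSE)
}

#' Set of species present in a tree
#' @param tree a `phylome_tree`
#' @return sorted character vector of species mnemonics
#' @export
tree_species <- function(tree) {
  i <- leaf_nodes(tree)
  sp <- if (tree$kind == "species") tree$label[i] else tree$species[i]
  sort(unique(sp[!is.na(sp)]))
}

# depth in edges from the root (root = 0)
node_depths <- function(tree) {
  d <- integer(tree$n)
  if (tree$n > 1L) for (i in 2:tree$n) d[i] <- d[tree$parent[i]] + 1L
  d
}

# cumulative branch length from the root; NA edge lengths count as `na_as`
node_depths_len <- function(tree, na_as = NA_real_) {
  d <- numeric(tree$n)
  if (tree$n > 1L) for (i in 2:tree$n) {
    len <- tree$length[i]
    if (is.na(len)) len <- na_as
    d[i] <- d[tree$parent[i]] + len
  }
  d
}

# lowest common ancestor of two nodes by parent walking
lca_node <- function(tree, i, j, depth = node_depths(tree)) {
  while (depth[i] > depth[j]) i <- tree$parent[i]
  while (depth[j] > depth[i]) j <- tree$parent[j]
  while (i != j) { i <- tree$parent[i]; j <- tree$parent[j] }
  i
}

# per-node leaf index sets, as a list over all nodes (postorder fill)
subtree_leaf_sets <- function(tree) {
  out <- vector("list", tree$n)
  for (i in tree$n:1) {
    ch <- tree$children[[i]]
    out[[i]] <- if (length(ch) == 0L) i else unlist(out[ch], use.names = FALSE)
  }
  out
}

# per-node species sets (unique, sorted) for a gene or species tree
species_sets <- function(tree) {
  sp <- if (tree$kind == "species") tree$label else tree$species
  out <- vector("list", tree$n)
  for (i in tree$n:1) {
    ch <- tree$children[[i]]
    out[[i]] <- if (length(ch) == 0L) sp[i]
                else sort(unique(unlist(out[ch], use.names = FALSE)))
  }
  out
}

# find the leaf id matching a reference: full label, or seq_id for gene trees
find_leaf <- function(tree, ref) {
  lv <- leaf_nodes(tree)
  hit <- lv[!is.na(tree$label[lv]) & tree$label[lv] == ref]
  if (length(hit) == 0L && tree$kind == "gene")
    hit <- lv[!is.na(tree$seq_id[lv]) & tree$seq_id[lv] == ref]
  if (length(hit) == 0L)
    stop("leaf '", ref, "' not found in tree", call. = FALSE)
  hit[1L]
}

# -- nested <-> flat conversion ------------------------------------------

# nested node constructor used by the parser and by rerooting
nested_node <- function(children = list(), label = NA_character_,
                        length = NA_real_, support = NA_real_,
                        seq_id = NA_character_, species = NA_character_,
                        event = NA_character_, sos = NA_real_,
                        age = NA_integer_, clade = NA_character_) {
  list(children = children, label = label, length = length,
       support = support, seq_id = seq_id, species = species,
       event = event, sos = sos, age = age, clade = clade)
}

count_nested <- function(node) {
  1L + sum(vapply(node$children, count_nested, integer(1)))
}

flatten_tree <- function(root, kind = "gene") {
  n <- count_nested(root)
  env <- new.env(parent = emptyenv())
  env$parent  <- integer(n)
  env$children <- vector("list", n)
  env$label   <- rep(NA_character_, n)
  env$length  <- rep(NA_real_, n)
  env$support <- rep(NA_real_, n)
  env$seq_id  <- rep(NA_character_, n)
  env$species <- rep(NA_character_, n)
  env$event   <- rep(NA_character_, n)
  env$sos     <- rep(NA_real_, n)
  env$age     <- rep(NA_integer_, n)
  env$clade   <- rep(NA_character_, n)
  env$next_id <- 1L
  fill <- function(node, parent_id) {
    id <- env$next_id
    env$next_id <- id + 1L
    env$parent[id]  <- parent_id
    env$label[id]   <- node$label
    env$length[id]  <- node$length
    env$support[id] <- node$support
    env$seq_id[id]  <- node$seq_id
    env$species[id] <- node$species
    env$event[id]   <- node$event
    env$sos[id]     <- node$sos
    env$age[id]     <- node$age
    env$clade[id]   <- node$clade
    kids <- integer(length(node$children))
    for (k in seq_along(node$children)) kids[k] <- fill(node$children[[k]], id)
    env$children[[id]] <- kids
    id
  }
  fill(root, 0L)
  new_phylome_tree(env$parent, env$children, env$label,
                   length = env$length, support = env$support,
                   seq_id = env$seq_id, species = env$species,
                   event = env$event, sos = env$sos, age = env$age,
                   clade = env$clade, kind = kind)
}

to_nested <- function(tree, i = 1L) {
  nested_node(
    children = lapply(tree$children[[i]], function(c) to_nested(tree, c)),
    label = tree$label[i], length = tree$length[i],
    support = tree$support[i], seq_id = tree$seq_id[i],
    species = tree$species[i], event = tree$event[i],
    sos = tree$sos[i], age = tree$age[i], clade = tree$clade[i])
}

#' @export
print.phylome_tree <- function(x, ...) {
  cat(sprintf("<phylome_tree: %s, %d leaves, %d nodes>\n",
              x$kind, n_leaves(x), x$n))
  sp <- tree_species(x)
  if (length(sp))
    cat("  species:", paste(utils::head(sp, 8), collapse = " "),
        if (length(sp) > 8) "..." else "", "\n")
  ev <- table(x$event[!is.na(x$event)])
  if (length(ev))
    cat("  events:", paste(names(ev), as.integer(ev), sep = "=", collapse = " "), "\n")
  invisible(x)
}

# equality on topology + labels + annotations (lengths to 1e-6)
trees_equal <- function(a, b, check_lengths = TRUE, check_annotations = TRUE) {
  key <- function(tree, i) {
    ch <- tree$children[[i]]
    ann <- if (check_annotations)
      paste(tree$event[i], tree$sos[i], tree$age[i], tree$support[i], sep = ";")
    else ""
    len <- if (check_lengths && !is.na(tree$length[i]))
      sprintf("%.6f", tree$length[i]) else ""
    if (length(ch) == 0L)
      return(paste0("L[", tree$label[i], "|", len, "|", ann, "]"))
    sub <- sort(vapply(ch, function(c) key(tree, c), character(1)))
    paste0("(", paste(sub, collapse = ","), ")", tree$label[i],
           "|", len, "|", ann)
  }
  identical(key(a, 1L), key(b, 1L))
}
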