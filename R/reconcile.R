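# LCA reconciliation of gene trees against a species tree,
# duplication/loss counting, and gene-tree-parsimony species-tree search.

check_binary <- function(tree, what) {
  deg <- lengths(tree$children)
  if (any(deg > 2L))
    stop(what, " has multifurcations; resolve them upstream ",
         "(species-overlap labeling tolerates them, reconciliation does not)",
         call. = FALSE)
}

# species tree preprocessed for repeated reconciliation:
# leaf index per species, full LCA matrix and node depths
prep_species <- function(species_tree) {
  n <- species_tree$n
  depth <- node_depths(species_tree)
  anc <- vector("list", n)
  for (i in seq_len(n)) {
    path <- i
    while (species_tree$parent[path[length(path)]] != 0L)
      path <- c(path, species_tree$parent[path[length(path)]])
    anc[[i]] <- path
  }
  lca <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    common <- intersect(anc[[i]], anc[[j]])
    lca[i, j] <- lca[j, i] <- common[which.max(depth[common])]
  }
  lv <- leaf_nodes(species_tree)
  list(tree = species_tree, depth = depth, lca = lca,
       leaf_of = stats::setNames(lv, species_tree$label[lv]))
}

# gene tree preprocessed once: postorder internal nodes with child ids,
# plus leaf species
prep_gene <- function(gene_tree) {
  internal <- which(lengths(gene_tree$children) > 0L)
  internal <- internal[order(internal, decreasing = TRUE)]  # postorder
  kids <- do.call(rbind, lapply(gene_tree$children[internal],
                                function(ch) ch[1:2]))
  if (is.null(kids)) kids <- matrix(integer(0), 0, 2)
  list(n = gene_tree$n, internal = internal, kids = kids,
       leaves = leaf_nodes(gene_tree),
       species = gene_tree$species[leaf_nodes(gene_tree)])
}

# core counting: returns mapping, per-node events, dup and loss counts
reconcile_core <- function(gp, sp) {
  M <- integer(gp$n)
  leaf_map <- sp$leaf_of[gp$species]
  if (anyNA(leaf_map))
    stop("species missing from species tree: ",
         paste(unique(gp$species[is.na(leaf_map)]), collapse = ", "),
         call. = FALSE)
  M[gp$leaves] <- leaf_map
  dup <- logical(gp$n)
  losses <- 0L
  ndup <- 0L
  ni <- length(gp$internal)
  if (ni) for (k in seq_len(ni)) {
    v <- gp$internal[k]
    c1 <- gp$kids[k, 1L]; c2 <- gp$kids[k, 2L]
    m1 <- M[c1]; m2 <- M[c2]
    m <- sp$lca[m1, m2]
    M[v] <- m
    isdup <- m == m1 || m == m2
    dup[v] <- isdup
    ndup <- ndup + isdup
    d <- (sp$depth[m1] - sp$depth[m]) + (sp$depth[m2] - sp$depth[m])
    losses <- losses + d + if (isdup) 0L else -2L
  }
  list(mapping = M, dup = dup, dup_count = as.integer(ndup),
       loss_count = as.integer(losses))
}

#' LCA-reconcile a gene tree with a species tree
#'
#' Maps every gene-tree node to the last common ancestor (in the
#' species tree) of its descendant species.  A node is a duplication
#' when its mapping equals the mapping of at least one child.  Losses
#' are counted per gene-tree edge v -> c as the species-tree edge
#' distance d(M(v), M(c)) minus 1 when v is a speciation, and d(M(v),
#' M(c)) when v is a duplication.
#'
#' @param gene_tree a rooted binary gene `phylome_tree`
#' @param species_tree a rooted binary species `phylome_tree` covering
#'   every species in the gene tree
#' @return a `reconciliation`: list with `mapping` (gene node ->
#'   species node id), `events` (per-node `"speciation"`/
#'   `"duplication"`/`"leaf"`), `dup_count`, `loss_count`
#' @examples
#' g <- parse_newick("((A_a,C_c),(B_b,C2_c));")
#' s <- parse_newick("((a,b),c);", naming = "none")
#' r <- lca_reconcile(g, s)
#' c(r$dup_count, r$loss_count)  # 1 duplication, 2 losses
#' @export
lca_reconcile <- function(gene_tree, species_tree) {
  check_binary(gene_tree, "gene tree")
  check_binary(species_tree, "species tree")
  gp <- prep_gene(gene_tree)
  sp <- prep_species(species_tree)
  core <- reconcile_core(gp, sp)
  events <- ifelse(lengths(gene_tree$children) == 0L, "leaf",
                   ifelse(core$dup, "duplication", "speciation"))
  structure(list(mapping = core$mapping, events = events,
                 dup_count = core$dup_count, loss_count = core$loss_count,
                 gene_tree = gene_tree, species_tree = species_tree),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation: %d duplications, %d losses over %d leaves>\n",
              x$dup_count, x$loss_count, n_leaves(x$gene_tree)))
  invisible(x)
}

#' Gene-tree-parsimony cost of a species tree
#'
#' Sums reconciliation costs (duplications, or duplications plus
#' losses) of a gene-tree collection against one candidate species
#' tree.
#'
#' @param gene_trees list of rooted binary gene `phylome_tree`s
#' @param species_tree candidate species `phylome_tree`
#' @param cost `"dup_plus_loss"` (default) or `"dup"`
#' @return integer total cost
#' @export
score_species_tree <- function(gene_trees, species_tree,
                               cost = c("dup_plus_loss", "dup")) {
  cost <- match.arg(cost)
  if (length(gene_trees) == 0L)
    stop("empty gene-tree collection", call. = FALSE)
  sp <- prep_species(species_tree)
  total <- 0L
  for (k in seq_along(gene_trees)) {
    gt <- gene_trees[[k]]
    check_binary(gt, paste0("gene tree #", k))
    core <- tryCatch(reconcile_core(prep_gene(gt), sp),
                     error = function(e)
                       stop("gene tree #", k, " is not reconcilable: ",
                            conditionMessage(e), call. = FALSE))
    total <- total + core$dup_count +
      if (cost == "dup_plus_loss") core$loss_count else 0L
  }
  total
}

# all rooted binary topologies over a label set, as nested label lists
enumerate_rooted <- function(labels) {
  if (length(labels) == 1L) return(list(labels[1]))
  if (length(labels) == 2L) return(list(list(labels[1], labels[2])))
  smaller <- enumerate_rooted(labels[-length(labels)])
  x <- labels[length(labels)]
  out <- list()
  graft <- function(node) {
    # returns list of variants of `node` with x attached on some edge in it
    res <- list(list(node, x))          # attach above this node
    if (is.list(node)) {
      for (k in 1:2) {
        for (sub in graft(node[[k]])) {
          mod <- node
          mod[[k]] <- sub
          res[[length(res) + 1L]] <- mod
        }
      }
    }
    res
  }
  for (t in smaller) out <- c(out, graft(t))
  out
}

nested_labels_to_tree <- function(x) {
  build <- function(node) {
    if (!is.list(node)) return(nested_node(label = node))
    nested_node(children = lapply(node, build))
  }
  flatten_tree(build(x), kind = "species")
}

#' Exhaustive gene-tree-parsimony search for the species tree
#'
#' Enumerates every rooted binary species-tree topology over the given
#' species (at most 8: (2n-3)!! topologies) and returns the one
#' minimizing the summed reconciliation cost of the gene-tree
#' collection.  Ties are broken by lexicographically smallest Newick
#' string; all co-optimal trees are also returned.
#'
#' @param gene_trees list of rooted binary gene `phylome_tree`s
#' @param species species mnemonics to search over; defaults to the
#'   union of species in `gene_trees`
#' @param cost `"dup_plus_loss"` (default) or `"dup"`
#' @return list with `best` (a species `phylome_tree`), `cost`,
#'   `co_optima` (list of all cost-tying trees) and `n_evaluated`
#' @export
search_species_trees <- function(gene_trees, species = NULL,
                                 cost = c("dup_plus_loss", "dup")) {
  cost <- match.arg(cost)
  if (length(gene_trees) == 0L)
    stop("empty gene-tree collection", call. = FALSE)
  if (is.null(species))
    species <- sort(unique(unlist(lapply(gene_trees, tree_species))))
  if (length(species) < 2L)
    stop("need at least 2 species", call. = FALSE)
  if (length(species) > 8L)
    stop("exhaustive search is limited to 8 species (",
         length(species), " requested); use an external heuristic ",
         "gene-tree-parsimony search for larger sets", call. = FALSE)
  preps <- lapply(gene_trees, function(gt) {
    check_binary(gt, "gene tree")
    prep_gene(gt)
  })
  dup_only <- cost == "dup"
  best_cost <- Inf
  best <- list()
  for (cand in enumerate_rooted(sort(species))) {
    st <- nested_labels_to_tree(cand)
    sp <- prep_species(st)
    total <- 0L
    for (gp in preps) {
      core <- reconcile_core(gp, sp)
      total <- total + core$dup_count +
        if (dup_only) 0L else core$loss_count
      if (total > best_cost) break
    }
    if (total < best_cost) {
      best_cost <- total
      best <- list(st)
    } else if (total == best_cost) {
      best[[length(best) + 1L]] <- st
    }
  }
  nwk <- vapply(best, write_newick, character(1))
  ord <- order(nwk)
  list(best = best[[ord[1]]], cost = as.integer(best_cost),
       co_optima = best[ord],
       n_evaluated = prod(seq(1, 2 * length(species) - 3, by = 2)))
}
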