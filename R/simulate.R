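# Duplication-loss simulation: Yule species trees and birth-death gene
# trees with ground-truth event logs.  Truth is recorded at generation
# time, never re-inferred, so benchmarking against it is
# circularity-free.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Simulate a species tree under a Yule process
#'
#' Pure-birth process: starting from the root split, a uniformly chosen
#' lineage splits after an exponential waiting time with rate equal to
#' the number of extant lineages.  The resulting ultrametric tree is
#' rescaled to unit root-to-tip depth and its species are named
#' `SP001`, `SP002`, ...
#'
#' @param n_species number of species (>= 2)
#' @param rng_seed integer seed; `NULL` uses the current RNG state
#' @return a species `phylome_tree` with branch lengths
#' @export
simulate_species_tree <- function(n_species, rng_seed = NULL) {
  if (n_species < 2L) stop("need at least 2 species", call. = FALSE)
  with_seed(rng_seed, {
    parent <- c(0L, 1L, 1L)
    start <- c(0, 0, 0)          # time each lineage began
    split_at <- rep(NA_real_, 3)
    active <- c(2L, 3L)
    t <- 0
    while (length(active) < n_species) {
      k <- length(active)
      t <- t + stats::rexp(1L, rate = k)
      pick <- active[sample.int(k, 1L)]
      split_at[pick] <- t
      id <- length(parent) + c(1L, 2L)
      parent <- c(parent, pick, pick)
      start <- c(start, t, t)
      split_at <- c(split_at, NA_real_, NA_real_)
      active <- c(setdiff(active, pick), id)
    }
    T_total <- t + stats::rexp(1L, rate = n_species)
    n <- length(parent)
    len <- ifelse(is.na(split_at), T_total - start, split_at - start) / T_total
    len[1] <- NA_real_
    # reindex to preorder (parents before children already hold)
    children <- lapply(seq_len(n), function(i) which(parent == i))
    label <- rep(NA_character_, n)
    lv <- which(lengths(children) == 0L)
    label[lv] <- sprintf("SP%03d", seq_along(lv))
    new_phylome_tree(parent, children, label, length = len, kind = "species")
  })
}

#' Simulate a gene tree along a species tree with duplications and losses
#'
#' A single gene lineage enters at the species-tree root (optionally
#' after evolving along a root edge of length `root_edge`).  Along each
#' species branch, duplications arise as a Poisson process at rate
#' `dup_rate` (the lineage forks; the node is logged as a ground-truth
#' duplication) and losses at rate `loss_rate` (the lineage dies; the
#' event is logged against the species branch).  At each species-tree
#' split the lineage enters both daughter branches (logged speciation);
#' lineages surviving to species leaves become gene leaves named
#' `g<k>_<SPECIES>`.  Fully lost subtrees are pruned and pass-through
#' nodes collapsed, so the returned event map covers exactly the
#' internal nodes of the final tree.
#'
#' @param species_tree a species `phylome_tree` with branch lengths
#' @param dup_rate duplication rate per lineage per unit branch length
#' @param loss_rate loss rate per lineage per unit branch length
#' @param rng_seed integer seed; `NULL` uses the current RNG state
#' @param root_edge length of a stem edge above the species root on
#'   which pre-root duplications (out-paralogs) can occur; default 0
#' @return a `sim_record`: list with `gene_tree` (its `event` field
#'   holds the ground truth; `NULL` if the whole family was lost),
#'   `true_events` (copy of the per-node truth), `loss_events`
#'   (data.frame species branch -> count) and `params`
#' @export
simulate_gene_tree <- function(species_tree, dup_rate = 0.0,
                               loss_rate = 0.0, rng_seed = NULL,
                               root_edge = 0.0) {
  if (dup_rate < 0 || loss_rate < 0)
    stop("rates must be nonnegative", call. = FALSE)
  st <- species_tree
  if (st$n > 1L && anyNA(st$length[2:st$n]))
    stop("species tree must have branch lengths on all edges",
         call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$leaf_count <- 0L
  env$losses <- integer(0)      # species node ids under lost branches
  rate <- dup_rate + loss_rate

  at_branch_end <- function(sp_node, elapsed) {
    ch <- st$children[[sp_node]]
    if (length(ch) == 0L) {
      env$leaf_count <- env$leaf_count + 1L
      sp <- st$label[sp_node]
      sid <- sprintf("g%d", env$leaf_count)
      return(nested_node(label = paste0(sid, "_", sp), seq_id = sid,
                         species = sp, length = elapsed))
    }
    kids <- Filter(Negate(is.null),
                   lapply(ch, function(c) evolve_branch(c, st$length[c])))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) {
      node <- kids[[1]]
      node$length <- node$length + elapsed
      return(node)
    }
    nested_node(children = kids, event = "speciation", length = elapsed)
  }

  evolve_branch <- function(sp_node, remaining) {
    elapsed <- 0
    repeat {
      w <- if (rate > 0) stats::rexp(1L, rate) else Inf
      if (w >= remaining) break
      elapsed <- elapsed + w
      remaining <- remaining - w
      if (stats::runif(1L) < dup_rate / rate) {
        left <- evolve_branch(sp_node, remaining)
        right <- evolve_branch(sp_node, remaining)
        if (is.null(left) && is.null(right)) return(NULL)
        if (is.null(left) || is.null(right)) {
          node <- if (is.null(left)) right else left
          node$length <- node$length + elapsed
          return(node)
        }
        return(nested_node(children = list(left, right),
                           event = "duplication", length = elapsed))
      }
      env$losses <- c(env$losses, sp_node)
      return(NULL)
    }
    at_branch_end(sp_node, elapsed + remaining)
  }

  root <- with_seed(rng_seed, {
    if (root_edge > 0) evolve_branch(1L, root_edge)
    else at_branch_end(1L, 0)
  })
  gene_tree <- if (is.null(root)) NULL else flatten_tree(root, kind = "gene")
  loss_tab <- table(env$losses)
  loss_events <- data.frame(
    species_node = as.integer(names(loss_tab)),
    species_label = st$label[as.integer(names(loss_tab))],
    count = as.integer(loss_tab), stringsAsFactors = FALSE)
  structure(list(
    gene_tree = gene_tree,
    true_events = if (is.null(gene_tree)) character(0) else gene_tree$event,
    loss_events = loss_events,
    params = list(dup_rate = dup_rate, loss_rate = loss_rate,
                  rng_seed = rng_seed, root_edge = root_edge)),
    class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  nl <- if (is.null(x$gene_tree)) 0L else n_leaves(x$gene_tree)
  cat(sprintf(
    "<sim_record: %d gene leaves, %d duplications, %d losses (lambda=%g, mu=%g)>\n",
    nl, sum(x$true_events == "duplication", na.rm = TRUE),
    sum(x$loss_events$count), x$params$dup_rate, x$params$loss_rate))
  invisible(x)
}

#' Ground-truth ortholog pairs of a simulation
#'
#' A leaf pair is a true ortholog when its LCA in the simulated gene
#' tree was logged as a speciation; all other same-tree pairs are true
#' paralogs.
#'
#' @param rec a `sim_record`
#' @return character vector of canonical pair keys (two leaf labels
#'   joined by a tab, smaller first); compare with [call_pair_keys()]
#' @export
true_orthologs <- function(rec) {
  tree <- rec$gene_tree
  if (is.null(tree) || n_leaves(tree) < 2L) return(character(0))
  leafsets <- subtree_leaf_sets(tree)
  keys <- character(0)
  for (i in which(lengths(tree$children) > 0L)) {
    if (!identical(tree$event[i], "speciation")) next
    ch <- tree$children[[i]]
    for (a in seq_along(ch)) for (b in seq_len(a - 1L)) {
      la <- tree$label[leafsets[[ch[a]]]]
      lb <- tree$label[leafsets[[ch[b]]]]
      x <- rep(la, each = length(lb)); y <- rep(lb, times = length(la))
      keys <- c(keys, paste(pmin(x, y), pmax(x, y), sep = "\t"))
    }
  }
  sort(keys)
}

#' Canonical pair keys of ortholog calls
#'
#' @param calls calls data.frame from [infer_orthology()]
#' @param relation keep only calls with this relation (default
#'   `"ortholog"`; `NULL` keeps all)
#' @return sorted character vector of canonical leaf-label pair keys,
#'   comparable with [true_orthologs()]
#' @export
call_pair_keys <- function(calls, relation = "ortholog") {
  if (!is.null(relation))
    calls <- calls[calls$relation == relation, , drop = FALSE]
  a <- paste0(calls$seq_a, "_", calls$species_a)
  b <- paste0(calls$seq_b, "_", calls$species_b)
  sort(unique(paste(pmin(a, b), pmax(a, b), sep = "\t")))
}
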