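# Tree-based orthology/paralogy inference: relation from the event at
# the leaf pair's LCA, type from co-ortholog counts at that node, the
# close2seed filter, and cross-tree consistency scores.

gene_key <- function(seq_id, species) paste(seq_id, species, sep = "\r")

# per-node counts of leaves by species, as named integer vectors
species_counts <- function(tree) {
  out <- vector("list", tree$n)
  for (i in tree$n:1) {
    ch <- tree$children[[i]]
    if (length(ch) == 0L) {
      out[[i]] <- stats::setNames(1L, tree$species[i])
    } else {
      acc <- unlist(out[ch])
      out[[i]] <- tapply(acc, names(acc), sum)
    }
  }
  out
}

#' Infer orthology and paralogy calls from a labeled gene tree
#'
#' Each leaf pair is related through the event at its last common
#' ancestor: a speciation LCA makes the genes orthologs, a duplication
#' LCA (or identical species) makes them paralogs.  Ortholog pairs are
#' typed by co-ortholog counts restricted to the LCA's child clades:
#' with `n_a` genes of a's species on a's side and `n_b` of b's species
#' on b's side, (1,1) is one-to-one, (1,>1) one-to-many, (>1,1)
#' many-to-one, and many-to-many otherwise.
#'
#' @param tree a gene `phylome_tree` labeled by [label_events()]
#' @param seed_leaf restrict calls to pairs containing this leaf
#'   (label or seq_id); `NULL` emits all-vs-all calls
#' @return data.frame of calls (`seq_a`, `species_a`, `seq_b`,
#'   `species_b`, `relation`, `type`, `lca_node`, `sos`), with the source
#'   tree attached as attribute `"tree"`.  In seed mode gene `a` is the
#'   seed; in all-vs-all mode pairs are in lexicographic label order.
#' @export
infer_orthology <- function(tree, seed_leaf = NULL) {
  internal <- which(lengths(tree$children) > 0L)
  if (length(internal) && anyNA(tree$event[internal]))
    stop("tree is not event-labeled; call label_events() first",
         call. = FALSE)
  seed <- if (!is.null(seed_leaf)) find_leaf(tree, seed_leaf) else NA_integer_
  leafsets <- subtree_leaf_sets(tree)
  spcounts <- species_counts(tree)
  all_sp <- tree_species(tree)
  cnt <- matrix(0L, tree$n, length(all_sp), dimnames = list(NULL, all_sp))
  for (i in seq_len(tree$n))
    cnt[i, names(spcounts[[i]])] <- as.integer(spcounts[[i]])
  xs <- list(); ys <- list(); nodes <- list(); chx <- list(); chy <- list()
  blk <- 0L
  for (i in internal) {
    ch <- tree$children[[i]]
    for (a in seq_along(ch)) for (b in seq_len(a - 1L)) {
      la <- leafsets[[ch[a]]]; lb <- leafsets[[ch[b]]]
      x <- rep(la, each = length(lb)); y <- rep(lb, times = length(la))
      if (!is.na(seed)) {
        keep <- x == seed | y == seed
        x <- x[keep]; y <- y[keep]
      }
      if (length(x) == 0L) next
      blk <- blk + 1L
      xs[[blk]] <- x; ys[[blk]] <- y
      nodes[[blk]] <- rep(i, length(x))
      chx[[blk]] <- rep(ch[a], length(x)); chy[[blk]] <- rep(ch[b], length(x))
    }
  }
  x <- unlist(xs); y <- unlist(ys); node <- unlist(nodes)
  cx <- unlist(chx); cy <- unlist(chy)
  if (is.null(x)) x <- y <- node <- cx <- cy <- integer(0)
  spx <- tree$species[x]; spy <- tree$species[y]
  ortho <- spx != spy & tree$event[node] == "speciation"
  nx <- cnt[cbind(cx, match(spx, all_sp))]
  ny <- cnt[cbind(cy, match(spy, all_sp))]
  type <- rep(NA_character_, length(x))
  type[ortho & nx == 1L & ny == 1L] <- "one-to-one"
  type[ortho & nx == 1L & ny > 1L]  <- "one-to-many"
  type[ortho & nx > 1L & ny == 1L]  <- "many-to-one"
  type[ortho & nx > 1L & ny > 1L]   <- "many-to-many"
  # orient: seed first in seed mode, else lexicographic label order
  swap <- if (!is.na(seed)) y == seed else tree$label[y] < tree$label[x]
  xs2 <- ifelse(swap, y, x); ys2 <- ifelse(swap, x, y)
  type <- ifelse(swap & !is.na(type) & type == "one-to-many", "MANY-TO-ONE",
                 type)
  type <- ifelse(swap & !is.na(type) & type == "many-to-one", "one-to-many",
                 type)
  type <- ifelse(!is.na(type) & type == "MANY-TO-ONE", "many-to-one", type)
  x <- xs2; y <- ys2
  calls <- data.frame(
    seq_a = tree$seq_id[x], species_a = tree$species[x],
    seq_b = tree$seq_id[y], species_b = tree$species[y],
    relation = as.character(ifelse(ortho, "ortholog", "paralog")),
    type = type, lca_node = node, sos = tree$sos[node],
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$seq_a, calls$species_a,
                       calls$seq_b, calls$species_b), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "tree") <- tree
  attr(calls, "seed") <- if (is.na(seed)) NULL else tree$label[seed]
  calls
}

#' Rank non-seed leaves by distance to the seed
#'
#' Nodal distance first, then branch-length path distance (missing
#' lengths count 0), then lexicographic seq_id.
#'
#' @param tree a gene `phylome_tree`
#' @param seed_leaf seed leaf reference
#' @return data.frame `node`, `seq_id`, `species`, `nodal`, `blen`
#'   ordered closest-first
#' @export
rank_by_seed_distance <- function(tree, seed_leaf) {
  seed <- find_leaf(tree, seed_leaf)
  depth <- node_depths(tree)
  dlen <- node_depths_len(tree, na_as = 0)
  lv <- setdiff(leaf_nodes(tree), seed)
  nodal <- integer(length(lv)); blen <- numeric(length(lv))
  for (k in seq_along(lv)) {
    l <- lca_node(tree, seed, lv[k], depth)
    nodal[k] <- depth[seed] + depth[lv[k]] - 2L * depth[l]
    blen[k] <- dlen[seed] + dlen[lv[k]] - 2 * dlen[l]
  }
  ord <- order(nodal, blen, tree$seq_id[lv])
  data.frame(node = lv[ord], seq_id = tree$seq_id[lv][ord],
             species = tree$species[lv][ord],
             nodal = nodal[ord], blen = blen[ord],
             stringsAsFactors = FALSE)
}

#' Filter calls to the k sequences closest to the seed (close2seed)
#'
#' Retains a pairwise prediction only when at least one member belongs
#' to the set of the `k` sequences nodally closest to the seed (the seed
#' itself is always retained and, by default, does not consume one of
#' the `k` slots).
#'
#' @param calls data.frame from [infer_orthology()]
#' @param tree the gene tree the calls came from
#' @param seed_leaf seed leaf reference
#' @param k number of closest sequences to keep (default 30)
#' @param include_seed if `TRUE`, the seed occupies one of the `k` slots
#' @return the retained subset of `calls`, original order preserved
#' @export
apply_close2seed <- function(calls, tree, seed_leaf, k = 30L,
                             include_seed = FALSE) {
  if (k < 1L) stop("close2seed k must be >= 1", call. = FALSE)
  seed <- find_leaf(tree, seed_leaf)
  ranking <- rank_by_seed_distance(tree, seed_leaf)
  n_keep <- if (include_seed) k - 1L else k
  keep_nodes <- utils::head(ranking$node, max(n_keep, 0L))
  keys <- gene_key(tree$seq_id[c(seed, keep_nodes)],
                   tree$species[c(seed, keep_nodes)])
  in_set <- gene_key(calls$seq_a, calls$species_a) %in% keys |
            gene_key(calls$seq_b, calls$species_b) %in% keys
  out <- calls[in_set, , drop = FALSE]
  attr(out, "tree") <- attr(calls, "tree")
  attr(out, "seed") <- attr(calls, "seed")
  out
}

#' Cross-tree consistency scores for gene pairs
#'
#' For each gene pair, counts the trees of a collection containing both
#' genes (`n_trees`) and reports the fraction of them in which the
#' pair's LCA is a speciation (its orthology consistency score).  Pairs
#' co-occurring in no tree are omitted.
#'
#' @param trees list of event-labeled gene `phylome_tree`s
#' @param pairs data.frame with columns `seq_a`, `species_a`, `seq_b`,
#'   `species_b`
#' @return `pairs` with `consistency_score` and `n_trees` added,
#'   restricted to pairs present in at least one tree
#' @export
consistency_scores <- function(trees, pairs) {
  if (length(trees) == 0L) stop("empty tree collection", call. = FALSE)
  n_trees <- integer(nrow(pairs))
  n_ortho <- integer(nrow(pairs))
  for (tree in trees) {
    internal <- which(lengths(tree$children) > 0L)
    if (length(internal) && anyNA(tree$event[internal]))
      stop("all trees must be event-labeled", call. = FALSE)
    lv <- leaf_nodes(tree)
    keys <- gene_key(tree$seq_id[lv], tree$species[lv])
    depth <- node_depths(tree)
    ia <- lv[match(gene_key(pairs$seq_a, pairs$species_a), keys)]
    ib <- lv[match(gene_key(pairs$seq_b, pairs$species_b), keys)]
    for (p in seq_len(nrow(pairs))) {
      if (is.na(ia[p]) || is.na(ib[p])) next
      n_trees[p] <- n_trees[p] + 1L
      lca <- lca_node(tree, ia[p], ib[p], depth)
      if (pairs$species_a[p] != pairs$species_b[p] &&
          identical(tree$event[lca], "speciation"))
        n_ortho[p] <- n_ortho[p] + 1L
    }
  }
  out <- pairs[n_trees > 0L, , drop = FALSE]
  out$consistency_score <- n_ortho[n_trees > 0L] / n_trees[n_trees > 0L]
  out$n_trees <- n_trees[n_trees > 0L]
  rownames(out) <- NULL
  out
}

#' One-to-one ortholog matrix across a species panel
#'
#' Rows are seed genes having exactly one ortholog, of type one-to-one,
#' in every listed species; cells hold the unique ortholog's seq_id.
#' The resulting matrix is the input for downstream concatenation.
#'
#' @param calls_by_seed named list: seed gene ID -> calls data.frame
#'   produced in seed mode by [infer_orthology()]
#' @param species ordered character vector of target species mnemonics
#' @return character matrix, rownames = seed IDs, colnames = species
#' @export
one_to_one_sets <- function(calls_by_seed, species) {
  if (length(species) == 0L)
    stop("empty species list", call. = FALSE)
  rows <- list()
  for (seed_id in names(calls_by_seed)) {
    calls <- calls_by_seed[[seed_id]]
    cells <- character(length(species))
    ok <- TRUE
    seed_sp <- if (nrow(calls)) calls$species_a[1] else NA_character_
    for (s in seq_along(species)) {
      sp <- species[s]
      if (!is.na(seed_sp) && sp == seed_sp) {
        cells[s] <- seed_id
        next
      }
      hits <- calls[calls$relation == "ortholog" & calls$species_b == sp, ,
                    drop = FALSE]
      if (nrow(hits) != 1L || hits$type[1] != "one-to-one") {
        ok <- FALSE
        break
      }
      cells[s] <- hits$seq_b[1]
    }
    if (ok && nrow(calls)) rows[[seed_id]] <- cells
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- matrix(character(0), nrow = 0, ncol = length(species))
  colnames(out) <- species
  out
}

#' Write orthology calls as TSV
#'
#' Columns: seed_id, seed_species, target_id, target_species, relation,
#' type, consistency_score, n_trees (empty when absent).
#'
#' @param calls calls data.frame
#' @param path output file
#' @export
write_orthology_tsv <- function(calls, path) {
  out <- data.frame(
    seed_id = calls$seq_a, seed_species = calls$species_a,
    target_id = calls$seq_b, target_species = calls$species_b,
    relation = calls$relation,
    type = ifelse(is.na(calls$type), "", calls$type),
    consistency_score = if ("consistency_score" %in% names(calls))
      calls$consistency_score else "",
    n_trees = if ("n_trees" %in% names(calls)) calls$n_trees else "",
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
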