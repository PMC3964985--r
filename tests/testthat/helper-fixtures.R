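# Shared fixtures and independent brute-force oracles.

# -- random trees ---------------------------------------------------------

# random rooted binary topology over `labels` by uniform sequential
# attachment; returns a Newick string
rand_topology_newick <- function(labels) {
  to_nwk <- function(t) {
    if (!is.list(t)) return(t)
    paste0("(", to_nwk(t[[1]]), ",", to_nwk(t[[2]]), ")")
  }
  count_pos <- function(t) if (!is.list(t)) 1L
                           else 1L + count_pos(t[[1]]) + count_pos(t[[2]])
  attach_at <- function(t, x, k) {
    # replace the k-th node (preorder) of t by (node, x)
    if (k == 1L) return(list(t, x))
    stopifnot(is.list(t))
    n1 <- count_pos(t[[1]])
    if (k - 1L <= n1) list(attach_at(t[[1]], x, k - 1L), t[[2]])
    else list(t[[1]], attach_at(t[[2]], x, k - 1L - n1))
  }
  t <- labels[1]
  for (x in labels[-1]) t <- attach_at(t, x, sample.int(count_pos(t), 1L))
  paste0(to_nwk(t), ";")
}

rand_gene_tree <- function(n, lengths = FALSE) {
  labels <- sprintf("g%02d_SP%02d", seq_len(n), sample.int(max(n, 3L), n,
                                                           replace = TRUE))
  tr <- parse_newick(rand_topology_newick(labels))
  if (lengths && tr$n > 1L)
    tr$length[2:tr$n] <- round(stats::runif(tr$n - 1L, 0.01, 1), 4)
  tr
}

# simulated gene tree with its record; labels ensure distinct leaf sets
rand_sim <- function(n_species = NULL, lambda = NULL, mu = 0,
                     seed = NULL) {
  if (is.null(n_species)) n_species <- sample(5:15, 1L)
  if (is.null(lambda)) lambda <- sample(c(0.1, 0.5, 1.0), 1L)
  st <- simulate_species_tree(n_species, rng_seed = seed)
  rec <- simulate_gene_tree(st, dup_rate = lambda, loss_rate = mu,
                            rng_seed = if (is.null(seed)) NULL else seed + 1L)
  rec$species_tree <- st
  rec
}

# -- brute-force Robinson-Foulds oracle ----------------------------------
# enumerates every internal edge's split by deleting the edge from the
# undirected node graph and flood-filling one side

bf_bipartitions <- function(tree) {
  n <- tree$n
  if (n < 2L) return(character(0))
  adj <- vector("list", n)
  for (i in 2:n) {
    p <- tree$parent[i]
    adj[[i]] <- c(adj[[i]], p)
    adj[[p]] <- c(adj[[p]], i)
  }
  lv <- which(lengths(tree$children) == 0L)
  universe <- sort(tree$label[lv])
  keys <- character(0)
  for (i in 2:n) {
    # remove edge (i, parent(i)); flood from i
    seen <- logical(n)
    queue <- i
    seen[i] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == i && w == tree$parent[i]) next
        if (w == i && v == tree$parent[i]) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    side <- sort(tree$label[intersect(which(seen), lv)])
    if (length(side) < 2L || length(side) > length(universe) - 2L) next
    other <- sort(setdiff(universe, side))
    k1 <- paste(side, collapse = "|")
    k2 <- paste(other, collapse = "|")
    keys <- c(keys, if (k1 < k2) k1 else k2)
  }
  unique(keys)
}

bf_rf <- function(t1, t2) {
  b1 <- bf_bipartitions(t1)
  b2 <- bf_bipartitions(t2)
  raw <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  den <- length(b1) + length(b2)
  list(raw = raw, normalized = if (den == 0) 0 else raw / den)
}

# -- independent reconciliation oracle -----------------------------------
# naive: maps every gene node through the species-set LCA (quadratic
# walks), no shared code with reconcile_core's postorder counting

naive_reconcile_cost <- function(gene_tree, species_tree,
                                 cost = "dup_plus_loss") {
  sp_sets <- phylomekit:::species_sets(gene_tree)
  depth <- phylomekit:::node_depths(species_tree)
  map1 <- function(set) phylomekit:::species_lca(species_tree, set, depth)
  M <- vapply(seq_len(gene_tree$n), function(i) map1(sp_sets[[i]]),
              integer(1))
  dups <- 0L; losses <- 0L
  for (v in seq_len(gene_tree$n)) {
    ch <- gene_tree$children[[v]]
    if (length(ch) == 0L) next
    isdup <- any(M[ch] == M[v])
    dups <- dups + isdup
    for (c in ch)
      losses <- losses + (depth[M[c]] - depth[M[v]]) - (!isdup)
  }
  if (cost == "dup") dups else dups + losses
}

# -- alignment bundles and brute-force trimming oracle -------------------

rand_aln_of <- function(seqs, max_extra = 6L) {
  rows <- lapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    ngap <- sample.int(max_extra, 1L)
    out <- character(length(chars) + ngap)
    pos <- sort(sample.int(length(out), length(chars)))
    out[pos] <- chars
    out[-pos] <- "-"
    paste(out, collapse = "")
  })
  width <- max(nchar(unlist(rows)))
  padded <- vapply(rows, function(r)
    paste0(r, strrep("-", width - nchar(r))), character(1))
  alignment(stats::setNames(padded, names(seqs)))
}

rand_bundle <- function(n_seq = NULL, len = NULL, K = NULL) {
  if (is.null(n_seq)) n_seq <- sample(2:5, 1L)
  if (is.null(len)) len <- sample(4:12, 1L)
  if (is.null(K)) K <- sample(2:6, 1L)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- stats::setNames(
    vapply(seq_len(n_seq), function(i)
      paste(sample(aas, sample(3:len, 1L), replace = TRUE), collapse = ""),
      character(1)),
    sprintf("seq%d", seq_len(n_seq)))
  list(consensus = rand_aln_of(seqs),
       alternatives = lapply(seq_len(K), function(k) rand_aln_of(seqs)))
}

# enumerate all residue pairs of an alignment into a data.frame
bf_pair_rows <- function(aln) {
  ri <- phylomekit:::residue_index(aln)
  rows <- list()
  for (col in seq_len(aln$ncol)) {
    present <- which(!is.na(ri[, col]))
    if (length(present) < 2L) next
    for (a in seq_along(present)) for (b in seq_len(a - 1L)) {
      i <- min(present[a], present[b]); j <- max(present[a], present[b])
      rows[[length(rows) + 1L]] <-
        data.frame(col = col - 1L, i = i, pi = ri[i, col],
                   j = j, pj = ri[j, col])
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(col = integer(0), i = integer(0), pi = integer(0),
                  j = integer(0), pj = integer(0))
}

# brute-force kept columns: score every consensus pair against a flat
# table of all alternative pairs
bf_filter_kept <- function(consensus, alternatives, mode = "strict",
                           min_fraction = 0.5) {
  K <- length(alternatives)
  ids <- consensus$ids
  alt_keys <- unlist(lapply(alternatives, function(alt) {
    ord <- match(ids, alt$ids)
    d <- bf_pair_rows(alignment(stats::setNames(alt$seqs[ord], ids)))
    paste(d$i, d$pi, d$j, d$pj)
  }))
  tab <- table(alt_keys)
  cons_pairs <- bf_pair_rows(consensus)
  kept <- logical(consensus$ncol)
  for (col in seq_len(consensus$ncol) - 1L) {
    d <- cons_pairs[cons_pairs$col == col, , drop = FALSE]
    if (nrow(d) == 0L) { kept[col + 1L] <- TRUE; next }
    supp <- as.integer(tab[paste(d$i, d$pi, d$j, d$pj)])
    supp[is.na(supp)] <- 0L
    kept[col + 1L] <- if (mode == "strict") all(pmax(supp, 1L) > 1L)
                      else mean(supp / K) >= min_fraction
  }
  which(kept) - 1L
}

# strip simulator truth labels so labeling can be re-inferred
strip_events <- function(tree) {
  tree$event[] <- NA_character_
  tree$sos[] <- NA_real_
  tree
}

find_leaf_id <- function(tree, ref) phylomekit:::find_leaf(tree, ref)
trees_equal_pub <- function(a, b, ...) phylomekit:::trees_equal(a, b, ...)
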