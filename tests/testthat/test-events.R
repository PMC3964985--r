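sp3 <- parse_newick("((HUMAN,MOUSE),YEAST);", naming = "none")

test_that("farthest_taxon rooting places the taxonomic outgroup basally", {
  tr <- parse_newick("(A_HUMAN,B_MOUSE,C_YEAST);")
  rooted <- root_tree(tr, sp3, seed_leaf = "A_HUMAN")
  expect_equal(length(rooted$children[[1]]), 2L)
  kid_sets <- lapply(rooted$children[[1]],
                     function(c) phylomekit:::species_sets(rooted)[[c]])
  expect_true(list(c("HUMAN", "MOUSE")) %in% kid_sets ||
              any(vapply(kid_sets, identical, TRUE, c("HUMAN", "MOUSE"))))
  expect_true(any(vapply(kid_sets, identical, TRUE, "YEAST")))
})

test_that("two-leaf trees are returned unchanged by rooting", {
  tr <- parse_newick("(A_HUMAN:0.1,B_MOUSE:0.2);")
  for (strat in c("farthest_taxon", "midpoint"))
    expect_true(trees_equal_pub(tr, root_tree(tr, sp3, "A_HUMAN", strat)))
})

test_that("single-species trees fall back to midpoint, splitting the longest path", {
  tr <- parse_newick("((A_HUMAN:0.1,B_HUMAN:0.3):0.2,C_HUMAN:0.6);")
  expect_message(rooted <- root_tree(tr, sp3, seed_leaf = "A_HUMAN"),
                 "midpoint")
  kids <- rooted$children[[1]]
  # old degree-2 root is suppressed: 0.05 above the midpoint merges into
  # the 0.2 edge
  expect_equal(sort(rooted$length[kids]), c(0.25, 0.55))
  # the two endpoints of the longest path (B, C) end up at depth 0.55
  dlen <- phylomekit:::node_depths_len(rooted)
  expect_equal(dlen[find_leaf_id(rooted, "C_HUMAN")], 0.55)
  expect_equal(dlen[find_leaf_id(rooted, "B_HUMAN")], 0.55)
})

test_that("midpoint rooting without branch lengths is an error", {
  tr <- parse_newick("((A_HUMAN,B_HUMAN),C_HUMAN);")
  expect_error(root_tree(tr, strategy = "midpoint"), "branch length")
})

test_that("species-overlap labeling scores and thresholds as defined", {
  tr <- label_events(parse_newick("((H1_HUMAN,M1_MOUSE),(H2_HUMAN,M2_MOUSE));"))
  expect_equal(tr$event[1], "duplication")
  expect_equal(tr$sos[1], 1.0)
  internal <- setdiff(which(lengths(tr$children) > 0L), 1L)
  expect_equal(tr$event[internal], c("speciation", "speciation"))
  expect_equal(tr$sos[internal], c(0, 0))

  tr2 <- label_events(parse_newick("((A_HUMAN,B_MOUSE),C_YEAST);"))
  expect_true(all(tr2$event[lengths(tr2$children) > 0] == "speciation"))

  # children {HUMAN,MOUSE,RAT} vs {HUMAN}: score 1/3
  tr3 <- parse_newick("(((A_HUMAN,B_MOUSE),C_RAT),D_HUMAN);")
  expect_equal(label_events(tr3, 0.5)$event[1], "speciation")
  expect_equal(label_events(tr3, 0.0)$event[1], "duplication")
  expect_equal(label_events(tr3)$sos[1], 1 / 3)
})

test_that("a score exactly at the threshold is a speciation (strict >)", {
  # children {HUMAN,MOUSE} vs {HUMAN}: score 1/2
  tr <- parse_newick("((A_HUMAN,B_MOUSE),C_HUMAN);")
  expect_equal(label_events(tr)$sos[1], 0.5)
  expect_equal(label_events(tr, 0.5)$event[1], "speciation")
  expect_equal(label_events(tr, 0.49)$event[1], "duplication")
})

test_that("multifurcating roots are refused by label_events", {
  expect_error(label_events(parse_newick("(A_HUMAN,B_MOUSE,C_YEAST);")),
               "root_tree")
})

test_that("labeling with threshold 0 recovers simulator truth on loss-free trees", {
  set.seed(21)
  for (rep in 1:50) {
    rec <- rand_sim()
    lab <- label_events(strip_events(rec$gene_tree))
    expect_equal(lab$event, rec$true_events)
  }
})

test_that("nodal distance counts path edges and is a metric", {
  tr <- parse_newick("(((((a_A,b_B),c_C),d_D),e_E),f_F);")
  expect_equal(nodal_distance(tr, "a_A", "b_B"), 2L)
  expect_equal(nodal_distance(tr, "a_A", "a_A"), 0L)
  expect_equal(nodal_distance(tr, "a_A", "f_F"), 6L)
  expect_error(nodal_distance(tr, "a_A", "zz_Z"), "not found")

  set.seed(22)
  for (rep in 1:10) {
    t2 <- rand_gene_tree(8)
    labs <- tree_leaves(t2)$label
    trip <- sample(labs, 3)
    dab <- nodal_distance(t2, trip[1], trip[2])
    dbc <- nodal_distance(t2, trip[2], trip[3])
    dac <- nodal_distance(t2, trip[1], trip[3])
    expect_equal(dab, nodal_distance(t2, trip[2], trip[1]))
    expect_gte(dab + dbc, dac)
    expect_gt(dab, 0L)
  }
})

test_that("lineage maps order seed ancestors tip-to-root with nested species sets", {
  sp <- parse_newick("(((HUMAN,PANTR)Primates,MOUSE)Mammalia,YEAST)Eukaryota;",
                     naming = "none")
  lin <- lineage_map(sp, "HUMAN")
  expect_equal(vapply(lin$levels, `[[`, "", "name"),
               c("HUMAN", "Primates", "Mammalia", "Eukaryota"))
  sizes <- vapply(lin$levels, function(l) length(l$species), 1L)
  expect_true(all(diff(sizes) > 0))
  expect_error(lineage_map(sp, "CANFA"), "not in species tree")
})

test_that("relative ages date nodes by the smallest containing clade", {
  sp <- parse_newick("(((HUMAN,PANTR)Primates,MOUSE)Mammalia,YEAST)Eukaryota;",
                     naming = "none")
  lin <- lineage_map(sp, "HUMAN")
  tr <- parse_newick("(((h1_HUMAN,h2_HUMAN),m_MOUSE),y_YEAST);")
  aged <- assign_relative_ages(tr, lin)
  hh <- aged$age[phylomekit:::lca_node(aged, find_leaf_id(aged, "h1_HUMAN"),
                                       find_leaf_id(aged, "h2_HUMAN"))]
  hm <- aged$age[phylomekit:::lca_node(aged, find_leaf_id(aged, "h1_HUMAN"),
                                       find_leaf_id(aged, "m_MOUSE"))]
  expect_equal(hh, 0L)          # HUMAN-only node
  expect_equal(hm, 2L)          # Mammalia
  expect_equal(aged$age[1], 3L) # Eukaryota at the root

  bad <- parse_newick("(h_HUMAN,c_CANFA);")
  expect_error(assign_relative_ages(bad, lin), "CANFA")
})

test_that("ages are non-decreasing toward the root", {
  set.seed(23)
  for (rep in 1:10) {
    rec <- rand_sim(n_species = 8, lambda = 0.5)
    lin <- lineage_map(rec$species_tree, tree_species(rec$gene_tree)[1])
    aged <- assign_relative_ages(rec$gene_tree, lin)
    for (i in 2:aged$n)
      expect_gte(aged$age[aged$parent[i]], aged$age[i])
  }
})
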