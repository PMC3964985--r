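test_that("alignment reversal flips columns and is an involution", {
  aln <- alignment(c(s1 = "AB-", s2 = "A-B"))
  rev <- reverse_alignment(aln)
  expect_equal(rev$seqs, c("-BA", "B-A"))
  expect_equal(reverse_alignment(rev)$seqs, aln$seqs)
  one <- alignment(c(s1 = "A", s2 = "C"))
  expect_equal(reverse_alignment(one)$seqs, one$seqs)
})

test_that("pair support counts alternatives co-aligning each residue pair", {
  cons <- alignment(c(a = "ACD", b = "ACD", c = "ACD"))
  alts <- list(cons, cons, cons)
  rep1 <- column_pair_support(cons, alts)
  expect_equal(rep1$n_pairs, rep(3L, 3))       # C(3,2) per full column
  expect_equal(rep1$mean_support, rep(1.0, 3))
  expect_equal(rep1$min_support, rep(3L, 3))

  # a pair placed together in exactly 1 of 5 alternatives
  cons2 <- alignment(c(a = "AC", b = "AC"))
  shift <- alignment(c(a = "AC-", b = "A-C"))
  alts2 <- c(list(cons2), lapply(1:4, function(i) shift))
  rep2 <- column_pair_support(cons2, alts2)
  expect_equal(rep2$min_support[2], 1L)
  expect_equal(rep2$mean_support[2], 1 / 5)

  # gap-only / single-residue columns carry no pairs
  cons3 <- alignment(c(a = "A-C", b = "A-C"))
  rep3 <- column_pair_support(cons3, list(cons3, cons3))
  expect_equal(rep3$n_pairs[2], 0L)
  expect_equal(rep3$mean_support[2], 1.0)
})

test_that("bundle validation names the offending sequence", {
  cons <- alignment(c(a = "AC", b = "AC"))
  bad <- alignment(c(a = "AG", b = "AC"))
  expect_error(column_pair_support(cons, list(bad, cons)), "a")
  expect_error(column_pair_support(cons, list(cons)), "K = 2")
})

test_that("strict filtering drops columns with singleton-support pairs", {
  # disagreeing column supported by 1 of 3 alternatives
  cons <- alignment(c(a = "ACD", b = "ACD"))
  agree <- cons
  shift <- alignment(c(a = "AC-D", b = "A-CD"))
  res <- filter_columns(cons, list(agree, shift, shift), mode = "strict")
  # column 1 (the C/C pair) is placed together only in `agree` -> support 1
  expect_false(1L %in% res$kept)
  expect_true(all(c(0L, 2L) %in% res$kept))
  expect_equal(res$alignment$seqs, c("AD", "AD"))

  all_kept <- filter_columns(cons, list(agree, agree), mode = "strict")
  expect_equal(all_kept$kept, 0:2)

  # all columns dropped -> warning and empty alignment
  c1 <- alignment(c(a = "AC", b = "CA"))
  a1 <- alignment(c(a = "AC--", b = "--CA"))
  expect_warning(empty <- filter_columns(c1, list(a1, a1)), "empty")
  expect_equal(empty$alignment$ncol, 0L)
  expect_equal(empty$kept, integer(0))
})

test_that("filtering is idempotent after re-projection and monotone in min_fraction", {
  set.seed(61)
  for (rep in 1:20) {
    b <- rand_bundle()
    res <- filter_columns(b$consensus, b$alternatives, mode = "strict")
    # re-project alternatives onto the surviving residues (original
    # ungapped coordinates of the kept consensus columns)
    ri <- phylomekit:::residue_index(b$consensus)
    keep <- lapply(stats::setNames(seq_along(b$consensus$ids),
                                   b$consensus$ids),
                   function(r) {
                     v <- ri[r, res$kept + 1L]
                     v[!is.na(v)]
                   })
    alts2 <- lapply(b$alternatives, phylomekit:::mask_residues,
                    keep_by_id = keep)
    # renumber the filtered consensus residues into the masked coordinate
    # system (residues are re-indexed after masking)
    cons2 <- phylomekit:::mask_residues(b$consensus, keep)
    res2 <- suppressWarnings(filter_columns(cons2, alts2, mode = "strict"))
    expect_equal(phylomekit:::ungapped(res2$alignment),
                 phylomekit:::ungapped(cons2))

    # monotonicity: raising min_fraction never adds columns
    prev <- NULL
    for (f in c(0.2, 0.5, 0.8, 1.0)) {
      kept <- suppressWarnings(
        filter_columns(b$consensus, b$alternatives, mode = "fraction",
                       min_fraction = f))$kept
      if (!is.null(prev)) expect_true(all(kept %in% prev))
      prev <- kept
    }
  }
})

test_that("filtering agrees with the brute-force residue-pair table", {
  set.seed(62)
  for (rep in 1:30) {
    b <- rand_bundle()
    for (mode in c("strict", "fraction")) {
      got <- suppressWarnings(
        filter_columns(b$consensus, b$alternatives, mode = mode))$kept
      want <- bf_filter_kept(b$consensus, b$alternatives, mode = mode)
      expect_equal(got, want)
    }
  }
})

test_that("filtering removes columns but never edits residues", {
  set.seed(63)
  for (rep in 1:10) {
    b <- rand_bundle()
    res <- suppressWarnings(filter_columns(b$consensus, b$alternatives))
    ug_in <- phylomekit:::ungapped(b$consensus)
    ug_out <- phylomekit:::ungapped(res$alignment)
    for (id in names(ug_out)) {
      # kept residues are a subsequence of the original sequence
      pat <- paste(strsplit(ug_out[[id]], "")[[1]], collapse = ".*")
      expect_true(ug_out[[id]] == "" || grepl(pat, ug_in[[id]]))
    }
    expect_true(all(diff(res$kept) > 0))
  }
})
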