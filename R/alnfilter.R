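# Consistency-based column filtering across alternative alignments.
#
# The heads-or-tails strategy aligns the same sequences several times
# (different programs, forward and reversed orientation).  A residue
# pair co-aligned in a consensus column is trustworthy to the extent
# that the alternative alignments also place it in a shared column;
# columns whose pairs are seen in just one underlying alignment are
# candidates for removal.

# validate that consensus and alternatives carry identical ungapped
# sequences per seq_id; returns alternatives with rows ordered as consensus
check_bundle <- function(consensus, alternatives) {
  if (length(alternatives) < 2L)
    stop("need at least K = 2 alternative alignments", call. = FALSE)
  ref <- ungapped(consensus)
  lapply(alternatives, function(alt) {
    if (!setequal(alt$ids, consensus$ids))
      stop("alternative alignment has different sequence IDs (",
           paste(symdiff_chr(alt$ids, consensus$ids), collapse = ", "), ")",
           call. = FALSE)
    ug <- ungapped(alt)[consensus$ids]
    bad <- names(ref)[ug != ref]
    if (length(bad))
      stop("ungapped sequence mismatch for: ", paste(bad, collapse = ", "),
           call. = FALSE)
    alignment(stats::setNames(alt$seqs[match(consensus$ids, alt$ids)],
                              consensus$ids))
  })
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

# hash (row_i, res_i, row_j, res_j) -> number of alternatives placing the
# pair in one column; rows are consensus row indices with i < j
pair_support_table <- function(consensus, alternatives) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (alt in alternatives) {
    ri <- residue_index(alt)
    for (col in seq_len(alt$ncol)) {
      rows <- which(!is.na(ri[, col]))
      if (length(rows) < 2L) next
      cmb <- utils::combn(rows, 2L)
      for (p in seq_len(ncol(cmb))) {
        i <- cmb[1L, p]; j <- cmb[2L, p]
        key <- paste(i, ri[i, col], j, ri[j, col], sep = "|")
        cur <- env[[key]]
        env[[key]] <- if (is.null(cur)) 1L else cur + 1L
      }
    }
  }
  env
}

#' Per-column residue-pair support across alternative alignments
#'
#' For every consensus column, every pair of residues placed together in
#' that column is looked up in each of the K alternative alignments; its
#' support is the number of alternatives that also co-align that exact
#' residue pair.  The consensus itself does not vote.
#'
#' @param consensus the consensus `msa`
#' @param alternatives list of K >= 2 alternative `msa`s of the same
#'   ungapped sequences
#' @return data.frame with one row per consensus column: `column`
#'   (0-based), `n_pairs`, `min_support` (raw support floored at 1, see
#'   Details), `mean_support` (mean of support/K, 1.0 for columns with
#'   fewer than two residues), and list-column `support_histogram`
#'   (table of raw supports)
#' @details A pair present in the consensus but in no alternative has raw
#'   support 0; it is reported as `min_support` 1 (strict-mode semantics:
#'   "observed in just one underlying alignment") while `mean_support`
#'   uses the raw 0/K fraction.
#' @export
column_pair_support <- function(consensus, alternatives) {
  alternatives <- check_bundle(consensus, alternatives)
  K <- length(alternatives)
  tab <- pair_support_table(consensus, alternatives)
  ri <- residue_index(consensus)
  nc <- consensus$ncol
  n_pairs <- integer(nc); min_s <- integer(nc); mean_s <- numeric(nc)
  hist <- vector("list", nc)
  for (col in seq_len(nc)) {
    rows <- which(!is.na(ri[, col]))
    if (length(rows) < 2L) {
      n_pairs[col] <- 0L; min_s[col] <- K; mean_s[col] <- 1.0
      hist[[col]] <- table(integer(0))
      next
    }
    cmb <- utils::combn(rows, 2L)
    supp <- integer(ncol(cmb))
    for (p in seq_len(ncol(cmb))) {
      i <- cmb[1L, p]; j <- cmb[2L, p]
      key <- paste(i, ri[i, col], j, ri[j, col], sep = "|")
      cur <- tab[[key]]
      supp[p] <- if (is.null(cur)) 0L else cur
    }
    n_pairs[col] <- length(supp)
    min_s[col] <- min(pmax(supp, 1L))
    mean_s[col] <- mean(supp / K)
    hist[[col]] <- table(supp)
  }
  out <- data.frame(column = seq_len(nc) - 1L, n_pairs = n_pairs,
                    min_support = min_s, mean_support = mean_s,
                    stringsAsFactors = FALSE)
  out$support_histogram <- hist
  out
}

#' Filter consensus columns by cross-alignment consistency
#'
#' `strict` mode drops any column containing a residue pair observed in
#' just one underlying alignment (raw support <= 1); `fraction` mode
#' drops columns whose mean pair support falls below `min_fraction`.
#' Columns with fewer than two residues are always kept.
#'
#' @inheritParams column_pair_support
#' @param mode `"strict"` (default) or `"fraction"`
#' @param min_fraction minimum mean support (fraction of K) for
#'   `fraction` mode; default 0.5
#' @return list with `alignment` (the filtered `msa`), `kept` (0-based
#'   kept column indices, strictly increasing) and `report` (the
#'   [column_pair_support()] table with a `kept` flag added)
#' @export
filter_columns <- function(consensus, alternatives,
                           mode = c("strict", "fraction"),
                           min_fraction = 0.5) {
  mode <- match.arg(mode)
  rep <- column_pair_support(consensus, alternatives)
  keep <- if (mode == "strict") !(rep$n_pairs > 0L & rep$min_support <= 1L)
          else rep$mean_support >= min_fraction
  rep$kept <- keep
  kept <- rep$column[keep]
  if (length(kept) == 0L)
    warning("all columns filtered out; returning an empty alignment",
            call. = FALSE)
  list(alignment = restrict_alignment(consensus, kept),
       kept = kept, report = rep)
}
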