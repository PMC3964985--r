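# Alignment container: ordered gapped rows over a shared column index.

#' Construct a multiple sequence alignment object
#'
#' @param seqs named character vector of gapped sequences (gap `-`),
#'   all the same length; names are sequence IDs
#' @return an `msa` object with fields `ids`, `seqs`, `ncol`
#' @export
alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment rows must be named by sequence ID", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence IDs in alignment", call. = FALSE)
  nc <- unique(nchar(seqs))
  if (length(nc) > 1L)
    stop("alignment rows differ in length: ",
         paste(range(nchar(seqs)), collapse = " vs "), call. = FALSE)
  structure(list(ids = names(seqs), seqs = unname(seqs),
                 ncol = if (length(seqs)) nc else 0L),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa: %d sequences x %d columns>\n", length(x$ids), x$ncol))
  invisible(x)
}

rows_to_strings <- function(m) {
  if (ncol(m) == 0L) return(rep("", nrow(m)))
  apply(m, 1L, paste, collapse = "")
}

# character matrix view (rows = sequences)
aln_matrix <- function(aln) {
  if (length(aln$ids) == 0L) return(matrix(character(0), 0, 0))
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

# ungapped sequences, named by ID
ungapped <- function(aln) {
  stats::setNames(gsub("-", "", aln$seqs, fixed = TRUE), aln$ids)
}

# per-row map column -> 0-based ungapped residue position (NA at gaps)
residue_index <- function(aln) {
  m <- aln_matrix(aln)
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = list(rownames(m)))
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    idx <- cumsum(row != "-") - 1L
    idx[row == "-"] <- NA_integer_
    out[r, ] <- idx
  }
  out
}

#' Read a FASTA alignment
#' @param path FASTA file of gapped sequences (gap `-`)
#' @return an `msa` object
#' @export
read_fasta_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  alignment(stats::setNames(as.character(x), ids))
}

#' Write an alignment to FASTA
#' @param aln an `msa` object
#' @param path output file
#' @export
write_fasta_alignment <- function(aln, path) {
  x <- Biostrings::BStringSet(stats::setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse an alignment (heads-or-tails orientation)
#'
#' Reverses every gapped row, so consensus column `c` maps to
#' `ncol - 1 - c` and each ungapped sequence is character-reversed.
#' Applying it twice restores the input.
#'
#' @param aln an `msa` object
#' @return the reversed `msa`
#' @export
reverse_alignment <- function(aln) {
  rev1 <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                            collapse = "")
  alignment(stats::setNames(vapply(aln$seqs, rev1, character(1)), aln$ids))
}

#' Restrict an alignment to a set of columns
#' @param aln an `msa` object
#' @param columns 0-based column indices to keep (strictly increasing)
#' @param drop_empty also drop columns that become all-gap? (used when
#'   re-projecting alternative alignments onto a filtered consensus)
#' @return an `msa` over the kept columns
#' @export
restrict_alignment <- function(aln, columns, drop_empty = FALSE) {
  m <- aln_matrix(aln)
  m <- m[, columns + 1L, drop = FALSE]
  if (drop_empty && ncol(m))
    m <- m[, colSums(m != "-") > 0L, drop = FALSE]
  alignment(stats::setNames(rows_to_strings(m), aln$ids))
}

# keep, per row, only the residues at 0-based ungapped positions in
# `keep_by_id`; other residues become gaps; then drop all-gap columns
mask_residues <- function(aln, keep_by_id) {
  m <- aln_matrix(aln)
  ri <- residue_index(aln)
  for (id in aln$ids) {
    r <- match(id, aln$ids)
    drop <- !is.na(ri[r, ]) & !(ri[r, ] %in% keep_by_id[[id]])
    m[r, drop] <- "-"
  }
  if (ncol(m)) m <- m[, colSums(m != "-") > 0L, drop = FALSE]
  alignment(stats::setNames(rows_to_strings(m), aln$ids))
}
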