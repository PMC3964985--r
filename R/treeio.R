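#' Parse a leaf name into sequence ID and species
#'
#' PhylomeDB-style exports name leaves `Phy00086SJ_HUMAN`: an opaque
#' sequence identifier followed by a Uniprot species mnemonic.  The
#' default `suffix_underscore` convention splits at the LAST underscore;
#' `prefix_underscore` splits at the first (species in front); `regex`
#' takes a pattern with two capture groups `(seq_id)(species)`.
#'
#' @param raw leaf label, non-empty string
#' @param convention one of `"suffix_underscore"`, `"prefix_underscore"`,
#'   `"regex"`
#' @param regex pattern with exactly two capture groups, used when
#'   `convention = "regex"`
#' @return list with elements `seq_id` and `species`
#' @examples
#' parse_leaf_name("Phy00086SJ_HUMAN")
#' parse_leaf_name("my_gene_1_YEAST")
#' @export
parse_leaf_name <- function(raw,
                            convention = c("suffix_underscore",
                                           "prefix_underscore", "regex"),
                            regex = NULL) {
  convention <- match.arg(convention)
  if (!nzchar(raw)) stop("empty leaf name", call. = FALSE)
  if (convention == "regex") {
    if (is.null(regex)) stop("convention 'regex' needs a pattern", call. = FALSE)
    m <- regmatches(raw, regexec(regex, raw))[[1]]
    if (length(m) != 3L)
      stop("leaf name '", raw, "' does not match pattern '", regex, "'",
           call. = FALSE)
    return(list(seq_id = m[2], species = m[3]))
  }
  pos <- gregexpr("_", raw, fixed = TRUE)[[1]]
  if (pos[1] == -1L)
    stop("leaf name '", raw, "' has no '_' separator (convention ",
         convention, ")", call. = FALSE)
  cut <- if (convention == "suffix_underscore") pos[length(pos)] else pos[1]
  a <- substr(raw, 1L, cut - 1L)
  b <- substr(raw, cut + 1L, nchar(raw))
  if (!nzchar(a) || !nzchar(b))
    stop("leaf name '", raw, "' splits into an empty token", call. = FALSE)
  if (convention == "suffix_underscore") list(seq_id = a, species = b)
  else list(seq_id = b, species = a)
}

# -- Newick/NHX reader ----------------------------------------------------

# tokenizer state kept in an environment; position is 1-based
nwk_error <- function(st, msg) {
  stop("newick parse error at position ", st$pos, ": ", msg, call. = FALSE)
}

nwk_peek <- function(st) {
  while (st$pos <= st$len && substr(st$text, st$pos, st$pos) %in% c(" ", "\t", "\n", "\r"))
    st$pos <- st$pos + 1L
  if (st$pos > st$len) "" else substr(st$text, st$pos, st$pos)
}

nwk_label <- function(st) {
  start <- st$pos
  while (st$pos <= st$len &&
         !(substr(st$text, st$pos, st$pos) %in% c("(", ")", ",", ":", ";", "[")))
    st$pos <- st$pos + 1L
  trimws(substr(st$text, start, st$pos - 1L))
}

nwk_nhx <- function(st) {
  # returns named character vector of NHX tags, or NULL
  if (nwk_peek(st) != "[") return(NULL)
  close <- regexpr("]", substr(st$text, st$pos, st$len), fixed = TRUE)
  if (close == -1L) nwk_error(st, "unterminated '[' comment")
  body <- substr(st$text, st$pos + 1L, st$pos + close - 2L)
  st$pos <- st$pos + close
  if (!startsWith(body, "&&NHX")) return(NULL)  # plain comment, ignored
  body <- sub("^&&NHX:?", "", body)
  if (!nzchar(body)) return(character(0))
  parts <- strsplit(body, ":", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals
}

nwk_subtree <- function(st) {
  node <- nested_node()
  if (nwk_peek(st) == "(") {
    st$pos <- st$pos + 1L
    repeat {
      node$children[[length(node$children) + 1L]] <- nwk_subtree(st)
      ch <- nwk_peek(st)
      if (ch == ",") { st$pos <- st$pos + 1L; next }
      if (ch == ")") { st$pos <- st$pos + 1L; break }
      nwk_error(st, if (ch == "") "unexpected end of input (unbalanced '(')"
                    else paste0("unexpected '", ch, "'"))
    }
  }
  nwk_peek(st)
  node$label <- nwk_label(st)
  if (!nzchar(node$label)) node$label <- NA_character_
  if (nwk_peek(st) == ":") {
    st$pos <- st$pos + 1L
    nwk_peek(st)
    start <- st$pos
    while (st$pos <= st$len &&
           grepl("[0-9eE+.\\-]", substr(st$text, st$pos, st$pos)))
      st$pos <- st$pos + 1L
    val <- suppressWarnings(as.numeric(substr(st$text, start, st$pos - 1L)))
    if (is.na(val)) nwk_error(st, "invalid branch length")
    node$length <- val
  }
  tags <- nwk_nhx(st)
  if (!is.null(tags)) {
    if ("Ev" %in% names(tags))
      node$event <- switch(tags[["Ev"]], D = "duplication", S = "speciation",
                           NA_character_)
    if ("S" %in% names(tags))   node$species <- tags[["S"]]
    if ("B" %in% names(tags))   node$support <- as.numeric(tags[["B"]])
    if ("sos" %in% names(tags)) node$sos <- as.numeric(tags[["sos"]])
    if ("age" %in% names(tags)) node$age <- as.integer(tags[["age"]])
  }
  node
}

#' Parse a Newick/NHX string into a tree
#'
#' Reads plain Newick and NHX-annotated Newick (tags `Ev` for
#' duplication/speciation, `S` for species, `B` for support, `sos` for
#' the species-overlap score, `age` for the relative-age index).
#' Multifurcations are accepted.  For gene trees, leaf labels are split
#' into (seq_id, species) under `naming`; internal labels are read as
#' support values when numeric and as clade names otherwise.
#'
#' @param text a Newick/NHX string (one tree, ';'-terminated)
#' @param naming leaf-name convention: `"suffix_underscore"` (default,
#'   `Phy00086SJ_HUMAN` style), `"prefix_underscore"`, `"regex"`, or
#'   `"none"` for species trees / unannotated leaves
#' @param regex pattern for `naming = "regex"` (two capture groups)
#' @return a `phylome_tree`
#' @examples
#' tr <- parse_newick("((A_HUMAN:0.1,B_MOUSE:0.2):0.05,C_YEAST:0.4);")
#' tree_species(tr)
#' @export
parse_newick <- function(text, naming = c("suffix_underscore",
                                          "prefix_underscore",
                                          "regex", "none"),
                         regex = NULL) {
  naming <- match.arg(naming)
  st <- new.env(parent = emptyenv())
  st$text <- text
  st$len <- nchar(text)
  st$pos <- 1L
  root <- nwk_subtree(st)
  if (nwk_peek(st) != ";")
    nwk_error(st, "expected ';' terminating the tree")
  st$pos <- st$pos + 1L
  if (nwk_peek(st) != "")
    nwk_error(st, "trailing characters after ';'")
  kind <- if (naming == "none") "species" else "gene"
  tree <- flatten_tree(root, kind = kind)
  internal <- which(lengths(tree$children) > 0L)
  lab <- tree$label[internal]
  num <- suppressWarnings(as.numeric(lab))
  tree$support[internal] <- ifelse(!is.na(num), num, tree$support[internal])
  tree$clade[internal] <- ifelse(is.na(num) & !is.na(lab), lab,
                                 tree$clade[internal])
  if (naming != "none") {
    for (i in leaf_nodes(tree)) {
      if (is.na(tree$label[i]))
        stop("unnamed leaf in gene tree", call. = FALSE)
      p <- parse_leaf_name(tree$label[i], naming, regex = regex)
      tree$seq_id[i] <- p$seq_id
      if (is.na(tree$species[i])) tree$species[i] <- p$species
    }
    key <- paste(tree$seq_id[leaf_nodes(tree)],
                 tree$species[leaf_nodes(tree)], sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (seq_id, species) leaves: ",
           paste(unique(tree$label[leaf_nodes(tree)][duplicated(key)]),
                 collapse = ", "), call. = FALSE)
  }
  tree
}

#' Read a Newick/NHX file
#' @param path file containing a single tree
#' @inheritParams parse_newick
#' @return a `phylome_tree`
#' @export
read_newick <- function(path, naming = "suffix_underscore", regex = NULL) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""),
               naming = naming, regex = regex)
}

# -- Newick/NHX writer ----------------------------------------------------

fmt_len <- function(x) sprintf(":%s", formatC(x, digits = 6, format = "fg",
                                              flag = "#"))

nhx_tags <- function(tree, i) {
  tags <- character(0)
  if (!is.na(tree$event[i]))
    tags <- c(tags, paste0("Ev=", if (tree$event[i] == "duplication") "D" else "S"))
  if (!is.na(tree$sos[i]))
    tags <- c(tags, sprintf("sos=%.15g", tree$sos[i]))
  if (!is.na(tree$age[i])) tags <- c(tags, sprintf("age=%d", tree$age[i]))
  if (is_leaf(tree, i) && !is.na(tree$species[i]))
    tags <- c(tags, paste0("S=", tree$species[i]))
  if (length(tags) == 0L) return("")
  paste0("[&&NHX:", paste(tags, collapse = ":"), "]")
}

#' Serialize a tree to Newick/NHX
#'
#' Inverse of [parse_newick()]: `parse_newick(write_newick(t))` restores
#' topology, labels, branch lengths (6 significant digits) and, with
#' `annotated = TRUE`, NHX event/score/age annotations.
#'
#' @param tree a `phylome_tree`
#' @param annotated emit `[&&NHX:...]` tags (Ev, sos, age, S)?
#' @return a single Newick string terminated by ';'
#' @export
write_newick <- function(tree, annotated = FALSE) {
  wr <- function(i) {
    ch <- tree$children[[i]]
    lab <- if (length(ch) == 0L) tree$label[i]
           else if (!is.na(tree$clade[i])) tree$clade[i]
           else if (!is.na(tree$support[i])) sprintf("%g", tree$support[i])
           else NA_character_
    core <- if (length(ch) == 0L) {
      if (is.na(lab)) "" else lab
    } else {
      paste0("(", paste(vapply(ch, wr, character(1)), collapse = ","), ")",
             if (is.na(lab)) "" else lab)
    }
    paste0(core,
           if (!is.na(tree$length[i])) fmt_len(tree$length[i]) else "",
           if (annotated) nhx_tags(tree, i) else "")
  }
  paste0(wr(1L), ";")
}

#' Write a tree to a Newick/NHX file
#' @inheritParams write_newick
#' @param path output file
#' @export
write_newick_file <- function(tree, path, annotated = FALSE) {
  writeLines(write_newick(tree, annotated = annotated), path)
  invisible(path)
}
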