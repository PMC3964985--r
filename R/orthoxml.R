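# OrthoXML 0.3 export/import of orthology calls.
#
# Ortholog clusters are emitted as nested orthologGroup/paralogGroup
# elements mirroring the labeled gene tree restricted to the called
# genes, so that the innermost group containing two genes encodes their
# relation.  When the most recent common ancestor of an exported gene
# set is a duplication the top-level element is a paralogGroup; the
# 0.3 schema technically allows only orthologGroup there, but emitting
# the true structure is what keeps write -> parse lossless, and the
# reader accepts both.

#' Write orthology calls as OrthoXML
#'
#' @param calls calls data.frame from [infer_orthology()] (must carry
#'   its source tree as attribute `"tree"`, which it does unless the
#'   attribute was stripped)
#' @param path output file; `NULL` returns the `xml_document`
#' @param origin database name for the `origin` attribute
#' @param origin_version database version string
#' @return the path (invisibly) or the `xml_document`
#' @export
write_orthoxml <- function(calls, path = NULL, origin = "phylomekit",
                           origin_version = "1") {
  if (is.null(calls) || nrow(calls) == 0L)
    stop("empty call list", call. = FALSE)
  tree <- attr(calls, "tree")
  if (is.null(tree))
    stop("calls carry no source tree (attribute 'tree'); ",
         "re-derive them with infer_orthology()", call. = FALSE)
  keys <- unique(c(gene_key(calls$seq_a, calls$species_a),
                   gene_key(calls$seq_b, calls$species_b)))
  lv <- leaf_nodes(tree)
  leaf_keys <- gene_key(tree$seq_id[lv], tree$species[lv])
  unknown <- setdiff(keys, leaf_keys)
  if (length(unknown))
    stop("calls reference genes absent from the tree: ",
         paste(gsub("\r", "_", unknown), collapse = ", "), call. = FALSE)
  ids <- stats::setNames(seq_along(keys), keys)
  species_of <- vapply(strsplit(keys, "\r", fixed = TRUE), `[`, "", 2)
  seq_of <- vapply(strsplit(keys, "\r", fixed = TRUE), `[`, "", 1)

  doc <- xml2::xml_new_root(
    "orthoXML", xmlns = "http://orthoXML.org/2011/", version = "0.3",
    origin = origin, originVersion = origin_version)
  for (sp in sort(unique(species_of))) {
    sp_node <- xml2::xml_add_child(doc, "species", name = sp,
                                   NCBITaxId = "0")
    db <- xml2::xml_add_child(sp_node, "database", name = origin,
                              version = origin_version)
    genes <- xml2::xml_add_child(db, "genes")
    for (k in which(species_of == sp))
      xml2::xml_add_child(genes, "gene", id = as.character(ids[k]),
                          protId = seq_of[k])
  }
  xml2::xml_add_child(xml2::xml_add_child(doc, "scores"), "scoreDef",
                      id = "consistency",
                      desc = "fraction of trees in which the pair is orthologous")

  has_score <- "consistency_score" %in% names(calls) &&
    any(!is.na(calls$consistency_score))
  call_keys_a <- gene_key(calls$seq_a, calls$species_a)
  call_keys_b <- gene_key(calls$seq_b, calls$species_b)

  # nested unit structure over the tree restricted to the called genes
  build <- function(i) {
    if (is_leaf(tree, i)) {
      k <- gene_key(tree$seq_id[i], tree$species[i])
      if (!k %in% keys) return(NULL)
      return(list(kind = "gene", id = ids[[k]], keys = k))
    }
    kids <- Filter(Negate(is.null), lapply(tree$children[[i]], build))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    list(kind = if (identical(tree$event[i], "duplication")) "paralogGroup"
                else "orthologGroup",
         children = kids,
         keys = unlist(lapply(kids, `[[`, "keys")))
  }
  emit_unit <- function(parent, unit) {
    if (unit$kind == "gene") {
      xml2::xml_add_child(parent, "geneRef", id = as.character(unit$id))
      return(invisible(NULL))
    }
    g <- xml2::xml_add_child(parent, unit$kind)
    if (has_score) {
      inside <- call_keys_a %in% unit$keys & call_keys_b %in% unit$keys
      sc <- calls$consistency_score[inside]
      if (any(!is.na(sc)))
        xml2::xml_add_child(g, "score", id = "consistency",
                            value = sprintf("%g", mean(sc, na.rm = TRUE)))
    }
    for (u in unit$children) emit_unit(g, u)
    invisible(NULL)
  }
  groups <- xml2::xml_add_child(doc, "groups")
  top <- build(1L)
  if (!is.null(top) && top$kind != "gene") emit_unit(groups, top)
  if (is.null(path)) return(doc)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read orthology calls back from an OrthoXML document
#'
#' Two genes are related through the innermost group containing both:
#' `orthologGroup` means ortholog, `paralogGroup` paralog; genes of the
#' same species are always reported as paralogs.  Genes in different
#' top-level groups carry no relation.
#'
#' @param path OrthoXML file (or an `xml_document`)
#' @return calls data.frame with `seq_a`, `species_a`, `seq_b`,
#'   `species_b`, `relation`, ordered canonically
#' @export
read_orthoxml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  doc <- xml2::xml_ns_strip(doc)
  gene_nodes <- xml2::xml_find_all(doc, ".//species//gene")
  gid <- xml2::xml_attr(gene_nodes, "id")
  prot <- xml2::xml_attr(gene_nodes, "protId")
  spp <- xml2::xml_attr(
    xml2::xml_find_first(gene_nodes, "./ancestor::species"), "name")
  seq_of <- stats::setNames(prot, gid)
  sp_of <- stats::setNames(spp, gid)
  rows <- list()
  walk <- function(node) {
    # returns gene ids below this group element
    kids <- xml2::xml_children(node)
    kind <- xml2::xml_name(node)
    sets <- list()
    for (k in kids) {
      nm <- xml2::xml_name(k)
      if (nm == "geneRef") sets[[length(sets) + 1L]] <- xml2::xml_attr(k, "id")
      else if (nm %in% c("orthologGroup", "paralogGroup"))
        sets[[length(sets) + 1L]] <- walk(k)
    }
    if (length(sets) > 1L) {
      for (a in seq_along(sets)) for (b in seq_len(a - 1L)) {
        x <- rep(sets[[a]], each = length(sets[[b]]))
        y <- rep(sets[[b]], times = length(sets[[a]]))
        rel <- ifelse(sp_of[x] == sp_of[y], "paralog",
                      if (kind == "orthologGroup") "ortholog" else "paralog")
        rows[[length(rows) + 1L]] <<- data.frame(
          ia = x, ib = y, relation = rel, stringsAsFactors = FALSE)
      }
    }
    unlist(sets)
  }
  for (g in xml2::xml_find_all(doc, "./groups/*")) walk(g)
  if (length(rows) == 0L)
    return(data.frame(seq_a = character(0), species_a = character(0),
                      seq_b = character(0), species_b = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  d <- do.call(rbind, rows)
  la <- paste0(seq_of[d$ia], "_", sp_of[d$ia])
  lb <- paste0(seq_of[d$ib], "_", sp_of[d$ib])
  swap <- lb < la
  ia <- ifelse(swap, d$ib, d$ia); ib <- ifelse(swap, d$ia, d$ib)
  out <- data.frame(seq_a = unname(seq_of[ia]), species_a = unname(sp_of[ia]),
                    seq_b = unname(seq_of[ib]), species_b = unname(sp_of[ib]),
                    relation = d$relation, stringsAsFactors = FALSE)
  out <- out[order(out$seq_a, out$species_a, out$seq_b, out$species_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
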