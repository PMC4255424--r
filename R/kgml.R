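#' Parse a KGML pathway file
#'
#' Reads one KEGG Markup Language (KGML) XML document and returns a structured
#' pathway definition holding its three object classes: entries (boxes and
#' circles on the pathway map), relations (signalling edges between entries)
#' and reactions (substrate/product conversions catalysed by enzyme entries).
#'
#' Gene identifiers such as `"hsa:5594"` are reduced to their canonical
#' numeric part (`"5594"`); the organism prefix is recorded once per pathway.
#' Relations or reactions whose endpoints do not resolve to parsed entries are
#' dropped with a warning rather than aborting the parse. Reactions missing a
#' `type` attribute (older KGML dialects) are treated as irreversible.
#'
#' @param xml_source Path to a KGML file, or a length-1 character vector
#'   containing KGML XML text.
#' @return An object of class `prs_pathway`: a list with elements `kegg_id`,
#'   `title`, `organism`, `entries`, `relations`, `reactions` and `category`
#'   (`"signalling"` or `"metabolic"`).
#' @seealso [classify_pathway()], [build_pathway_graph()]
#' @examples
#' kgml <- paste0(
#'   '<pathway name="path:hsa00001" org="hsa" title="demo">',
#'   '<entry id="1" name="hsa:10" type="gene"/>',
#'   '<entry id="2" name="hsa:20" type="gene"/>',
#'   '<relation entry1="1" entry2="2" type="PPrel">',
#'   '<subtype name="activation" value="--&gt;"/></relation></pathway>'
#' )
#' p <- parse_kgml(kgml)
#' p$category
#' @export
parse_kgml <- function(xml_source) {
  src_label <- if (length(xml_source) == 1L && !grepl("<", xml_source, fixed = TRUE)) {
    xml_source
  } else {
    "<inline XML>"
  }
  doc <- tryCatch(
    xml2::read_xml(xml_source),
    error = function(e) {
      stop("Malformed XML in '", src_label, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  root <- xml2::xml_name(doc)
  if (!identical(root, "pathway")) {
    stop("Not a KGML document (root element <", root, ">, expected <pathway>): ",
         src_label, call. = FALSE)
  }

  kegg_name <- xml2::xml_attr(doc, "name")
  kegg_id <- sub("^path:", "", kegg_name %||% "")
  organism <- xml2::xml_attr(doc, "org") %||% ""
  title <- xml2::xml_attr(doc, "title") %||% kegg_id

  entries <- lapply(xml2::xml_find_all(doc, "./entry"), parse_kgml_entry)
  names(entries) <- vapply(entries, `[[`, "", "entry_id")
  if (anyDuplicated(names(entries))) {
    warning("Duplicate entry ids in ", src_label, "; keeping first occurrence")
    entries <- entries[!duplicated(names(entries))]
  }
  entry_ids <- names(entries)

  # validate group components against parsed entries
  for (i in seq_along(entries)) {
    comp <- entries[[i]]$component_ids
    bad <- setdiff(comp, entry_ids)
    if (length(bad)) {
      warning("Group entry ", entries[[i]]$entry_id, " in ", src_label,
              " references missing components: ", paste(bad, collapse = ", "))
      entries[[i]]$component_ids <- setdiff(comp, bad)
    }
  }

  relations <- lapply(xml2::xml_find_all(doc, "./relation"), parse_kgml_relation)
  keep <- vapply(relations, function(r) {
    ok <- r$entry1_id %in% entry_ids && r$entry2_id %in% entry_ids
    if (!ok) {
      warning("Dropping relation ", r$entry1_id, "->", r$entry2_id, " in ",
              src_label, ": unresolved endpoint")
    }
    ok
  }, logical(1))
  relations <- relations[keep]

  reactions <- lapply(xml2::xml_find_all(doc, "./reaction"),
                      parse_kgml_reaction, entries = entries)
  keep <- vapply(reactions, function(r) {
    if (length(r$enzyme_entry_ids) == 0L) {
      warning("Dropping reaction '", r$reaction_name, "' in ", src_label,
              ": no enzyme entry resolves to it")
      return(FALSE)
    }
    if (length(r$substrate_ids) == 0L || length(r$product_ids) == 0L) {
      warning("Dropping reaction '", r$reaction_name, "' in ", src_label,
              ": empty substrate or product list")
      return(FALSE)
    }
    TRUE
  }, logical(1))
  reactions <- reactions[keep]

  defn <- structure(
    list(kegg_id = kegg_id, title = title, organism = organism,
         entries = entries, relations = relations, reactions = reactions,
         category = NA_character_),
    class = "prs_pathway"
  )
  defn$category <- classify_pathway(defn)
  defn
}

parse_kgml_entry <- function(node) {
  type <- xml2::xml_attr(node, "type") %||% "gene"
  name <- xml2::xml_attr(node, "name") %||% ""
  graphics <- xml2::xml_find_first(node, "./graphics")
  display <- if (inherits(graphics, "xml_node")) {
    xml2::xml_attr(graphics, "name") %||% name
  } else {
    name
  }
  gene_ids <- character(0)
  if (type %in% c("gene", "enzyme", "ortholog")) {
    toks <- split_ws(name)
    # only org-prefixed tokens resolve to genes; EC numbers / KO ids do not
    toks <- toks[grepl("^[a-z]{2,4}:", toks)]
    gene_ids <- sub("^[a-z]{2,4}:", "", toks)
    if (type %in% c("enzyme", "ortholog") && length(gene_ids) == 0L) {
      # unresolvable enzyme/ortholog: parsed, but never becomes a gene node
      gene_ids <- character(0)
    }
  }
  comp <- character(0)
  if (identical(type, "group")) {
    comp <- xml2::xml_attr(xml2::xml_find_all(node, "./component"), "id")
  }
  list(
    entry_id = xml2::xml_attr(node, "id"),
    entry_type = type,
    gene_ids = unique(gene_ids),
    component_ids = comp,
    display_name = display,
    reaction_names = split_ws(xml2::xml_attr(node, "reaction") %||% "")
  )
}

parse_kgml_relation <- function(node) {
  list(
    entry1_id = xml2::xml_attr(node, "entry1"),
    entry2_id = xml2::xml_attr(node, "entry2"),
    relation_type = xml2::xml_attr(node, "type") %||% "",
    subtypes = xml2::xml_attr(xml2::xml_find_all(node, "./subtype"), "name")
  )
}

parse_kgml_reaction <- function(node, entries) {
  rname <- xml2::xml_attr(node, "name") %||% ""
  rid <- xml2::xml_attr(node, "id")
  # KGML >= 0.7.1 carries the catalysing entry id on the reaction; older
  # dialects link via the entry's own "reaction" attribute
  enz <- character(0)
  if (!is.na(rid) && rid %in% names(entries)) enz <- rid
  rnames <- split_ws(rname)
  via_attr <- names(entries)[vapply(entries, function(e) {
    any(e$reaction_names %in% rnames)
  }, logical(1))]
  enz <- union(enz, via_attr)
  strip_cpd <- function(x) sub("^cpd:", "", x)
  list(
    reaction_name = rname,
    enzyme_entry_ids = enz,
    substrate_ids = strip_cpd(xml2::xml_attr(
      xml2::xml_find_all(node, "./substrate"), "name")),
    product_ids = strip_cpd(xml2::xml_attr(
      xml2::xml_find_all(node, "./product"), "name")),
    reversible = identical(xml2::xml_attr(node, "type"), "reversible")
  )
}

#' Classify a pathway as signalling or metabolic
#'
#' A pathway is metabolic if and only if it contains at least one reaction
#' element; KGML offers no other structural discriminator between the two
#' representations. A pathway carrying both relations and reactions is
#' classified metabolic.
#'
#' @param defn A `prs_pathway` from [parse_kgml()].
#' @return `"metabolic"` if any reactions are present, else `"signalling"`.
#' @export
classify_pathway <- function(defn) {
  stopifnot(inherits(defn, "prs_pathway"))
  if (length(defn$reactions) > 0L) "metabolic" else "signalling"
}

#' Parse every KGML file in a directory
#'
#' @param dir Directory containing `.xml`/`.kgml` files, one pathway each.
#' @return Named list of `prs_pathway` objects (names are KEGG ids).
#' @export
parse_kgml_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(xml|kgml)$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("No KGML files (*.xml, *.kgml) found in ", dir, call. = FALSE)
  }
  defs <- lapply(files, parse_kgml)
  names(defs) <- vapply(defs, `[[`, "", "kegg_id")
  defs
}

#' Serialize a pathway definition back to KGML
#'
#' Writes entries, relations and reactions in KGML form. Used by the fixture
#' generator and for round-trip checks; not intended to reproduce KEGG's
#' graphics annotations.
#'
#' @param defn A `prs_pathway`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kgml <- function(defn, path) {
  stopifnot(inherits(defn, "prs_pathway"))
  doc <- xml2::xml_new_root(
    "pathway",
    name = paste0("path:", defn$kegg_id),
    org = defn$organism,
    number = sub("^[a-z]+", "", defn$kegg_id),
    title = defn$title
  )
  pfx <- function(ids) {
    if (nzchar(defn$organism)) paste0(defn$organism, ":", ids) else ids
  }
  for (e in defn$entries) {
    nm <- switch(e$entry_type,
                 gene = , enzyme = , ortholog = paste(pfx(e$gene_ids), collapse = " "),
                 compound = e$display_name,
                 e$display_name)
    attrs <- list(id = e$entry_id, name = nm, type = e$entry_type)
    if (length(e$reaction_names)) {
      attrs$reaction <- paste(e$reaction_names, collapse = " ")
    }
    en <- do.call(xml2::xml_add_child, c(list(doc, "entry"), attrs))
    for (cid in e$component_ids) xml2::xml_add_child(en, "component", id = cid)
  }
  for (r in defn$relations) {
    rn <- xml2::xml_add_child(doc, "relation", entry1 = r$entry1_id,
                              entry2 = r$entry2_id, type = r$relation_type)
    for (s in r$subtypes) xml2::xml_add_child(rn, "subtype", name = s, value = "-->")
  }
  for (r in defn$reactions) {
    rn <- xml2::xml_add_child(
      doc, "reaction",
      id = r$enzyme_entry_ids[[1]],
      name = r$reaction_name,
      type = if (r$reversible) "reversible" else "irreversible"
    )
    for (s in r$substrate_ids) {
      xml2::xml_add_child(rn, "substrate", id = s, name = paste0("cpd:", s))
    }
    for (p in r$product_ids) {
      xml2::xml_add_child(rn, "product", id = p, name = paste0("cpd:", p))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @export
print.prs_pathway <- function(x, ...) {
  cat("KGML pathway", x$kegg_id, "-", x$title, "\n")
  cat("  category:", x$category, "\n")
  cat(sprintf("  %d entries, %d relations, %d reactions\n",
              length(x$entries), length(x$relations), length(x$reactions)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

split_ws <- function(x) {
  out <- strsplit(trimws(x), "\\s+")[[1]]
  out[nzchar(out)]
}
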