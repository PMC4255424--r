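#' Build a directed gene graph from a pathway definition
#'
#' Dispatches to [build_signalling_graph()] or [build_metabolic_graph()]
#' according to the pathway's category. Both builders finish by merging nodes
#' that share a gene ([deduplicate_nodes()]), so every gene appears exactly
#' once in the returned graph.
#'
#' @param defn A `prs_pathway` from [parse_kgml()].
#' @return A `prs_graph` object (see Details). Graphs with zero gene nodes are
#'   returned empty with a warning; callers exclude them from scoring.
#'
#' @details A `prs_graph` is a list with `pathway_id`, `title`, `category`,
#' `nodes` (named list; each node has `gene_ids` and `source_entry_ids`) and
#' `edges` (two-column character matrix of node ids, duplicate-free, no
#' self-edges). Node ids equal the lexicographically smallest member gene id,
#' giving deterministic output ordering.
#' @export
build_pathway_graph <- function(defn) {
  stopifnot(inherits(defn, "prs_pathway"))
  if (identical(defn$category, "metabolic")) {
    build_metabolic_graph(defn)
  } else {
    build_signalling_graph(defn)
  }
}

new_prs_graph <- function(defn, nodes, edges) {
  structure(
    list(pathway_id = defn$kegg_id, title = defn$title,
         category = defn$category, nodes = nodes, edges = edges),
    class = "prs_graph"
  )
}

empty_edges <- function() {
  matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
}

# entry_id -> gene-bearing entry ids, expanding group entries one level
resolve_gene_entries <- function(entry_id, entries) {
  e <- entries[[entry_id]]
  if (is.null(e)) return(character(0))
  if (identical(e$entry_type, "group")) {
    out <- unlist(lapply(e$component_ids, function(cid) {
      ce <- entries[[cid]]
      if (!is.null(ce) && length(ce$gene_ids)) cid else character(0)
    }))
    return(unique(out))
  }
  if (length(e$gene_ids)) entry_id else character(0)
}

provisional_nodes <- function(defn) {
  keep <- vapply(defn$entries, function(e) length(e$gene_ids) > 0L, logical(1))
  lapply(defn$entries[keep], function(e) {
    list(gene_ids = e$gene_ids, source_entry_ids = e$entry_id)
  })
}

#' Build the graph of a signalling pathway
#'
#' One provisional node per gene-bearing entry; one directed edge
#' `entry1 -> entry2` per relation whose endpoints resolve to gene nodes.
#' Relations touching a group entry fan out to every gene component of the
#' group; relations to or from map/compound entries are dropped. The result is
#' deduplicated so each gene occurs in exactly one node.
#'
#' @param defn A `prs_pathway` with `category == "signalling"`.
#' @return A `prs_graph`.
#' @export
build_signalling_graph <- function(defn) {
  stopifnot(inherits(defn, "prs_pathway"))
  nodes <- provisional_nodes(defn)
  if (length(nodes) == 0L) {
    warning("Pathway ", defn$kegg_id, " has no gene entries; empty graph")
    return(new_prs_graph(defn, list(), empty_edges()))
  }
  from <- character(0); to <- character(0)
  for (r in defn$relations) {
    src <- resolve_gene_entries(r$entry1_id, defn$entries)
    tgt <- resolve_gene_entries(r$entry2_id, defn$entries)
    if (length(src) && length(tgt)) {
      pairs <- expand.grid(src, tgt, stringsAsFactors = FALSE)
      from <- c(from, pairs[[1]]); to <- c(to, pairs[[2]])
    }
  }
  edges <- cbind(from = from, to = to)
  deduplicate_nodes(new_prs_graph(defn, nodes, edges))
}

#' Build the graph of a metabolic pathway
#'
#' Enzymes become nodes; substrates and products orient the edges. A directed
#' edge `E1 -> E2` is added whenever some product of a reaction catalysed by
#' `E1` is a substrate of a reaction catalysed by `E2`. For reversible
#' reactions both compound lists count as substrates and as products. ECrel
#' relations between enzyme entries contribute additional edges. Self-edges
#' are discarded and the graph is deduplicated.
#'
#' @param defn A `prs_pathway` with `category == "metabolic"`.
#' @return A `prs_graph`.
#' @export
build_metabolic_graph <- function(defn) {
  stopifnot(inherits(defn, "prs_pathway"))
  nodes <- provisional_nodes(defn)
  if (length(nodes) == 0L) {
    warning("Pathway ", defn$kegg_id, " has no enzyme gene entries; empty graph")
    return(new_prs_graph(defn, list(), empty_edges()))
  }
  rx <- defn$reactions
  eff_products <- lapply(rx, function(r) {
    if (r$reversible) union(r$product_ids, r$substrate_ids) else r$product_ids
  })
  eff_substrates <- lapply(rx, function(r) {
    if (r$reversible) union(r$product_ids, r$substrate_ids) else r$substrate_ids
  })
  from <- character(0); to <- character(0)
  n_rx <- length(rx)
  if (n_rx >= 2L) {
    for (i in seq_len(n_rx)) {
      for (j in seq_len(n_rx)) {
        if (i == j) next
        if (length(intersect(eff_products[[i]], eff_substrates[[j]])) == 0L) next
        e1 <- intersect(rx[[i]]$enzyme_entry_ids, names(nodes))
        e2 <- intersect(rx[[j]]$enzyme_entry_ids, names(nodes))
        if (length(e1) && length(e2)) {
          pairs <- expand.grid(e1, e2, stringsAsFactors = FALSE)
          from <- c(from, pairs[[1]]); to <- c(to, pairs[[2]])
        }
      }
    }
  }
  for (r in defn$relations) {
    if (!identical(r$relation_type, "ECrel")) next
    src <- resolve_gene_entries(r$entry1_id, defn$entries)
    tgt <- resolve_gene_entries(r$entry2_id, defn$entries)
    if (length(src) && length(tgt)) {
      pairs <- expand.grid(src, tgt, stringsAsFactors = FALSE)
      from <- c(from, pairs[[1]]); to <- c(to, pairs[[2]])
    }
  }
  keep <- from != to
  edges <- cbind(from = from[keep], to = to[keep])
  deduplicate_nodes(new_prs_graph(defn, nodes, edges))
}

#' Merge nodes sharing a gene so each gene appears once per graph
#'
#' All nodes sharing any gene id are merged transitively into one node whose
#' edge set is the union of the originals' in- and out-edges. Duplicate edges
#' are collapsed and self-edges arising from a merge are removed. Every node
#' is (re)named with its lexicographically smallest member gene id, so the
#' operation is idempotent and its output deterministic.
#'
#' @param graph A `prs_graph`, possibly with the same gene in several nodes.
#' @return A deduplicated `prs_graph`.
#' @export
deduplicate_nodes <- function(graph) {
  stopifnot(inherits(graph, "prs_graph"))
  n <- length(graph$nodes)
  if (n == 0L) return(graph)

  # union-find over provisional nodes keyed by shared gene ids
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  gene_owner <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (g in graph$nodes[[i]]$gene_ids) {
      j <- gene_owner[[g]]
      if (is.null(j)) {
        gene_owner[[g]] <- i
      } else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))

  merged <- lapply(split(seq_len(n), root), function(idx) {
    list(
      gene_ids = sort(unique(unlist(lapply(graph$nodes[idx], `[[`, "gene_ids"))),
                      method = "radix"),
      source_entry_ids = sort(unique(unlist(
        lapply(graph$nodes[idx], `[[`, "source_entry_ids"))), method = "radix")
    )
  })
  new_ids <- vapply(merged, function(nd) nd$gene_ids[[1]], character(1))
  names(merged) <- new_ids
  merged <- merged[sort(new_ids, method = "radix")]

  # map old node names to merged ids
  old_names <- names(graph$nodes)
  id_map <- stats::setNames(new_ids[as.character(root)], old_names)

  edges <- graph$edges
  if (nrow(edges) > 0L) {
    from <- unname(id_map[edges[, 1]])
    to <- unname(id_map[edges[, 2]])
    keep <- !is.na(from) & !is.na(to) & from != to
    edges <- unique(cbind(from = from[keep], to = to[keep]))
    ord <- order(edges[, 1], edges[, 2], method = "radix")
    edges <- edges[ord, , drop = FALSE]
  } else {
    edges <- empty_edges()
  }

  out <- graph
  out$nodes <- merged
  out$edges <- edges
  out
}

graph_adjacency <- function(graph) {
  ids <- names(graph$nodes)
  adj <- vector("list", length(ids))
  names(adj) <- ids
  for (i in seq_along(adj)) adj[[i]] <- integer(0)
  if (nrow(graph$edges) > 0L) {
    fi <- match(graph$edges[, 1], ids)
    ti <- match(graph$edges[, 2], ids)
    for (k in seq_along(fi)) adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
  }
  adj
}

# iterative DFS: count significant nodes (indices where sig is TRUE) reachable
# from start through significant intermediates; start itself not counted
dfs_downstream_count <- function(adj, start, sig) {
  visited <- logical(length(adj))
  visited[start] <- TRUE
  stack <- adj[[start]]
  count <- 0L
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (visited[v] || !sig[v]) next
    visited[v] <- TRUE
    count <- count + 1L
    stack <- c(stack, adj[[v]])
  }
  count
}

# variant allowing non-significant intermediates on the path
dfs_downstream_count_any_path <- function(adj, start, sig) {
  visited <- logical(length(adj))
  visited[start] <- TRUE
  stack <- adj[[start]]
  count <- 0L
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (visited[v]) next
    visited[v] <- TRUE
    if (sig[v]) count <- count + 1L
    stack <- c(stack, adj[[v]])
  }
  count
}

#' Count significant downstream nodes of a significant node
#'
#' Returns the number of distinct significant nodes reachable from `node`
#' along directed paths, visiting each node at most once so that loops are
#' counted a single time. By default (`through_nonsignificant = FALSE`) every
#' intermediate vertex on a path must itself be significant: a
#' non-significant node blocks propagation. Setting
#' `through_nonsignificant = TRUE` counts significant nodes reachable along
#' any directed path.
#'
#' @param graph A deduplicated `prs_graph`.
#' @param node A node id present in the graph.
#' @param significant Character vector of significant node ids.
#' @param through_nonsignificant Allow non-significant intermediates
#'   (default `FALSE`).
#' @return Integer count; `node` itself is never counted.
#' @export
downstream_significant_count <- function(graph, node, significant,
                                         through_nonsignificant = FALSE) {
  stopifnot(inherits(graph, "prs_graph"))
  ids <- names(graph$nodes)
  start <- match(node, ids)
  if (is.na(start)) stop("Node '", node, "' not found in graph ",
                         graph$pathway_id, call. = FALSE)
  sig <- ids %in% significant
  adj <- graph_adjacency(graph)
  if (through_nonsignificant) {
    dfs_downstream_count_any_path(adj, start, sig)
  } else {
    dfs_downstream_count(adj, start, sig)
  }
}

#' Export a graph as plain-text node and edge tables
#'
#' Writes `<pathway_id>_edges.tsv` (from, to) and `<pathway_id>_nodes.tsv`
#' (node_id, comma-joined gene ids) for debugging.
#'
#' @param graph A `prs_graph`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_graph_tables <- function(graph, dir) {
  stopifnot(inherits(graph, "prs_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ef <- file.path(dir, paste0(graph$pathway_id, "_edges.tsv"))
  nf <- file.path(dir, paste0(graph$pathway_id, "_nodes.tsv"))
  utils::write.table(as.data.frame(graph$edges), ef, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nd <- data.frame(
    node_id = names(graph$nodes),
    gene_ids = vapply(graph$nodes, function(x) paste(x$gene_ids, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(nd, nf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ef, nf))
}

#' @export
print.prs_graph <- function(x, ...) {
  cat("Pathway graph", x$pathway_id, "-", x$title, "\n")
  cat(sprintf("  category: %s; %d nodes, %d edges\n",
              x$category, length(x$nodes), nrow(x$edges)))
  invisible(x)
}
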