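# Shared helpers: inline KGML builders, hand-rolled oracles, toy objects.

kgml_signalling_text <- function(genes, edges, extra = "") {
  entries <- paste0(
    vapply(seq_along(genes), function(i) {
      sprintf('<entry id="%d" name="hsa:%s" type="gene"/>', i, genes[[i]])
    }, ""),
    collapse = ""
  )
  rels <- if (length(edges)) {
    paste0(vapply(edges, function(e) {
      sprintf(paste0('<relation entry1="%d" entry2="%d" type="PPrel">',
                     '<subtype name="activation" value="--&gt;"/></relation>'),
              e[[1]], e[[2]])
    }, ""), collapse = "")
  } else ""
  paste0('<pathway name="path:hsa09999" org="hsa" title="toy">',
         entries, extra, rels, "</pathway>")
}

# graph from an inline signalling KGML: genes a character vector,
# edges a list of c(from_index, to_index)
toy_graph <- function(genes, edges) {
  build_pathway_graph(parse_kgml(kgml_signalling_text(genes, edges)))
}

# gene-level stats object with prescribed fold-change magnitudes and flags
toy_stats <- function(gene_ids, fc_magnitude, significant,
                      p_value = ifelse(significant, 0.001, 0.5)) {
  structure(
    list(
      stats = data.frame(
        gene_id = gene_ids,
        probe_id = sprintf("P%d", seq_along(gene_ids)),
        log2_fc = log2(fc_magnitude),
        fc_magnitude = fc_magnitude,
        p_value = p_value,
        significant = significant,
        stringsAsFactors = FALSE
      ),
      universe = list(T = length(gene_ids), F = sum(significant)),
      fc_threshold = 1.3, p_threshold = 0.05
    ),
    class = "prs_gene_stats"
  )
}

# a bare graph object (single-gene nodes) for property tests
bare_graph <- function(node_ids, edge_mat) {
  nodes <- lapply(node_ids, function(id) {
    list(gene_ids = id, source_entry_ids = id)
  })
  names(nodes) <- node_ids
  if (is.null(edge_mat) || nrow(edge_mat) == 0L) {
    edges <- matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))
  } else {
    edges <- cbind(from = node_ids[edge_mat[, 1]],
                   to = node_ids[edge_mat[, 2]])
  }
  structure(
    list(pathway_id = "toy", title = "toy", category = "signalling",
         nodes = nodes, edges = edges),
    class = "prs_graph"
  )
}

random_edge_mat <- function(k, density) {
  pairs <- expand.grid(from = seq_len(k), to = seq_len(k))
  pairs <- as.matrix(pairs[pairs$from != pairs$to, ])
  pairs[stats::runif(nrow(pairs)) < density, , drop = FALSE]
}

# independent oracle: brute-force transitive closure on the subgraph induced
# by {start} union significant, via boolean matrix products
oracle_downstream <- function(graph, start, significant) {
  ids <- names(graph$nodes)
  k <- length(ids)
  A <- matrix(FALSE, k, k, dimnames = list(ids, ids))
  if (nrow(graph$edges) > 0L) {
    A[cbind(graph$edges[, 1], graph$edges[, 2])] <- TRUE
  }
  allowed <- ids %in% c(start, significant)
  A[!allowed, ] <- FALSE
  A[, !allowed] <- FALSE
  reach <- A
  repeat {
    nxt <- reach | ((reach %*% A) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  sum(reach[start, ] & ids %in% significant & ids != start)
}

# independent BH step-up implementation
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# independent evaluation of the hypergeometric-variance z
oracle_zscore <- function(n, f, T_total, F_total) {
  p <- F_total / T_total
  (f - n * p) / sqrt(n * p * (1 - p) * (1 - (n - 1) / (T_total - 1)))
}
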