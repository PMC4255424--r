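#' Assess pathway nodes against gene-level statistics
#'
#' A node is significant iff any of its member genes is significant; its
#' fold-change magnitude is the maximum over its significant member genes
#' (1.0 when none). Significant nodes are weighted by
#' `1 + downstream_significant_count`, i.e. one for the node itself plus the
#' number of distinct significant nodes it points to directly or via other
#' significant nodes; non-significant nodes get weight 0.
#'
#' @param graph A deduplicated `prs_graph`.
#' @param stats A `prs_gene_stats` object from [gene_stats()].
#' @param through_nonsignificant Passed to [downstream_significant_count()].
#' @return Data frame with columns `node_id`, `significant`, `fc_magnitude`,
#'   `weight`.
#' @export
assess_nodes <- function(graph, stats, through_nonsignificant = FALSE) {
  stopifnot(inherits(graph, "prs_graph"), inherits(stats, "prs_gene_stats"))
  st <- stats$stats
  prep <- prepare_graph_index(graph, st$gene_id)
  res <- node_assessments(prep, st$significant, st$fc_magnitude,
                          through_nonsignificant)
  data.frame(
    node_id = names(graph$nodes),
    significant = res$sig,
    fc_magnitude = res$fc,
    weight = res$weight,
    stringsAsFactors = FALSE
  )
}

# Precompute, for one graph, the adjacency (integer index lists) and each
# node's member-gene positions in the gene-stats table. Shared by scoring and
# the permutation loop, where it is the hot path.
prepare_graph_index <- function(graph, universe_gene_ids) {
  ids <- names(graph$nodes)
  gidx <- lapply(graph$nodes, function(nd) {
    idx <- match(nd$gene_ids, universe_gene_ids)
    idx[!is.na(idx)]
  })
  list(
    pathway_id = graph$pathway_id,
    title = graph$title,
    node_ids = ids,
    node_count = length(ids),
    adj = graph_adjacency(graph),
    gene_idx = gidx,
    n_expressed = sum(vapply(gidx, length, integer(1)) > 0L)
  )
}

# node-level significance, fold-change and weights given gene-level vectors
node_assessments <- function(prep, gene_sig, gene_fc,
                             through_nonsignificant = FALSE) {
  k <- prep$node_count
  sig <- logical(k)
  fc <- rep(1, k)
  for (i in seq_len(k)) {
    gi <- prep$gene_idx[[i]]
    if (length(gi)) {
      s <- gene_sig[gi]
      if (any(s)) {
        sig[i] <- TRUE
        fc[i] <- max(gene_fc[gi][s])
      }
    }
  }
  weight <- integer(k)
  dfs <- if (through_nonsignificant) {
    dfs_downstream_count_any_path
  } else {
    dfs_downstream_count
  }
  for (i in which(sig)) {
    weight[i] <- 1L + dfs(prep$adj, i, sig)
  }
  list(sig = sig, fc = fc, weight = weight)
}

prs_from_assessment <- function(res, node_count) {
  raw <- sum(res$fc[res$sig] * res$weight[res$sig])
  list(prs_raw = raw, prs = raw / node_count)
}

#' Pathway Regulation Score from node assessments
#'
#' `prs_raw` is the sum over significant nodes of fold-change magnitude times
#' topological weight; `prs` divides by the deduplicated node count,
#' normalizing for pathway size.
#'
#' @param assessments Data frame from [assess_nodes()].
#' @param node_count Number of nodes in the deduplicated graph (> 0).
#' @return List with `prs_raw` and `prs`.
#' @export
compute_prs <- function(assessments, node_count) {
  stopifnot(node_count > 0)
  sig <- assessments$significant
  raw <- sum(assessments$fc_magnitude[sig] * assessments$weight[sig])
  list(prs_raw = raw, prs = raw / node_count)
}

#' Hypergeometric over-representation z-score
#'
#' Standardized deviation of the observed significant count `f` in a pathway
#' of size `n` from its expectation under sampling without replacement from a
#' universe of `T` genes containing `F` significant ones:
#' \deqn{z = \frac{f - nF/T}{\sqrt{n (F/T)(1 - F/T)(1 - \frac{n-1}{T-1})}}}
#' Counts are taken after redundancy removal (each gene once per pathway).
#'
#' @param n Pathway members in the expressed universe (0 < n < T).
#' @param f Significant pathway members (0 <= f <= n).
#' @param T_total Universe size.
#' @param F_total Significant genes in the universe.
#' @return The z-score, or `NA_real_` when the variance term is zero
#'   (F = 0, F = T or n = T).
#' @export
compute_zscore <- function(n, f, T_total, F_total) {
  stopifnot(n >= 0, f >= 0, f <= n, F_total >= 0, F_total <= T_total,
            T_total > 1)
  if (n == 0 || n >= T_total || F_total == 0 || F_total == T_total) {
    return(NA_real_)
  }
  p <- F_total / T_total
  v <- n * p * (1 - p) * (1 - (n - 1) / (T_total - 1))
  if (v <= 0) return(NA_real_)
  (f - n * p) / sqrt(v)
}

#' Score every pathway by PRS and z-score
#'
#' Empty graphs (zero gene nodes) are excluded. For each remaining pathway,
#' `n` counts graph nodes with at least one gene in the expressed universe,
#' `f` counts significant nodes, `prs_raw`/`prs` follow [compute_prs()] and
#' `z_score` follows [compute_zscore()].
#'
#' @param graphs List of `prs_graph` objects.
#' @param stats A `prs_gene_stats` object.
#' @param through_nonsignificant Passed to [assess_nodes()].
#' @return Data frame (one row per scoreable pathway, ordered by
#'   `pathway_id`): `pathway_id`, `title`, `node_count`, `n`, `f`, `prs_raw`,
#'   `prs`, `z_score`.
#' @export
score_all <- function(graphs, stats, through_nonsignificant = FALSE) {
  stopifnot(inherits(stats, "prs_gene_stats"))
  graphs <- Filter(function(g) length(g$nodes) > 0L, graphs)
  if (length(graphs) == 0L) stop("No scoreable pathway graphs", call. = FALSE)
  st <- stats$stats
  rows <- lapply(graphs, function(g) {
    prep <- prepare_graph_index(g, st$gene_id)
    res <- node_assessments(prep, st$significant, st$fc_magnitude,
                            through_nonsignificant)
    pr <- prs_from_assessment(res, prep$node_count)
    data.frame(
      pathway_id = g$pathway_id,
      title = g$title,
      node_count = prep$node_count,
      n = prep$n_expressed,
      f = sum(res$sig),
      prs_raw = pr$prs_raw,
      prs = pr$prs,
      z_score = compute_zscore(prep$n_expressed, sum(res$sig),
                               stats$universe$T, stats$universe$F),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pathway_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank scored pathways
#'
#' Orders pathways by the chosen score in descending order, ties broken by
#' `pathway_id` so output is deterministic. For the z-score ranking,
#' pathways with an undefined z are placed last and flagged in the
#' `score_defined` column.
#'
#' @param scores Data frame from [score_all()].
#' @param by `"prs"` or `"z_score"`.
#' @return `scores` reordered, with `rank` (1..K) and `score_defined` columns.
#' @export
rank_pathways <- function(scores, by = c("prs", "z_score")) {
  by <- match.arg(by)
  s <- scores[[by]]
  defined <- !is.na(s)
  key <- ifelse(defined, -s, Inf)
  ord <- order(key, scores$pathway_id, method = "radix")
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$score_defined <- defined[ord]
  rownames(out) <- NULL
  out
}
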