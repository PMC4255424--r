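#' Permute gene-level statistics across gene labels
#'
#' Reassigns the multiset of per-gene statistics (fold-change magnitude and
#' significance flag, together with the log2 fold-change and p-value they came
#' from) to the gene IDs by one uniform random permutation. Gene IDs and the
#' universe totals T and F are unchanged, so the permutation randomizes where
#' differential expression lands on the pathways without altering how much of
#' it there is. Uses R's global random number generator; seed with
#' [set.seed()] for reproducibility.
#'
#' @param stats A `prs_gene_stats` object.
#' @return A `prs_gene_stats` object with permuted statistics.
#' @export
permute_gene_stats <- function(stats) {
  stopifnot(inherits(stats, "prs_gene_stats"))
  st <- stats$stats
  if (nrow(st) < 2L) stop("Need at least 2 genes to permute", call. = FALSE)
  perm <- sample.int(nrow(st))
  cols <- c("probe_id", "log2_fc", "fc_magnitude", "p_value", "significant")
  st[cols] <- st[perm, cols]
  out <- stats
  out$stats <- st
  out
}

#' Permutation p-values for pathway regulation scores
#'
#' Estimates, for each pathway, the probability of a PRS at least as high as
#' the observed one by chance: gene-level statistics are permuted across the
#' expressed universe `n_perm` times, the PRS recomputed each time, and the
#' empirical p-value taken as the fraction of permutations meeting or
#' exceeding the observed score. All pathways share the same permutation
#' stream, preserving the cross-pathway correlation of the null. p-values are
#' adjusted by Benjamini-Hochberg FDR ([bh_fdr()]).
#'
#' By default p = exceed_count / n_perm, so a pathway beaten by no permutation
#' reports p = 0; set `add_one = TRUE` for the strictly positive
#' (exceed_count + 1) / (n_perm + 1) estimator.
#'
#' @param graphs List of `prs_graph` objects (empty graphs are skipped).
#' @param stats A `prs_gene_stats` object.
#' @param n_perm Number of permutations (>= 1); 1000 is typical.
#' @param seed Optional integer seed for the permutation stream.
#' @param fdr_threshold Threshold for the `significant_fdr` flag
#'   (default 0.05).
#' @param add_one Use the (count+1)/(n+1) estimator (default `FALSE`).
#' @param through_nonsignificant Passed to the node weighting.
#' @return Data frame, one row per scoreable pathway: `pathway_id`,
#'   `observed_prs`, `n_perm`, `exceed_count`, `p_value`, `q_value`,
#'   `significant_fdr`.
#' @export
permutation_pvalues <- function(graphs, stats, n_perm = 1000, seed = NULL,
                                fdr_threshold = 0.05, add_one = FALSE,
                                through_nonsignificant = FALSE) {
  stopifnot(inherits(stats, "prs_gene_stats"))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  graphs <- Filter(function(g) length(g$nodes) > 0L, graphs)
  if (length(graphs) == 0L) stop("No scoreable pathway graphs", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  st <- stats$stats
  gene_sig <- st$significant
  gene_fc <- st$fc_magnitude
  ng <- length(gene_sig)
  if (ng < 2L) stop("Need at least 2 genes in the universe", call. = FALSE)

  preps <- lapply(graphs, prepare_graph_index, universe_gene_ids = st$gene_id)
  observed <- vapply(preps, function(pp) {
    prs_from_assessment(
      node_assessments(pp, gene_sig, gene_fc, through_nonsignificant),
      pp$node_count
    )$prs
  }, numeric(1))

  exceed <- integer(length(preps))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(ng)
    sig_b <- gene_sig[perm]
    fc_b <- gene_fc[perm]
    for (gi in seq_along(preps)) {
      pp <- preps[[gi]]
      prs_b <- prs_from_assessment(
        node_assessments(pp, sig_b, fc_b, through_nonsignificant),
        pp$node_count
      )$prs
      if (prs_b >= observed[gi]) exceed[gi] <- exceed[gi] + 1L
    }
  }

  p <- if (add_one) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  q <- bh_fdr(p)
  data.frame(
    pathway_id = vapply(preps, `[[`, "", "pathway_id"),
    observed_prs = unname(observed),
    n_perm = as.integer(n_perm),
    exceed_count = exceed,
    p_value = p,
    q_value = q,
    significant_fdr = q < fdr_threshold,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: with p-values sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1. Delegates to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}
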