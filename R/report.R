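#' Write the PRS and z-score ranking tables
#'
#' Produces `prs_ranking.csv` and `zscore_ranking.csv` in `out_dir`, each with
#' columns `rank`, `pathway_id`, `title`, `prs`, `z_score`, `p_value`,
#' `q_value`, `n`, `f`, sorted by the respective score in descending order
#' (ties broken by pathway id). Scores are printed with six decimal places.
#' A JSON run-state file (`run_state.json`) holding the run metadata
#' (thresholds, permutation count, seed, tool version) is written alongside.
#'
#' @param scores Data frame from [score_all()].
#' @param perms Data frame from [permutation_pvalues()], or `NULL` when no
#'   permutation test was run (p/q columns are then `NA`).
#' @param out_dir Output directory, created if needed.
#' @param fdr_filter Optional q-value threshold; when given, only rows with
#'   `q_value < fdr_filter` are kept (ranks are re-numbered 1..K).
#' @param metadata Named list recorded in `run_state.json`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_ranked_tables <- function(scores, perms = NULL, out_dir = ".",
                                fdr_filter = NULL, metadata = list()) {
  stopifnot(nrow(scores) >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tab <- scores
  if (!is.null(perms)) {
    m <- match(tab$pathway_id, perms$pathway_id)
    tab$p_value <- perms$p_value[m]
    tab$q_value <- perms$q_value[m]
  } else {
    tab$p_value <- NA_real_
    tab$q_value <- NA_real_
  }

  make_rows <- function(by) {
    r <- rank_pathways(tab, by = by)
    if (!is.null(fdr_filter)) {
      r <- r[!is.na(r$q_value) & r$q_value < fdr_filter, , drop = FALSE]
      r$rank <- seq_len(nrow(r))
    }
    data.frame(
      rank = r$rank,
      pathway_id = r$pathway_id,
      title = r$title,
      prs = round(r$prs, 6),
      z_score = round(r$z_score, 6),
      p_value = round(r$p_value, 6),
      q_value = round(r$q_value, 6),
      n = r$n,
      f = r$f,
      stringsAsFactors = FALSE
    )
  }

  prs_file <- file.path(out_dir, "prs_ranking.csv")
  z_file <- file.path(out_dir, "zscore_ranking.csv")
  utils::write.csv(make_rows("prs"), prs_file, row.names = FALSE, na = "NA")
  utils::write.csv(make_rows("z_score"), z_file, row.names = FALSE, na = "NA")

  state_file <- file.path(out_dir, "run_state.json")
  state <- c(
    list(tool = "prsenrich",
         version = as.character(utils::packageVersion("prsenrich")),
         n_pathways = nrow(scores)),
    metadata
  )
  jsonlite::write_json(state, state_file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  invisible(c(prs = prs_file, zscore = z_file, state = state_file))
}

#' Build a KEGG colour-map URL for a pathway
#'
#' Constructs the URL of the KEGG pathway-mapping web service
#' (`show_pathway`) with every expressed gene coloured by its significance:
#' red background for significant genes, green for non-significant ones. No
#' network call is made; the function only assembles and returns the string.
#' The gene list is sorted, so the URL is byte-identical for identical
#' inputs.
#'
#' @param pathway_id KEGG pathway id, e.g. `"hsa04010"`; propagated verbatim.
#' @param stats A `prs_gene_stats` object (the expressed universe).
#' @param graph Optional `prs_graph` for the pathway; when supplied, the
#'   function checks that at least one of the pathway's genes is expressed.
#' @param organism Organism prefix for gene identifiers; defaults to the
#'   alphabetic prefix of `pathway_id`.
#' @return The URL as a single string.
#' @export
kegg_color_url <- function(pathway_id, stats, graph = NULL,
                           organism = sub("^([a-z]+).*$", "\\1", pathway_id)) {
  stopifnot(inherits(stats, "prs_gene_stats"))
  st <- stats$stats
  if (nrow(st) == 0L) stop("Empty gene list", call. = FALSE)
  if (!is.null(graph)) {
    path_genes <- unlist(lapply(graph$nodes, `[[`, "gene_ids"))
    if (!any(path_genes %in% st$gene_id)) {
      stop("Pathway ", pathway_id, " has no gene in the expressed universe",
           call. = FALSE)
    }
  }
  ord <- order(st$gene_id, method = "radix")
  genes <- st$gene_id[ord]
  colour <- ifelse(st$significant[ord], "red", "green")
  gene_tok <- if (nzchar(organism)) paste0(organism, ":", genes) else genes
  query <- paste0(gene_tok, "+", colour, collapse = "%0A")
  paste0("https://www.kegg.jp/kegg-bin/show_pathway?map=", pathway_id,
         "&multi_query=", query)
}
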