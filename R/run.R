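#' Configuration for an end-to-end PRS run
#'
#' @param expression Path to the expression table (CSV/TSV/XLSX; first column
#'   probe ID, then control columns followed by test columns).
#' @param mapping Path to the probe-to-gene mapping (2-column text).
#' @param kgml_dir Directory of KGML pathway files.
#' @param n_control,n_test Sample counts per group.
#' @param fc_threshold Fold-change magnitude threshold (default 1.3).
#' @param p_threshold t-test p-value threshold (default 0.05).
#' @param pathway_classes Which pathway classes to score: `"both"`,
#'   `"signalling"` or `"metabolic"`.
#' @param n_perm Number of permutations (default 1000); 0 disables the
#'   permutation test.
#' @param fdr_threshold FDR threshold for the significance flag
#'   (default 0.05).
#' @param fdr_filter_output Keep only FDR-significant rows in the ranking
#'   tables (default `FALSE`: all pathways are reported).
#' @param log2_scale Expression values are log2-scale (default `TRUE`).
#' @param seed Integer seed for the permutation stream.
#' @param out_dir Output directory.
#' @return A `prs_run_config` list.
#' @export
run_config <- function(expression, mapping, kgml_dir, n_control, n_test,
                       fc_threshold = 1.3, p_threshold = 0.05,
                       pathway_classes = c("both", "signalling", "metabolic"),
                       n_perm = 1000, fdr_threshold = 0.05,
                       fdr_filter_output = FALSE, log2_scale = TRUE,
                       seed = 1, out_dir = "results") {
  pathway_classes <- match.arg(pathway_classes)
  stopifnot(fc_threshold >= 1, p_threshold > 0, p_threshold <= 1,
            n_perm >= 0, fdr_threshold > 0, fdr_threshold <= 1)
  for (p in c(expression, mapping, kgml_dir)) {
    if (!file.exists(p)) stop("Input path does not exist: ", p, call. = FALSE)
  }
  structure(
    list(expression = expression, mapping = mapping, kgml_dir = kgml_dir,
         n_control = n_control, n_test = n_test,
         fc_threshold = fc_threshold, p_threshold = p_threshold,
         pathway_classes = pathway_classes, n_perm = n_perm,
         fdr_threshold = fdr_threshold,
         fdr_filter_output = fdr_filter_output,
         log2_scale = log2_scale, seed = as.integer(seed), out_dir = out_dir),
    class = "prs_run_config"
  )
}

#' Run the full PRS enrichment workflow
#'
#' Parses every KGML file in the configured directory, filters by pathway
#' class, builds and deduplicates the gene graphs, computes gene-level
#' differential expression, scores each pathway by PRS and z-score, assesses
#' significance by fold-change permutation with BH-FDR correction, and writes
#' the two ranking tables plus `run_state.json` and `run.log` to the output
#' directory. Stage counts (pathways parsed, class-filtered, excluded as
#' empty, genes mapped, DEGs) are logged and returned.
#'
#' @param config A `prs_run_config` from [run_config()].
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with `scores`, `perms`, `files`, `counts` and
#'   `graphs`.
#' @export
prs_run <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "prs_run_config"))
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  say("[kgml] parsing directory: ", config$kgml_dir)
  defs <- parse_kgml_dir(config$kgml_dir)
  n_parsed <- length(defs)
  say("[kgml] pathways parsed: ", n_parsed)

  if (config$pathway_classes != "both") {
    keep <- vapply(defs, function(d) d$category == config$pathway_classes,
                   logical(1))
    defs <- defs[keep]
  }
  n_class_filtered <- n_parsed - length(defs)
  say("[kgml] excluded by class filter (", config$pathway_classes, "): ",
      n_class_filtered)
  if (length(defs) == 0L) {
    stop("[kgml] no pathways of class '", config$pathway_classes,
         "' in ", config$kgml_dir, call. = FALSE)
  }

  graphs <- withCallingHandlers(
    lapply(defs, build_pathway_graph),
    warning = function(w) {
      say("[graph] ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  nonempty <- vapply(graphs, function(g) length(g$nodes) > 0L, logical(1))
  n_excluded_empty <- sum(!nonempty)
  graphs <- graphs[nonempty]
  say("[graph] excluded empty graphs: ", n_excluded_empty)
  if (length(graphs) == 0L) {
    stop("[graph] zero scoreable pathways after graph construction",
         call. = FALSE)
  }

  say("[expression] loading: ", config$expression)
  expr <- load_expression(config$expression, config$n_control, config$n_test)
  mapping <- load_mapping(config$mapping)
  stats <- gene_stats(expr, mapping,
                      fc_threshold = config$fc_threshold,
                      p_threshold = config$p_threshold,
                      log2_scale = config$log2_scale)
  say("[expression] genes mapped: ", stats$universe$T,
      "; DEGs: ", stats$universe$F)

  scores <- score_all(graphs, stats)
  say("[scoring] pathways scored: ", nrow(scores))

  perms <- NULL
  if (config$n_perm >= 1) {
    say("[significance] permutations: ", config$n_perm,
        " (seed ", config$seed, ")")
    perms <- permutation_pvalues(graphs, stats, n_perm = config$n_perm,
                                 seed = config$seed,
                                 fdr_threshold = config$fdr_threshold)
    say("[significance] pathways with q < ", config$fdr_threshold, ": ",
        sum(perms$significant_fdr))
  }

  files <- write_ranked_tables(
    scores, perms, config$out_dir,
    fdr_filter = if (config$fdr_filter_output) config$fdr_threshold else NULL,
    metadata = list(
      fc_threshold = config$fc_threshold, p_threshold = config$p_threshold,
      pathway_classes = config$pathway_classes, n_perm = config$n_perm,
      fdr_threshold = config$fdr_threshold, seed = config$seed,
      n_control = config$n_control, n_test = config$n_test,
      pathways_parsed = n_parsed, class_filtered = n_class_filtered,
      excluded_empty = n_excluded_empty, pathways_scored = nrow(scores),
      genes_mapped = stats$universe$T, degs = stats$universe$F
    )
  )
  say("[report] wrote: ", paste(basename(files), collapse = ", "))

  log_file <- file.path(config$out_dir, "run.log")
  writeLines(log_lines, log_file)

  counts <- list(pathways_parsed = n_parsed,
                 class_filtered = n_class_filtered,
                 excluded_empty = n_excluded_empty,
                 pathways_scored = nrow(scores),
                 genes_mapped = stats$universe$T,
                 degs = stats$universe$F)
  invisible(list(scores = scores, perms = perms, stats = stats,
                 graphs = graphs, files = c(files, log = log_file),
                 counts = counts))
}
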