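#' Specification for a synthetic fixture set
#'
#' Bundles the knobs controlling the synthetic pathway and expression
#' generators. Defaults describe a small but realistic study: 30 pathways of
#' 8-12 genes each, a 5 vs 5 replicate design, log2-scale intensities with
#' baseline uniform in \[4, 12\] (the typical RMA range) and replicate noise
#' of 0.5 log2 units. When `planted_pathway_index` is set, the corresponding
#' pathway receives a planted differential-expression signal: a fraction
#' `planted_fraction` of its genes is shifted by `log2(planted_fc)` in the
#' test group.
#'
#' @param n_pathways Number of pathways to generate.
#' @param nodes_min,nodes_max Range of genes (nodes) per pathway.
#' @param topology One of `"chain"`, `"cycle"`, `"random_dag"`,
#'   `"random_digraph"`, `"metabolic_chain"`.
#' @param edge_prob Edge probability for the random topologies.
#' @param planted_pathway_index 1-based index of the pathway receiving the
#'   planted signal, or `NULL` for a null dataset.
#' @param planted_fraction Fraction of the planted pathway's genes made
#'   differentially expressed.
#' @param planted_fc Fold-change magnitude of the planted effect.
#' @param n_control,n_test Replicates per group.
#' @param noise_sd Per-sample noise standard deviation, log2 units.
#' @param probes_per_gene_max Probes per gene drawn uniformly from
#'   `1:probes_per_gene_max`.
#' @param unmapped_fraction Fraction of additional probes left out of the
#'   probe-to-gene mapping (exercises the unmapped-probe path).
#' @param organism Organism prefix used in the KGML files.
#' @param variants Include the three structural test variants (a duplicated
#'   gene entry, a 3-cycle, a group entry) among the pathways.
#' @param seed Integer seed fixing all randomness of the generators.
#' @return A `prs_fixture_spec` list.
#' @export
fixture_spec <- function(n_pathways = 30, nodes_min = 8, nodes_max = 12,
                         topology = c("random_digraph", "chain", "cycle",
                                      "random_dag", "metabolic_chain"),
                         edge_prob = 0.3,
                         planted_pathway_index = NULL, planted_fraction = 0.8,
                         planted_fc = 2, n_control = 5, n_test = 5,
                         noise_sd = 0.5, probes_per_gene_max = 2,
                         unmapped_fraction = 0.05, organism = "hsa",
                         variants = TRUE, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(n_pathways >= 1, nodes_min >= 2, nodes_max >= nodes_min,
            edge_prob >= 0, edge_prob <= 1,
            planted_fraction >= 0, planted_fraction <= 1,
            planted_fc >= 1, n_control >= 2, n_test >= 2, noise_sd > 0,
            probes_per_gene_max >= 1,
            unmapped_fraction >= 0, unmapped_fraction < 1)
  if (!is.null(planted_pathway_index)) {
    stopifnot(planted_pathway_index >= 1, planted_pathway_index <= n_pathways)
  }
  structure(
    list(n_pathways = n_pathways, nodes_min = nodes_min, nodes_max = nodes_max,
         topology = topology, edge_prob = edge_prob,
         planted_pathway_index = planted_pathway_index,
         planted_fraction = planted_fraction, planted_fc = planted_fc,
         n_control = n_control, n_test = n_test, noise_sd = noise_sd,
         probes_per_gene_max = probes_per_gene_max,
         unmapped_fraction = unmapped_fraction, organism = organism,
         variants = variants, seed = as.integer(seed)),
    class = "prs_fixture_spec"
  )
}

# edges (two-column integer matrix) for one synthetic topology
synth_edges <- function(topology, k, edge_prob) {
  switch(
    topology,
    chain = cbind(seq_len(k - 1), seq_len(k - 1) + 1L),
    cycle = rbind(cbind(seq_len(k - 1), seq_len(k - 1) + 1L), c(k, 1L)),
    random_dag = {
      pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
      pairs[stats::runif(nrow(pairs)) < edge_prob, , drop = FALSE]
    },
    random_digraph = {
      pairs <- expand.grid(from = seq_len(k), to = seq_len(k))
      pairs <- as.matrix(pairs[pairs$from != pairs$to, ])
      pairs[stats::runif(nrow(pairs)) < edge_prob, , drop = FALSE]
    },
    stop("Unknown topology: ", topology)
  )
}

# assemble a prs_pathway object for a synthetic signalling pathway
synth_signalling_defn <- function(kegg_id, title, organism, gene_ids, edges,
                                  duplicate_gene = FALSE, group_entry = FALSE) {
  k <- length(gene_ids)
  entries <- lapply(seq_len(k), function(i) {
    list(entry_id = as.character(i), entry_type = "gene",
         gene_ids = gene_ids[[i]], component_ids = character(0),
         display_name = paste0("G", gene_ids[[i]]),
         reaction_names = character(0))
  })
  relations <- lapply(seq_len(nrow(edges)), function(i) {
    list(entry1_id = as.character(edges[i, 1]),
         entry2_id = as.character(edges[i, 2]),
         relation_type = "PPrel", subtypes = "activation")
  })
  if (duplicate_gene && k >= 2) {
    # same gene in a second entry, wired to node 2: dedup must fold it away
    dup_id <- as.character(k + 1L)
    entries <- c(entries, list(list(
      entry_id = dup_id, entry_type = "gene", gene_ids = gene_ids[[1]],
      component_ids = character(0),
      display_name = paste0("G", gene_ids[[1]], "_dup"),
      reaction_names = character(0)
    )))
    relations <- c(relations, list(list(
      entry1_id = dup_id, entry2_id = "2",
      relation_type = "PPrel", subtypes = "activation"
    )))
  }
  if (group_entry && k >= 3) {
    grp_id <- as.character(length(entries) + 1L)
    entries <- c(entries, list(list(
      entry_id = grp_id, entry_type = "group", gene_ids = character(0),
      component_ids = c("1", "2"), display_name = "complex",
      reaction_names = character(0)
    )))
    relations <- c(relations, list(list(
      entry1_id = "3", entry2_id = grp_id,
      relation_type = "PPrel", subtypes = "activation"
    )))
  }
  names(entries) <- vapply(entries, `[[`, "", "entry_id")
  defn <- structure(
    list(kegg_id = kegg_id, title = title, organism = organism,
         entries = entries, relations = relations, reactions = list(),
         category = "signalling"),
    class = "prs_pathway"
  )
  defn
}

# metabolic chain: reaction R_i converts C_i -> C_{i+1}, catalysed by enzyme i
synth_metabolic_defn <- function(kegg_id, title, organism, gene_ids) {
  k <- length(gene_ids)
  entries <- lapply(seq_len(k), function(i) {
    list(entry_id = as.character(i), entry_type = "gene",
         gene_ids = gene_ids[[i]], component_ids = character(0),
         display_name = paste0("E", gene_ids[[i]]),
         reaction_names = paste0("rn:R", kegg_id, "_", i))
  })
  reactions <- lapply(seq_len(k), function(i) {
    list(reaction_name = paste0("rn:R", kegg_id, "_", i),
         enzyme_entry_ids = as.character(i),
         substrate_ids = paste0("C", kegg_id, "_", i),
         product_ids = paste0("C", kegg_id, "_", i + 1L),
         reversible = FALSE)
  })
  names(entries) <- vapply(entries, `[[`, "", "entry_id")
  structure(
    list(kegg_id = kegg_id, title = title, organism = organism,
         entries = entries, relations = list(), reactions = reactions,
         category = "metabolic"),
    class = "prs_pathway"
  )
}

#' Generate a set of synthetic KGML pathway files
#'
#' Writes `n_pathways` syntactically valid KGML files to `dir`, each holding
#' one pathway over its own disjoint gene set. With `variants = TRUE` (and a
#' compatible topology) pathway 1 additionally duplicates its first gene in a
#' second entry, pathway 2 is forced to a cycle topology, and pathway 3
#' carries a group entry — exercising deduplication, loop handling and group
#' expansion downstream.
#'
#' @param spec A `prs_fixture_spec` from [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `files`, `pathway_ids` and `gene_sets`
#'   (named list: pathway id -> character vector of gene ids).
#' @export
make_kgml_fixtures <- function(spec, dir) {
  stopifnot(inherits(spec, "prs_fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  files <- character(spec$n_pathways)
  gene_sets <- vector("list", spec$n_pathways)
  pathway_ids <- character(spec$n_pathways)
  for (i in seq_len(spec$n_pathways)) {
    k <- sample(seq(spec$nodes_min, spec$nodes_max), 1)
    kegg_id <- sprintf("%s9%04d", spec$organism, i)
    title <- sprintf("Synthetic pathway %d", i)
    gene_ids <- as.character(100000L + 1000L * i + seq_len(k))
    if (identical(spec$topology, "metabolic_chain")) {
      defn <- synth_metabolic_defn(kegg_id, title, spec$organism, gene_ids)
    } else {
      use_variants <- isTRUE(spec$variants)
      topo <- spec$topology
      if (use_variants && i == 2L) topo <- "cycle"
      edges <- synth_edges(topo, k, spec$edge_prob)
      defn <- synth_signalling_defn(
        kegg_id, title, spec$organism, gene_ids, edges,
        duplicate_gene = use_variants && i == 1L,
        group_entry = use_variants && i == 3L
      )
    }
    files[i] <- file.path(dir, paste0(kegg_id, ".xml"))
    write_kgml(defn, files[i])
    gene_sets[[i]] <- gene_ids
    pathway_ids[i] <- kegg_id
  }
  names(gene_sets) <- pathway_ids
  invisible(list(files = files, pathway_ids = pathway_ids,
                 gene_sets = gene_sets))
}

#' Simulate a normalized expression dataset over fixture gene sets
#'
#' Each gene receives a baseline intensity uniform in \[4, 12\] log2 units and
#' 1 to `probes_per_gene_max` probes; every probe value is baseline plus
#' Gaussian noise of `noise_sd` log2 units per sample. If the spec names a
#' planted pathway, `planted_fraction` of its genes have `log2(planted_fc)`
#' added to their test-group mean. A configurable fraction of extra probes is
#' generated without a mapping row. Deterministic given the spec's seed.
#'
#' @param spec A `prs_fixture_spec`.
#' @param gene_sets Named list of gene-id vectors as returned by
#'   [make_kgml_fixtures()].
#' @return List with `expr` (a `prs_expression`), `mapping` (data frame
#'   `probe_id`, `gene_id`) and `planted_genes` (character vector, possibly
#'   empty).
#' @export
simulate_expression <- function(spec, gene_sets) {
  stopifnot(inherits(spec, "prs_fixture_spec"))
  set.seed(spec$seed + 1L)
  genes <- unique(unlist(gene_sets, use.names = FALSE))
  planted_genes <- character(0)
  if (!is.null(spec$planted_pathway_index)) {
    pg <- gene_sets[[spec$planted_pathway_index]]
    n_pl <- round(spec$planted_fraction * length(pg))
    planted_genes <- sort(sample(pg, n_pl))
  }
  n_probes_per_gene <- sample.int(spec$probes_per_gene_max,
                                  length(genes), replace = TRUE)
  gene_per_probe <- rep(genes, n_probes_per_gene)
  n_mapped <- length(gene_per_probe)
  n_unmapped <- round(spec$unmapped_fraction * n_mapped)
  n_total <- n_mapped + n_unmapped
  probe_ids <- sprintf("P%06d", seq_len(n_total))

  n_samples <- spec$n_control + spec$n_test
  baseline_gene <- stats::setNames(stats::runif(length(genes), 4, 12), genes)
  baseline <- c(baseline_gene[gene_per_probe],
                stats::runif(n_unmapped, 4, 12))
  vals <- matrix(stats::rnorm(n_total * n_samples, mean = 0,
                              sd = spec$noise_sd),
                 nrow = n_total, ncol = n_samples)
  vals <- vals + baseline
  if (length(planted_genes)) {
    shift_rows <- which(gene_per_probe %in% planted_genes)
    test_cols <- spec$n_control + seq_len(spec$n_test)
    vals[shift_rows, test_cols] <- vals[shift_rows, test_cols] +
      log2(spec$planted_fc)
  }
  colnames(vals) <- c(paste0("ctrl", seq_len(spec$n_control)),
                      paste0("test", seq_len(spec$n_test)))
  rownames(vals) <- probe_ids

  list(
    expr = expression_matrix(vals, spec$n_control, spec$n_test),
    mapping = data.frame(probe_id = probe_ids[seq_len(n_mapped)],
                         gene_id = gene_per_probe,
                         stringsAsFactors = FALSE),
    planted_genes = planted_genes
  )
}

#' Write a complete demo workspace to disk
#'
#' Generates the KGML fixture files, the simulated expression table
#' (`expression.csv`) and the probe mapping (`mapping.tsv`) under `dir`,
#' ready for an end-to-end [prs_run()].
#'
#' @param dir Workspace directory (created if needed).
#' @param spec A `prs_fixture_spec`; the default plants a signal in
#'   pathway 1.
#' @return Invisibly, a list with `kgml_dir`, `expression`, `mapping`,
#'   `gene_sets`, `planted_genes` and the `spec` used.
#' @export
make_demo_workspace <- function(dir,
                                spec = fixture_spec(planted_pathway_index = 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kgml_dir <- file.path(dir, "kgml")
  fx <- make_kgml_fixtures(spec, kgml_dir)
  sim <- simulate_expression(spec, fx$gene_sets)

  expr_file <- file.path(dir, "expression.csv")
  df <- data.frame(probe_id = sim$expr$probe_ids,
                   sim$expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, expr_file, row.names = FALSE)

  map_file <- file.path(dir, "mapping.tsv")
  utils::write.table(sim$mapping, map_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  invisible(list(kgml_dir = kgml_dir, expression = expr_file,
                 mapping = map_file, gene_sets = fx$gene_sets,
                 planted_genes = sim$planted_genes, spec = spec))
}
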