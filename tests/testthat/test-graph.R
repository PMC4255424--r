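test_that("signalling chain and cycle build the expected edges", {
  g <- toy_graph(c("1", "2", "3"), list(c(1, 2), c(2, 3)))
  expect_length(g$nodes, 3)
  expect_identical(unname(g$edges),
                   matrix(c("1", "2", "2", "3"), 2, byrow = TRUE))
  # cycle preserved
  g2 <- toy_graph(c("1", "2"), list(c(1, 2), c(2, 1)))
  expect_length(g2$nodes, 2)
  expect_identical(nrow(g2$edges), 2L)
})

test_that("relations touching a group fan out to all gene components", {
  xml <- paste0(
    '<pathway name="path:hsa09996" org="hsa" title="grp">',
    '<entry id="1" name="hsa:9" type="gene"/>',
    '<entry id="2" name="hsa:5" type="gene"/>',
    '<entry id="3" name="hsa:6" type="gene"/>',
    '<entry id="4" name="undefined" type="group">',
    '<component id="2"/><component id="3"/></entry>',
    '<relation entry1="1" entry2="4" type="PPrel"/></pathway>'
  )
  g <- build_pathway_graph(parse_kgml(xml))
  expect_length(g$nodes, 3)
  expect_setequal(paste(g$edges[, 1], g$edges[, 2]), c("9 5", "9 6"))
})

test_that("relations to or from map/compound entries are dropped", {
  xml <- paste0(
    '<pathway name="path:hsa09995" org="hsa" title="mx">',
    '<entry id="1" name="hsa:7" type="gene"/>',
    '<entry id="2" name="path:hsa00010" type="map"/>',
    '<relation entry1="1" entry2="2" type="maplink"/></pathway>'
  )
  g <- build_pathway_graph(parse_kgml(xml))
  expect_length(g$nodes, 1)
  expect_identical(nrow(g$edges), 0L)
})

test_that("pathway with zero gene entries yields an empty graph with warning", {
  xml <- paste0(
    '<pathway name="path:hsa09994" org="hsa" title="empty">',
    '<entry id="1" name="cpd:C1" type="compound"/></pathway>'
  )
  expect_warning(g <- build_pathway_graph(parse_kgml(xml)), "no gene entries")
  expect_length(g$nodes, 0)
})

metabolic_text <- function(reactions) {
  # reactions: list of list(id, gene, subs, prods, rev)
  entries <- paste0(vapply(reactions, function(r) {
    sprintf('<entry id="%s" name="hsa:%s" type="gene" reaction="rn:R%s"/>',
            r$id, r$gene, r$id)
  }, ""), collapse = "")
  rx <- paste0(vapply(reactions, function(r) {
    paste0(
      sprintf('<reaction id="%s" name="rn:R%s" type="%s">',
              r$id, r$id, if (isTRUE(r$rev)) "reversible" else "irreversible"),
      paste0(sprintf('<substrate id="s%s" name="cpd:%s"/>', r$subs, r$subs),
             collapse = ""),
      paste0(sprintf('<product id="p%s" name="cpd:%s"/>', r$prods, r$prods),
             collapse = ""),
      "</reaction>"
    )
  }, ""), collapse = "")
  paste0('<pathway name="path:hsa09993" org="hsa" title="met">',
         entries, rx, "</pathway>")
}

test_that("metabolic product-substrate chaining orients edges", {
  # R1: C1 -> C2 by E1; R2: C2 -> C3 by E2  =>  E1 -> E2
  g <- build_pathway_graph(parse_kgml(metabolic_text(list(
    list(id = "1", gene = "101", subs = "C1", prods = "C2"),
    list(id = "2", gene = "102", subs = "C2", prods = "C3")
  ))))
  expect_length(g$nodes, 2)
  expect_identical(unname(g$edges), matrix(c("101", "102"), 1))
})

test_that("reversible reactions chain through both compound lists", {
  # R1 reversible C1 <-> C2 by E1; R2: C2 -> C3 by E2: exactly one edge E1->E2
  g <- build_pathway_graph(parse_kgml(metabolic_text(list(
    list(id = "1", gene = "101", subs = "C1", prods = "C2", rev = TRUE),
    list(id = "2", gene = "102", subs = "C2", prods = "C3")
  ))))
  expect_identical(unname(g$edges), matrix(c("101", "102"), 1))
})

test_that("a single reaction with a single enzyme gives one node, no edges", {
  g <- build_pathway_graph(parse_kgml(metabolic_text(list(
    list(id = "1", gene = "101", subs = "C1", prods = "C2")
  ))))
  expect_length(g$nodes, 1)
  expect_identical(nrow(g$edges), 0L)
})

test_that("ECrel relations contribute edges in metabolic graphs", {
  xml <- metabolic_text(list(
    list(id = "1", gene = "101", subs = "C1", prods = "C2"),
    list(id = "2", gene = "102", subs = "C9", prods = "C8")
  ))
  xml <- sub("</pathway>",
             '<relation entry1="2" entry2="1" type="ECrel"/></pathway>', xml)
  g <- build_pathway_graph(parse_kgml(xml))
  expect_identical(unname(g$edges), matrix(c("102", "101"), 1))
})

test_that("deduplication merges nodes sharing a gene with edge union", {
  # gene 5 appears in entries 1 and 3; edges 1->2 and 4->3 must both survive
  xml <- paste0(
    '<pathway name="path:hsa09992" org="hsa" title="dup">',
    '<entry id="1" name="hsa:5" type="gene"/>',
    '<entry id="2" name="hsa:6" type="gene"/>',
    '<entry id="3" name="hsa:5" type="gene"/>',
    '<entry id="4" name="hsa:7" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>',
    '<relation entry1="4" entry2="3" type="PPrel"/></pathway>'
  )
  g <- build_pathway_graph(parse_kgml(xml))
  expect_length(g$nodes, 3)
  expect_setequal(paste(g$edges[, 1], g$edges[, 2]), c("5 6", "7 5"))
})

test_that("merging entries joined by an edge removes the self-edge", {
  xml <- paste0(
    '<pathway name="path:hsa09991" org="hsa" title="self">',
    '<entry id="1" name="hsa:5" type="gene"/>',
    '<entry id="2" name="hsa:5" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/></pathway>'
  )
  g <- build_pathway_graph(parse_kgml(xml))
  expect_length(g$nodes, 1)
  expect_identical(nrow(g$edges), 0L)
})

test_that("deduplication is idempotent and conserves genes and edges", {
  set.seed(404)
  for (rep in 1:20) {
    k <- sample(4:10, 1)
    ids <- sprintf("g%02d", seq_len(k))
    # random duplication: some nodes share genes
    genes <- sample(ids[seq_len(sample(2:k, 1))], k, replace = TRUE)
    em <- random_edge_mat(k, 0.3)
    g <- bare_graph(ids, em)
    for (i in seq_len(k)) g$nodes[[i]]$gene_ids <- genes[[i]]
    d1 <- deduplicate_nodes(g)
    d2 <- deduplicate_nodes(d1)
    expect_identical(d1[c("nodes", "edges")], d2[c("nodes", "edges")])
    # gene set conserved
    expect_setequal(unlist(lapply(d1$nodes, `[[`, "gene_ids")), unique(genes))
    # every pre-merge edge between distinct merged nodes survives
    owner <- function(gn) {
      names(d1$nodes)[vapply(d1$nodes, function(nd) gn %in% nd$gene_ids,
                             logical(1))]
    }
    if (nrow(g$edges) > 0) {
      for (r in seq_len(nrow(g$edges))) {
        from_gene <- genes[match(g$edges[r, 1], ids)]
        to_gene <- genes[match(g$edges[r, 2], ids)]
        mf <- owner(from_gene); mt <- owner(to_gene)
        if (mf != mt) {
          expect_true(any(d1$edges[, 1] == mf & d1$edges[, 2] == mt))
        }
      }
    }
  }
})

test_that("downstream counts follow the significant-intermediates rule", {
  chain <- bare_graph(c("A", "B", "C"),
                      matrix(c(1, 2, 2, 3), 2, byrow = TRUE))
  sig <- c("A", "B", "C")
  expect_identical(downstream_significant_count(chain, "A", sig), 2L)
  expect_identical(downstream_significant_count(chain, "B", sig), 1L)
  expect_identical(downstream_significant_count(chain, "C", sig), 0L)

  cyc <- bare_graph(c("A", "B", "C"),
                    matrix(c(1, 2, 2, 3, 3, 1), 3, byrow = TRUE))
  for (v in c("A", "B", "C")) {
    expect_identical(downstream_significant_count(cyc, v, c("A", "B", "C")), 2L)
  }

  # a non-significant intermediate blocks propagation by default...
  blocked <- bare_graph(c("A", "X", "B"),
                        matrix(c(1, 2, 2, 3), 2, byrow = TRUE))
  expect_identical(downstream_significant_count(blocked, "A", c("A", "B")), 0L)
  # ...unless the any-path variant is requested
  expect_identical(
    downstream_significant_count(blocked, "A", c("A", "B"),
                                 through_nonsignificant = TRUE),
    1L
  )

  expect_error(downstream_significant_count(chain, "Z", sig), "not found")
})

test_that("DFS count equals brute-force closure on random digraphs", {
  set.seed(2024)
  for (rep in 1:200) {
    k <- sample(3:12, 1)
    ids <- sprintf("n%02d", seq_len(k))
    g <- bare_graph(ids, random_edge_mat(k, stats::runif(1, 0.1, 0.5)))
    sig <- sample(ids, sample.int(k, 1))
    start <- sample(sig, 1)
    expect_identical(
      downstream_significant_count(g, start, sig),
      as.integer(oracle_downstream(g, start, sig))
    )
  }
})

test_that("DFS terminates on a fully-connected cyclic graph of 100 nodes", {
  k <- 100
  ids <- sprintf("n%03d", seq_len(k))
  pairs <- expand.grid(from = seq_len(k), to = seq_len(k))
  pairs <- as.matrix(pairs[pairs$from != pairs$to, ])
  g <- bare_graph(ids, pairs)
  expect_identical(downstream_significant_count(g, ids[[1]], ids),
                   as.integer(k - 1))
})

test_that("graph tables export as readable TSV", {
  g <- toy_graph(c("1", "2"), list(c(1, 2)))
  dir <- withr::local_tempdir()
  files <- write_graph_tables(g, dir)
  edges <- read.delim(files[[1]], colClasses = "character")
  expect_identical(edges$from, "1")
  nodes <- read.delim(files[[2]], colClasses = "character")
  expect_setequal(nodes$node_id, c("1", "2"))
})
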