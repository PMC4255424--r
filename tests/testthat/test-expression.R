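write_expr_csv <- function(df, path = withr::local_tempfile(fileext = ".csv"),
                           .local_envir = parent.frame()) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("CSV expression tables load with the declared layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(probe = c("P1", "P2", "P3"),
               c1 = 1:3, c2 = 2:4, t1 = 3:5, t2 = 4:6),
    path, row.names = FALSE
  )
  e <- load_expression(path, 2, 2)
  expect_identical(dim(e$values), c(3L, 4L))
  expect_identical(e$probe_ids, c("P1", "P2", "P3"))

  expect_error(load_expression(path, 2, 3), "value columns")
})

test_that("a text cell in the value block is reported by row and column", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(probe = c("P1", "P2"), c1 = c("1.5", "oops"),
               c2 = c(1, 2), t1 = c(2, 3), t2 = c(2, 4)),
    path, row.names = FALSE
  )
  expect_error(load_expression(path, 2, 2), "row 2, column 'c1'")
})

test_that("mapping loads with header auto-detection and dedup", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tgene_id", "P1\t10", "P2\t20", "P2\t30"), path)
  expect_warning(m <- load_mapping(path), "mapped more than once")
  expect_identical(m$probe_id, c("P1", "P2"))
  expect_identical(m$gene_id, c("10", "20"))
})

make_expr <- function(rows, n_control = 2, n_test = 2) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  expression_matrix(m, n_control, n_test)
}

test_that("fold-change arithmetic on the log2 scale", {
  e <- make_expr(list(P1 = c(3, 3, 4, 4), P2 = c(5, 6, 5, 6)))
  map <- data.frame(probe_id = c("P1", "P2"), gene_id = c("1", "2"))
  st <- gene_stats(e, map, fc_threshold = 1, p_threshold = 0.05)$stats
  expect_equal(st$log2_fc[st$gene_id == "1"], 1)
  expect_equal(st$fc_magnitude[st$gene_id == "1"], 2)
  # identical groups: no change, never significant
  expect_equal(st$log2_fc[st$gene_id == "2"], 0)
  expect_equal(st$fc_magnitude[st$gene_id == "2"], 1)
  expect_false(st$significant[st$gene_id == "2"])
})

test_that("linear-scale input computes fold-change as a ratio of means", {
  e <- make_expr(list(P1 = c(10, 10, 30, 30)))
  map <- data.frame(probe_id = "P1", gene_id = "1")
  st <- gene_stats(e, map, log2_scale = FALSE)$stats
  expect_equal(st$fc_magnitude, 3)
})

test_that("probes collapse to the minimum-p probe per gene", {
  set.seed(9)
  ctrl <- rnorm(4, 5, 0.3)
  e <- make_expr(list(
    P1 = c(ctrl, ctrl + 0.2 + rnorm(4, 0, 0.6)),   # weak, noisy
    P2 = c(ctrl, ctrl + 1.0 + rnorm(4, 0, 0.05))   # strong, clean
  ), n_control = 4, n_test = 4)
  map <- data.frame(probe_id = c("P1", "P2"), gene_id = c("1", "1"))
  st <- gene_stats(e, map)$stats
  # exhaustive comparison of candidate probes via direct Welch tests
  p1 <- t.test(e$values["P1", 5:8], e$values["P1", 1:4])$p.value
  p2 <- t.test(e$values["P2", 5:8], e$values["P2", 1:4])$p.value
  best <- if (p1 < p2) "P1" else "P2"
  expect_identical(nrow(st), 1L)
  expect_identical(st$probe_id, best)
  expect_equal(st$p_value, min(p1, p2))
})

test_that("significance is FC-inclusive and p-strict at the boundary", {
  set.seed(10)
  ctrl <- rnorm(5, 7, 0.1)
  e <- make_expr(list(P1 = c(ctrl, ctrl + 1)), n_control = 5, n_test = 5)
  map <- data.frame(probe_id = "P1", gene_id = "1")
  st0 <- gene_stats(e, map, fc_threshold = 1)$stats
  # threshold set exactly at the observed magnitude: still significant
  st_at <- gene_stats(e, map, fc_threshold = st0$fc_magnitude)$stats
  expect_true(st_at$significant)
  # p threshold exactly at the observed p: strict, so not significant
  st_p <- gene_stats(e, map, fc_threshold = 1, p_threshold = st0$p_value)$stats
  expect_false(st_p$significant)
})

test_that("raising the fold-change threshold never increases F", {
  set.seed(11)
  spec <- fixture_spec(n_pathways = 5, seed = 11)
  dir <- withr::local_tempdir()
  fx <- make_kgml_fixtures(spec, dir)
  sim <- simulate_expression(spec, fx$gene_sets)
  Fs <- vapply(c(1, 1.2, 1.3, 1.5, 2), function(fc) {
    gene_stats(sim$expr, sim$mapping, fc_threshold = fc)$universe$F
  }, numeric(1))
  expect_true(all(diff(Fs) <= 0))
})

test_that("swapping group labels negates log2 fold-changes only", {
  set.seed(12)
  vals <- matrix(rnorm(40, 8, 1), 10, 4)
  rownames(vals) <- sprintf("P%d", 1:10)
  e1 <- expression_matrix(vals, 2, 2)
  e2 <- expression_matrix(vals[, c(3, 4, 1, 2)], 2, 2)
  map <- data.frame(probe_id = rownames(vals), gene_id = as.character(1:10))
  s1 <- gene_stats(e1, map)
  s2 <- gene_stats(e2, map)
  expect_equal(s2$stats$log2_fc, -s1$stats$log2_fc)
  expect_equal(s2$stats$fc_magnitude, s1$stats$fc_magnitude)
  expect_equal(s2$stats$p_value, s1$stats$p_value)
  expect_identical(s2$stats$significant, s1$stats$significant)
})

test_that("null data yield about 5% of probes with p < 0.05", {
  set.seed(13)
  n <- 2000
  vals <- matrix(rnorm(n * 10, 8, 0.5), n, 10)
  rownames(vals) <- sprintf("P%04d", seq_len(n))
  e <- expression_matrix(vals, 5, 5)
  map <- data.frame(probe_id = rownames(vals), gene_id = as.character(seq_len(n)))
  st <- gene_stats(e, map)$stats
  frac <- mean(st$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("degenerate and incomplete probes are handled as documented", {
  e <- make_expr(list(P1 = c(5, 5, 5, 5), P2 = c(1, NA, 2, 2),
                      P3 = c(1, 2, 3, 4)))
  map <- data.frame(probe_id = c("P1", "P2", "P3"),
                    gene_id = c("1", "2", "3"))
  warns <- capture_warnings(st <- gene_stats(e, map))
  expect_match(warns, "zero variance", all = FALSE)
  expect_match(warns, "missing values", all = FALSE)
  expect_identical(st$stats$p_value[st$stats$gene_id == "1"], 1)
  # dropped probe's gene leaves the universe
  expect_identical(st$universe$T, 2L)
  expect_false("2" %in% st$stats$gene_id)
})

test_that("unmapped probes are excluded from the universe", {
  e <- make_expr(list(P1 = c(1, 2, 3, 4), P2 = c(2, 3, 4, 5)))
  map <- data.frame(probe_id = "P1", gene_id = "1")
  st <- gene_stats(e, map)
  expect_identical(st$universe$T, 1L)
  expect_identical(st$stats$gene_id, "1")
})
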