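#' Load a normalized expression table
#'
#' Reads a probes-by-samples table of normalized intensities. The first column
#' must be the probe ID; the remaining columns are replicate expression values
#' with all control samples first, then all test samples. CSV, TSV and XLSX
#' (first sheet, via readxl) are accepted; one header row is expected.
#'
#' @param path File path (`.csv`, `.tsv`/`.txt`, or `.xlsx`).
#' @param n_control,n_test Number of control and test columns; the file must
#'   contain exactly `n_control + n_test` value columns.
#' @return A `prs_expression` object: list with `probe_ids`, `values`
#'   (numeric matrix), `n_control`, `n_test`.
#' @export
load_expression <- function(path, n_control, n_test) {
  stopifnot(n_control >= 2, n_test >= 2)
  ext <- tolower(tools::file_ext(path))
  df <- switch(
    ext,
    csv = utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    tsv = ,
    txt = utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("Reading XLSX requires the readxl package; ",
             "convert the table to CSV/TSV instead", call. = FALSE)
      }
      as.data.frame(readxl::read_excel(path, sheet = 1),
                    check.names = FALSE, stringsAsFactors = FALSE)
    },
    stop("Unsupported expression file extension '.", ext,
         "' (expected csv, tsv, txt or xlsx): ", path, call. = FALSE)
  )
  if (ncol(df) - 1L != n_control + n_test) {
    stop("Expression file ", path, " has ", ncol(df) - 1L,
         " value columns but n_control + n_test = ", n_control + n_test,
         call. = FALSE)
  }
  probe_ids <- as.character(df[[1]])
  if (anyNA(probe_ids) || any(!nzchar(probe_ids))) {
    stop("Missing probe IDs in column 1 of ", path, call. = FALSE)
  }
  vals <- df[-1]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]))
      if (length(bad)) {
        stop("Non-numeric expression value at row ", bad[[1]],
             ", column '", names(vals)[j], "' of ", path, call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- probe_ids
  structure(
    list(probe_ids = probe_ids, values = m,
         n_control = as.integer(n_control), n_test = as.integer(n_test)),
    class = "prs_expression"
  )
}

#' Construct an expression object from an in-memory matrix
#'
#' @param values Numeric matrix, probes x samples, control columns first.
#' @param probe_ids Character vector of probe IDs (defaults to rownames).
#' @param n_control,n_test Group sizes.
#' @return A `prs_expression` object.
#' @export
expression_matrix <- function(values, n_control, n_test,
                              probe_ids = rownames(values)) {
  stopifnot(is.matrix(values), is.numeric(values),
            n_control >= 2, n_test >= 2,
            ncol(values) == n_control + n_test,
            length(probe_ids) == nrow(values))
  rownames(values) <- probe_ids
  structure(
    list(probe_ids = as.character(probe_ids), values = values,
         n_control = as.integer(n_control), n_test = as.integer(n_test)),
    class = "prs_expression"
  )
}

#' Load a probe-to-gene mapping table
#'
#' Two-column whitespace- or tab-delimited text: probe ID, canonical gene ID.
#' A header row is auto-detected when the second field of the first line is
#' non-numeric. A probe may map to at most one gene (later duplicates are
#' dropped with a warning); a gene may have many probes; probes absent from
#' the table remain unmapped.
#'
#' @param path File path.
#' @return Data frame with columns `probe_id` and `gene_id`.
#' @export
load_mapping <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("Mapping file ", path, " needs 2 columns", call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("probe_id", "gene_id")
  if (nrow(df) > 0L && !grepl("^[0-9]+$", df$gene_id[[1]])) {
    df <- df[-1, , drop = FALSE]  # header row
  }
  dup <- duplicated(df$probe_id)
  if (any(dup)) {
    warning(sum(dup), " probes mapped more than once in ", path,
            "; keeping the first gene for each")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

welch_p <- function(test_vals, control_vals) {
  v1 <- stats::var(test_vals); v2 <- stats::var(control_vals)
  if (v1 == 0 && v2 == 0) {
    if (mean(test_vals) == mean(control_vals)) return(list(p = 1, degenerate = TRUE))
    return(list(p = 0, degenerate = FALSE))
  }
  list(p = stats::t.test(test_vals, control_vals, var.equal = FALSE)$p.value,
       degenerate = FALSE)
}

#' Per-gene differential expression statistics
#'
#' Computes, for every mapped probe, the Welch two-sample two-sided t-test
#' p-value and the fold-change between test and control groups, then
#' collapses probes to genes by keeping the probe with the smallest p-value
#' (ties broken by larger absolute log2 fold-change, then lexicographic probe
#' ID). A gene is flagged significant when its fold-change magnitude meets
#' `fc_threshold` (inclusive) and its p-value is strictly below `p_threshold`.
#'
#' Expression values are assumed log2 scale (e.g. RMA output), so the
#' fold-change magnitude is `2^|mean(test) - mean(control)|`; with
#' `log2_scale = FALSE` values are linear and the fold-change is the ratio of
#' group means. Probes with missing values are dropped with a warning. Probes
#' in a degenerate configuration (both groups constant with equal means) get
#' p = 1 with a warning.
#'
#' @param expr A `prs_expression` from [load_expression()] or
#'   [expression_matrix()].
#' @param mapping Data frame from [load_mapping()] (columns `probe_id`,
#'   `gene_id`).
#' @param fc_threshold Fold-change magnitude threshold (ratio >= 1);
#'   default 1.3.
#' @param p_threshold p-value threshold; default 0.05.
#' @param log2_scale Are the intensities log2-scale? Default `TRUE`.
#' @return A `prs_gene_stats` object: list with `stats` (data frame:
#'   `gene_id`, `probe_id`, `log2_fc`, `fc_magnitude`, `p_value`,
#'   `significant`) and `universe` (list `T` = mapped genes, `F` = significant
#'   genes).
#' @export
gene_stats <- function(expr, mapping, fc_threshold = 1.3, p_threshold = 0.05,
                       log2_scale = TRUE) {
  stopifnot(inherits(expr, "prs_expression"),
            fc_threshold >= 1, p_threshold > 0, p_threshold <= 1)
  gene_of <- stats::setNames(mapping$gene_id, mapping$probe_id)
  mapped <- expr$probe_ids %in% names(gene_of)
  if (!any(mapped)) stop("No probe in the expression table is mapped to a gene",
                         call. = FALSE)
  vals <- expr$values[mapped, , drop = FALSE]
  probes <- expr$probe_ids[mapped]

  complete <- stats::complete.cases(vals)
  if (!all(complete)) {
    warning(sum(!complete), " probes dropped due to missing values")
    vals <- vals[complete, , drop = FALSE]
    probes <- probes[complete]
  }
  if (nrow(vals) == 0L) stop("No mapped probes with complete values", call. = FALSE)

  ctrl_cols <- seq_len(expr$n_control)
  test_cols <- expr$n_control + seq_len(expr$n_test)

  n_degenerate <- 0L
  log2_fc <- numeric(nrow(vals))
  p_value <- numeric(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    cv <- vals[i, ctrl_cols]; tv <- vals[i, test_cols]
    if (log2_scale) {
      log2_fc[i] <- mean(tv) - mean(cv)
    } else {
      if (mean(cv) <= 0 || mean(tv) <= 0) {
        stop("Non-positive group mean for probe ", probes[i],
             " with log2_scale = FALSE", call. = FALSE)
      }
      log2_fc[i] <- log2(mean(tv) / mean(cv))
    }
    wp <- welch_p(tv, cv)
    p_value[i] <- wp$p
    if (wp$degenerate) n_degenerate <- n_degenerate + 1L
  }
  if (n_degenerate > 0L) {
    warning(n_degenerate, " probes with zero variance and identical means; p set to 1")
  }

  probe_stats <- data.frame(
    gene_id = unname(gene_of[probes]),
    probe_id = probes,
    log2_fc = log2_fc,
    fc_magnitude = 2^abs(log2_fc),
    p_value = p_value,
    stringsAsFactors = FALSE
  )
  # collapse: best probe per gene = smallest p, then largest |log2FC|,
  # then lexicographic probe id
  ord <- order(probe_stats$p_value, -abs(probe_stats$log2_fc),
               probe_stats$probe_id, method = "radix")
  probe_stats <- probe_stats[ord, , drop = FALSE]
  collapsed <- probe_stats[!duplicated(probe_stats$gene_id), , drop = FALSE]
  collapsed <- collapsed[order(collapsed$gene_id, method = "radix"), , drop = FALSE]
  rownames(collapsed) <- NULL

  collapsed$significant <- collapsed$fc_magnitude >= fc_threshold &
    collapsed$p_value < p_threshold

  structure(
    list(
      stats = collapsed,
      universe = list(T = nrow(collapsed), F = sum(collapsed$significant)),
      fc_threshold = fc_threshold,
      p_threshold = p_threshold
    ),
    class = "prs_gene_stats"
  )
}

#' @export
print.prs_gene_stats <- function(x, ...) {
  cat(sprintf("Gene-level differential expression: %d genes, %d significant\n",
              x$universe$T, x$universe$F))
  cat(sprintf("  thresholds: fold-change >= %g, p < %g\n",
              x$fc_threshold, x$p_threshold))
  invisible(x)
}
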