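#' Read a two-condition expression table
#'
#' Parses a delimited text table (tab or comma, auto-detected from the
#' header line) with a header row, gene identifiers in the first column and
#' one column per replicate. Condition membership comes either from an
#' explicit design table (columns `sample`, `condition` with condition in
#' `control`/`treatment`) or, when `design` is `NULL`, from column-name
#' prefixes: names starting with `c` are control, with `t` treatment.
#'
#' @param path path to the expression table.
#' @param design optional design: a path to a two-column delimited file or a
#'   data frame with columns `sample` and `condition`.
#' @param log2_transform apply log2 to the values after reading (for tables
#'   stored on the raw intensity scale). Off by default: input is assumed
#'   already log-scale.
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, design = NULL, log2_transform = FALSE) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 5L)
    stop_validation("expected a gene-id column plus >= 2 replicates per condition, got %d columns",
                    ncol(tab))
  gene_ids <- as.character(tab[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop_validation("duplicated gene id(s) in %s: %s", path, paste(dup, collapse = ", "))
  samples <- colnames(tab)[-1L]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    bad <- which(apply(is.na(suppressWarnings(apply(vals, 2L, as.numeric))), 1L, any))
    stop_validation("missing or non-numeric cell(s) in %s (data line %s)",
                    path, paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (log2_transform) vals <- log2(vals)

  cond <- resolve_design(samples, design)
  expression_dataset(gene_ids,
                     control = vals[, cond == "control", drop = FALSE],
                     treatment = vals[, cond == "treatment", drop = FALSE])
}

resolve_design <- function(samples, design) {
  if (is.null(design)) {
    cond <- rep(NA_character_, length(samples))
    cond[startsWith(tolower(samples), "c")] <- "control"
    cond[startsWith(tolower(samples), "t")] <- "treatment"
  } else {
    if (is.character(design) && length(design) == 1L) {
      if (!file.exists(design)) stop_validation("design file not found: %s", design)
      header <- readLines(design, n = 1L)
      sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
      design <- utils::read.table(design, header = TRUE, sep = sep,
                                  stringsAsFactors = FALSE)
    }
    if (!all(c("sample", "condition") %in% colnames(design)))
      stop_validation("design needs columns `sample` and `condition`")
    if (!all(design$condition %in% c("control", "treatment")))
      stop_validation("design conditions must be `control` or `treatment`")
    cond <- design$condition[match(samples, design$sample)]
  }
  if (anyNA(cond))
    stop_validation("sample column(s) not assigned to a condition: %s",
                    paste(samples[is.na(cond)], collapse = ", "))
  cond
}

#' Write an expression dataset as a delimited table
#'
#' Inverse of [read_expression_table()]: writes a header row with the gene-id
#' column followed by control columns `c1..` and treatment columns `t1..`.
#'
#' @param data an [expression_dataset()].
#' @param path output path; the delimiter is tab for `.tsv`/anything else,
#'   comma for `.csv`.
#' @export
write_expression_table <- function(data, path) {
  if (!inherits(data, "expression_dataset"))
    stop_validation("`data` must be an expression_dataset")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- data.frame(gene_id = data$gene_ids, data$control, data$treatment,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene_id",
                     sprintf("c%d", seq_len(ncol(data$control))),
                     sprintf("t%d", seq_len(ncol(data$treatment))))
  write_table6(tab, path, sep)
}

# shared writer: header always present, floats at 6 significant digits,
# deterministic column order.
write_table6 <- function(df, path, sep = "\t") {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(signif(x, 6), format = "g", digits = 6))
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_validation("cannot write to %s", path)
  invisible(path)
}

#' Write detection or benchmark results
#'
#' Serialises a [pa_detect()] result, a [test_genes()] per-gene table, or a
#' [run_benchmark()] report to a TSV with a header row, deterministic column
#' order and floating-point values at 6 significant digits.
#'
#' @param result a `detection_result`, a per-gene test data frame, or a
#'   `benchmark_report`.
#' @param path output path.
#' @param wide for benchmark reports only: also write the wide per-metric
#'   rendering next to `path` (suffix `_wide_<metric>.tsv`).
#' @export
write_results <- function(result, path, wide = FALSE) {
  if (inherits(result, "detection_result")) {
    write_table6(as.data.frame(result), path)
  } else if (inherits(result, "benchmark_report")) {
    write_table6(as.data.frame(result), path)
    if (wide) {
      for (met in intersect(c("tpr", "fpr", "tdr"), unique(result$metric))) {
        wpath <- sub("(\\.[a-zA-Z]+)?$", sprintf("_wide_%s.tsv", met), path)
        write_table6(report_wide(result, met), wpath)
      }
    }
  } else if (is.data.frame(result)) {
    write_table6(result, path)
  } else {
    stop_validation("unsupported result type: %s", paste(class(result), collapse = "/"))
  }
  invisible(path)
}

#' Write simulation truth labels
#'
#' Two-column TSV: `gene_id`, `truth` (0/1 indicator of a simulated
#' expression difference).
#'
#' @param sim a `labeled_dataset` from [simulate_dataset()].
#' @param path output path.
#' @export
write_truth <- function(sim, path) {
  if (!inherits(sim, "labeled_dataset"))
    stop_validation("`sim` must be a labeled_dataset")
  write_table6(data.frame(gene_id = sim$data$gene_ids, truth = sim$truth), path)
}
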