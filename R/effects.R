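#' Construct a two-condition expression dataset
#'
#' Bundles a control and a treatment replicate matrix (genes in rows,
#' replicates in columns, log-expression units) with unique gene identifiers.
#' Values are assumed to be already log-transformed and normalised; no
#' transformation is applied here.
#'
#' @param gene_ids character vector of unique gene identifiers, length `n`.
#' @param control numeric matrix, `n` genes x `n_c >= 2` replicates.
#' @param treatment numeric matrix, `n` genes x `n_t >= 2` replicates.
#' @return An object of class `expression_dataset`: a list with elements
#'   `gene_ids`, `control`, `treatment`.
#' @export
expression_dataset <- function(gene_ids, control, treatment) {
  control <- as.matrix(control)
  treatment <- as.matrix(treatment)
  gene_ids <- as.character(gene_ids)
  n <- length(gene_ids)
  if (n < 2L)
    stop_validation("at least 2 genes are required, got %d", n)
  if (anyDuplicated(gene_ids))
    stop_validation("duplicated gene id(s): %s",
                    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (nrow(control) != n || nrow(treatment) != n)
    stop_validation("matrix rows (%d control, %d treatment) do not match the %d gene ids",
                    nrow(control), nrow(treatment), n)
  if (ncol(control) < 2L || ncol(treatment) < 2L)
    stop_validation("each condition needs >= 2 replicates (got n_c = %d, n_t = %d)",
                    ncol(control), ncol(treatment))
  bad_c <- !apply(is.finite(control), 1L, all)
  bad_t <- !apply(is.finite(treatment), 1L, all)
  if (any(bad_c | bad_t))
    stop_validation("non-finite expression value(s) for gene(s): %s",
                    paste(gene_ids[bad_c | bad_t], collapse = ", "))
  structure(list(gene_ids = gene_ids, control = unname(control),
                 treatment = unname(treatment)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes, %d control + %d treatment replicates\n",
              length(x$gene_ids), ncol(x$control), ncol(x$treatment)))
  invisible(x)
}

#' Per-gene mean treatment effects
#'
#' For each gene g computes Y_g = mean(treatment row) - mean(control row),
#' the sampled mean treatment effect on the log scale. The vector of all Y_g
#' is the input to the predictive-interval detector.
#'
#' @param data an [expression_dataset()].
#' @return An object of class `treatment_effects`: list with `gene_ids` and
#'   the numeric vector `y`, in the input gene order.
#' @examples
#' d <- expression_dataset(c("g1", "g2"),
#'                         control = rbind(c(1, 1), c(0, 0)),
#'                         treatment = rbind(c(2, 4), c(0, 0)))
#' compute_treatment_effects(d)$y  # 2, 0
#' @export
compute_treatment_effects <- function(data) {
  if (!inherits(data, "expression_dataset"))
    stop_validation("`data` must be an expression_dataset")
  y <- rowMeans(data$treatment) - rowMeans(data$control)
  structure(list(gene_ids = data$gene_ids, y = y), class = "treatment_effects")
}

#' @export
print.treatment_effects <- function(x, ...) {
  cat(sprintf("treatment_effects: %d genes, y in [%.4g, %.4g]\n",
              length(x$y), min(x$y), max(x$y)))
  invisible(x)
}
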