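#' Score detection calls against ground truth
#'
#' Confusion-matrix rates for one replicate: true positive rate (called
#' among truly differential), false positive rate (called among truly null)
#' and true discovery rate (truly differential among called; the precision).
#' The TDR is `NA` when nothing was called.
#'
#' @param truth 0/1 (or logical) indicator vector, 1 = truly differential;
#'   must contain at least one 0 and one 1.
#' @param called logical (or 0/1) call vector of the same length.
#' @return An object of class `metric_set`: list with `tpr`, `fpr`, `tdr`,
#'   `n_true`, `n_called`.
#' @examples
#' score_calls(c(1, 1, 0, 0), c(TRUE, FALSE, TRUE, FALSE))  # all rates 0.5
#' @export
score_calls <- function(truth, called) {
  truth <- as.integer(truth); called <- as.logical(called)
  if (length(truth) != length(called))
    stop_validation("`truth` (%d) and `called` (%d) lengths differ",
                    length(truth), length(called))
  if (!all(truth %in% 0:1) || anyNA(called))
    stop_validation("`truth` must be 0/1 and `called` logical, no NAs")
  n_true <- sum(truth)
  if (n_true == 0L || n_true == length(truth))
    stop_validation("`truth` must contain at least one 0 and one 1")
  tp <- sum(called & truth == 1L)
  fp <- sum(called & truth == 0L)
  n_called <- sum(called)
  structure(list(tpr = tp / n_true,
                 fpr = fp / (length(truth) - n_true),
                 tdr = if (n_called > 0) tp / n_called else NA_real_,
                 n_true = n_true, n_called = n_called),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("metric_set: TPR %.3f, FPR %.3f, TDR %s (%d true, %d called)\n",
              x$tpr, x$fpr,
              if (is.na(x$tdr)) "NA" else sprintf("%.3f", x$tdr),
              x$n_true, x$n_called))
  invisible(x)
}

#' Monte-Carlo benchmark over a scenario grid
#'
#' For every scenario cell and replicate: simulate one dataset, run each
#' requested method on that same dataset (a paired design, so method
#' contrasts carry reduced Monte-Carlo variance), score against truth, then
#' average over replicates. The TDR mean drops replicates with zero
#' discoveries. Monte-Carlo standard errors are the replicate standard
#' deviation over sqrt(#replicates entering the mean).
#'
#' @param grid a list of [scenario_config()]s (e.g. from [scenario_grid()]),
#'   or a single `scenario_config`.
#' @param methods subset of `c("pa", "tt", "ct", "btt")`.
#' @param alpha working significance / credibility level.
#' @param prior an [nig_prior()] for the `"pa"` method.
#' @param verbose print one line per finished cell.
#' @return A long-format data frame of class `benchmark_report`: one row per
#'   (cell, method, metric) with columns `n`, `n_c`, `n_t`, `p_over`,
#'   `p_under`, `delta`, `gamma`, `n_reps`, `method`, `metric`
#'   (`tpr`/`fpr`/`tdr`), `mean`, `mc_se`, `n_used`.
#' @export
run_benchmark <- function(grid, methods = c("pa", "tt", "ct", "btt"),
                          alpha = 0.05, prior = nig_prior(), verbose = FALSE) {
  if (inherits(grid, "scenario_config")) grid <- list(grid)
  methods <- match.arg(methods, several.ok = TRUE)
  assert_scalar_prob(alpha, "alpha")
  rows <- vector("list", length(grid))
  for (ci in seq_along(grid)) {
    cfg <- grid[[ci]]
    t0 <- proc.time()[["elapsed"]]
    per_rep <- array(NA_real_, dim = c(cfg$n_reps, length(methods), 3L),
                     dimnames = list(NULL, methods, c("tpr", "fpr", "tdr")))
    for (r in seq_len(cfg$n_reps)) {
      sim <- simulate_dataset(cfg, r)
      for (m in methods) {
        res <- test_genes(sim$data, method = m, alpha = alpha, prior = prior)
        ms <- score_calls(sim$truth, res$called)
        per_rep[r, m, ] <- c(ms$tpr, ms$fpr, ms$tdr)
      }
    }
    cell <- data.frame(n = cfg$n, n_c = cfg$n_c, n_t = cfg$n_t,
                       p_over = cfg$p_over, p_under = cfg$p_under,
                       delta = cfg$delta, gamma = cfg$gamma,
                       n_reps = cfg$n_reps)
    out <- do.call(rbind, lapply(methods, function(m) {
      do.call(rbind, lapply(c("tpr", "fpr", "tdr"), function(met) {
        v <- per_rep[, m, met]
        v <- v[!is.na(v)]  # zero-discovery replicates drop out of the TDR mean
        cbind(cell,
              data.frame(method = m, metric = met,
                         mean = if (length(v)) mean(v) else NA_real_,
                         mc_se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
                         n_used = length(v)))
      }))
    }))
    rows[[ci]] <- out
    if (verbose)
      message(sprintf("cell %d/%d (n_c=%d, p=%g+%g%%, delta=%g, gamma=%g): %.1fs",
                      ci, length(grid), cfg$n_c, cfg$p_over, cfg$p_under,
                      cfg$delta, cfg$gamma, proc.time()[["elapsed"]] - t0))
  }
  structure(do.call(rbind, rows), class = c("benchmark_report", "data.frame"))
}

#' Pivot a benchmark report to the wide table layout
#'
#' Renders one metric as a wide table with one row per (gamma, method) and
#' one column per delta, the layout used to eyeball power curves.
#'
#' @param report a `benchmark_report` from [run_benchmark()].
#' @param metric one of `"tpr"`, `"fpr"`, `"tdr"`.
#' @return A data frame with columns `gamma`, `method`, then one `delta_*`
#'   column per distinct delta.
#' @export
report_wide <- function(report, metric = c("tpr", "fpr", "tdr")) {
  metric <- match.arg(metric)
  d <- report[report$metric == metric, , drop = FALSE]
  if (nrow(d) == 0L) stop_validation("report has no rows for metric `%s`", metric)
  deltas <- sort(unique(d$delta))
  keys <- unique(d[, c("gamma", "method")])
  keys <- keys[order(keys$gamma, keys$method), , drop = FALSE]
  wide <- keys
  for (dl in deltas) {
    col <- vapply(seq_len(nrow(keys)), function(i) {
      v <- d$mean[d$gamma == keys$gamma[i] & d$method == keys$method[i] & d$delta == dl]
      if (length(v) == 1L) v else NA_real_
    }, numeric(1))
    wide[[sprintf("delta_%g", dl)]] <- col
  }
  rownames(wide) <- NULL
  wide
}
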