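#' Per-gene baseline tests: Welch t, Cyber-t, Bayesian t
#'
#' Three two-sample tests of a mean difference between the control and
#' treatment replicates of a single gene, all two-sided:
#'
#' * `welch_t_test()`: the unequal-variance t statistic with fractional
#'   Welch--Satterthwaite degrees of freedom.
#' * `cyber_t_test()`: replaces each condition's variance with a Bayesian
#'   shrinkage blend sigma~^2_h = (nu0 sigma0^2 + (n_h - 1) s_h^2) /
#'   (nu0 + n_h - 2), with nu0 = 10 - n_g pseudo-observations (k = 10 rule,
#'   floored at 0 when n_g >= 10) and sigma0^2 = ((n_g - 1)/n_g) s_g^2, the
#'   biased variance of the pooled two-condition values of this gene;
#'   df = nu0 + n_c + n_t - 2.
#' * `bayes_t_test()`: a conjugate posterior-t for the mean difference with
#'   nu0 = n_g and sigma0^2 = s_g^2 (pooled two-condition sample variance);
#'   nu_n sigma_n^2 = nu0 sigma0^2 + (n_c - 1) s_c^2 + (n_t - 1) s_t^2 and
#'   df = nu_n = nu0 + n_c + n_t - 2.
#'
#' All three share the numerator mean(trt) - mean(ctrl); `called` is
#' `p_value < alpha`.
#'
#' @param ctrl,trt numeric replicate vectors, length >= 2 each.
#' @param alpha working significance level.
#' @return A one-row data frame of class `gene_test_result` with columns
#'   `statistic`, `df`, `p_value`, `called`.
#' @name baseline_tests
NULL

finite_pair <- function(ctrl, trt) {
  if (length(ctrl) < 2L || length(trt) < 2L)
    stop_validation("each condition needs >= 2 replicates (got %d and %d)",
                    length(ctrl), length(trt))
  if (!all(is.finite(ctrl)) || !all(is.finite(trt)))
    stop_validation("non-finite replicate values")
}

test_result <- function(statistic, df, alpha) {
  p <- 2 * stats::pt(-abs(statistic), df = df)
  structure(data.frame(statistic = statistic, df = df, p_value = p,
                       called = p < alpha),
            class = c("gene_test_result", "data.frame"))
}

#' @rdname baseline_tests
#' @export
welch_t_test <- function(ctrl, trt, alpha = 0.05) {
  finite_pair(ctrl, trt); assert_scalar_prob(alpha, "alpha")
  nc <- length(ctrl); nt <- length(trt)
  vc <- stats::var(ctrl); vt <- stats::var(trt)
  if (vc == 0 && vt == 0)
    stop_numerical("both sample variances are zero; t statistic undefined")
  se2 <- vc / nc + vt / nt
  stat <- (mean(trt) - mean(ctrl)) / sqrt(se2)
  df <- se2^2 / ((vc / nc)^2 / (nc - 1) + (vt / nt)^2 / (nt - 1))
  test_result(stat, df, alpha)
}

#' @rdname baseline_tests
#' @export
cyber_t_test <- function(ctrl, trt, alpha = 0.05) {
  finite_pair(ctrl, trt); assert_scalar_prob(alpha, "alpha")
  nc <- length(ctrl); nt <- length(trt)
  ng <- nc + nt
  nu0 <- max(0, 10 - ng)
  if (nu0 + nc - 2 <= 0 || nu0 + nt - 2 <= 0)
    stop_validation("nu0 + n_h - 2 <= 0: too few replicates for the k = 10 rule")
  sg2 <- stats::var(c(ctrl, trt))
  sigma0_2 <- ((ng - 1) / ng) * sg2
  shrink <- function(x) {
    nh <- length(x)
    (nu0 * sigma0_2 + (nh - 1) * stats::var(x)) / (nu0 + nh - 2)
  }
  vtc <- shrink(ctrl); vtt <- shrink(trt)
  if (vtc == 0 && vtt == 0)
    stop_numerical("shrunk variances are zero; t statistic undefined")
  stat <- (mean(trt) - mean(ctrl)) / sqrt(vtt / nt + vtc / nc)
  test_result(stat, nu0 + nc + nt - 2, alpha)
}

#' @rdname baseline_tests
#' @export
bayes_t_test <- function(ctrl, trt, alpha = 0.05) {
  finite_pair(ctrl, trt); assert_scalar_prob(alpha, "alpha")
  nc <- length(ctrl); nt <- length(trt)
  ng <- nc + nt
  nu0 <- ng
  sigma0_2 <- stats::var(c(ctrl, trt))
  nu_n <- nu0 + nc + nt - 2
  sigma_n2 <- (nu0 * sigma0_2 + (nc - 1) * stats::var(ctrl) +
                 (nt - 1) * stats::var(trt)) / nu_n
  if (sigma_n2 == 0)
    stop_numerical("posterior variance is zero; t statistic undefined")
  stat <- (mean(trt) - mean(ctrl)) / (sqrt(sigma_n2) * sqrt(1 / nt + 1 / nc))
  test_result(stat, nu_n, alpha)
}

#' Apply a detection method to every gene of a dataset
#'
#' Runs one of the four methods on a two-condition dataset. The baseline
#' tests are evaluated with vectorised row statistics (identical to the
#' per-gene functions); `"pa"` dispatches to [pa_detect()] on the treatment
#' effects.
#'
#' @param data an [expression_dataset()].
#' @param method one of `"pa"`, `"tt"` (Welch), `"ct"` (Cyber-t),
#'   `"btt"` (Bayesian t).
#' @param alpha working significance / credibility level.
#' @param prior an [nig_prior()], used by `"pa"` only.
#' @return For `"pa"` a `detection_result`; for the baselines a data frame
#'   with columns `gene_id`, `mean_diff`, `statistic`, `df`, `p_value`,
#'   `called`.
#' @export
test_genes <- function(data, method = c("pa", "tt", "ct", "btt"),
                       alpha = 0.05, prior = nig_prior()) {
  method <- match.arg(method)
  if (!inherits(data, "expression_dataset"))
    stop_validation("`data` must be an expression_dataset")
  assert_scalar_prob(alpha, "alpha")
  if (method == "pa")
    return(pa_detect(compute_treatment_effects(data), prior = prior, alpha = alpha))

  ctrl <- data$control; trt <- data$treatment
  nc <- ncol(ctrl); nt <- ncol(trt); ng <- nc + nt
  mc <- rowMeans(ctrl); mt <- rowMeans(trt)
  vc <- rowSums((ctrl - mc)^2) / (nc - 1)
  vt <- rowSums((trt - mt)^2) / (nt - 1)
  diff <- mt - mc

  if (method == "tt") {
    se2 <- vc / nc + vt / nt
    stat <- diff / sqrt(se2)
    df <- se2^2 / ((vc / nc)^2 / (nc - 1) + (vt / nt)^2 / (nt - 1))
  } else {
    pooled <- cbind(ctrl, trt)
    mg <- rowMeans(pooled)
    sg2 <- rowSums((pooled - mg)^2) / (ng - 1)
    if (method == "ct") {
      nu0 <- max(0, 10 - ng)
      if (nu0 + nc - 2 <= 0 || nu0 + nt - 2 <= 0)
        stop_validation("nu0 + n_h - 2 <= 0: too few replicates for the k = 10 rule")
      sigma0_2 <- ((ng - 1) / ng) * sg2
      vtc <- (nu0 * sigma0_2 + (nc - 1) * vc) / (nu0 + nc - 2)
      vtt <- (nu0 * sigma0_2 + (nt - 1) * vt) / (nu0 + nt - 2)
      stat <- diff / sqrt(vtt / nt + vtc / nc)
      df <- rep(nu0 + nc + nt - 2, length(diff))
    } else { # btt
      nu_n <- ng + nc + nt - 2
      sigma_n2 <- (ng * sg2 + (nc - 1) * vc + (nt - 1) * vt) / nu_n
      stat <- diff / (sqrt(sigma_n2) * sqrt(1 / nt + 1 / nc))
      df <- rep(nu_n, length(diff))
    }
  }
  p <- 2 * stats::pt(-abs(stat), df = df)
  data.frame(gene_id = data$gene_ids, mean_diff = diff, statistic = stat,
             df = df, p_value = p, called = p < alpha,
             stringsAsFactors = FALSE)
}
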