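# Independent scalar oracles. These deliberately avoid the package's code
# paths: sums and variances are accumulated in explicit loops and every
# posterior quantity is recomputed from scratch at every step.

loop_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

loop_var <- function(x) {
  m <- loop_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / (length(x) - 1)
}

# Sequential predictive-interval criterion, rebuilt from scratch each step:
# order the effects increasingly, and for each one recompute ybar, s^2,
# tau*, beta*, Var on the reference set (everything except the current
# effect and the previously called ones).
naive_pa_oracle <- function(y, alpha = 0.05, mu0 = 0, lambda = 1e-2, tau = 3,
                            beta = NULL) {
  n <- length(y)
  if (is.null(beta)) beta <- (tau - 2) * (max(y) - min(y))^2
  ord <- order(y)
  ys <- y[ord]
  called <- logical(n)
  thr <- numeric(n)
  for (g in seq_len(n)) {
    ref <- ys[setdiff(which(!called), g)]
    m <- length(ref)
    ybar <- loop_mean(ref)
    s2 <- loop_var(ref)
    tau_star <- tau + m + 1
    beta_star <- beta + (m - 1) * s2 + m * lambda * (ybar - mu0)^2 / (m + lambda)
    v <- (tau_star / (tau_star - 2)) *
      (beta_star * (m + lambda + 1) / (tau_star * (m + lambda)))
    thr[g] <- qt(1 - alpha / 2, tau_star) * sqrt(v)
    if (abs(ys[g]) > thr[g]) called[g] <- TRUE
  }
  out <- logical(n); out[ord] <- called
  thr_out <- numeric(n); thr_out[ord] <- thr
  list(called = out, threshold = thr_out)
}

# Welch statistic and Welch-Satterthwaite df, term by term.
welch_oracle <- function(ctrl, trt) {
  nc <- length(ctrl); nt <- length(trt)
  a <- loop_var(ctrl) / nc
  b <- loop_var(trt) / nt
  stat <- (loop_mean(trt) - loop_mean(ctrl)) / sqrt(a + b)
  df <- (a + b)^2 / (a^2 / (nc - 1) + b^2 / (nt - 1))
  list(statistic = stat, df = df, p = 2 * pt(-abs(stat), df))
}

cyber_oracle <- function(ctrl, trt) {
  nc <- length(ctrl); nt <- length(trt); ng <- nc + nt
  nu0 <- max(0, 10 - ng)
  sigma0_2 <- ((ng - 1) / ng) * loop_var(c(ctrl, trt))
  vc <- (nu0 * sigma0_2 + (nc - 1) * loop_var(ctrl)) / (nu0 + nc - 2)
  vt <- (nu0 * sigma0_2 + (nt - 1) * loop_var(trt)) / (nu0 + nt - 2)
  stat <- (loop_mean(trt) - loop_mean(ctrl)) / sqrt(vt / nt + vc / nc)
  df <- nu0 + nc + nt - 2
  list(statistic = stat, df = df, p = 2 * pt(-abs(stat), df))
}

btt_oracle <- function(ctrl, trt) {
  nc <- length(ctrl); nt <- length(trt); ng <- nc + nt
  nu_n <- ng + nc + nt - 2
  sn2 <- (ng * loop_var(c(ctrl, trt)) + (nc - 1) * loop_var(ctrl) +
            (nt - 1) * loop_var(trt)) / nu_n
  stat <- (loop_mean(trt) - loop_mean(ctrl)) / (sqrt(sn2) * sqrt(1 / nt + 1 / nc))
  list(statistic = stat, df = nu_n, p = 2 * pt(-abs(stat), nu_n))
}

# Confusion-matrix rates by explicit counting.
counting_oracle <- function(truth, called) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && called[i]) tp <- tp + 1
    if (truth[i] == 0 && called[i]) fp <- fp + 1
    if (truth[i] == 1 && !called[i]) fn <- fn + 1
    if (truth[i] == 0 && !called[i]) tn <- tn + 1
  }
  list(tpr = tp / (tp + fn), fpr = fp / (fp + tn),
       tdr = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

# Student-t upper quantile by numerically integrating the density and
# inverting the CDF with bisection (independent of stats::qt).
t_quantile_oracle <- function(p, df) {
  cdf <- function(q) 0.5 + integrate(function(x) dt(x, df), 0, q,
                                     rel.tol = 1e-10)$value
  lo <- 0; hi <- 100
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# small convenience used by several files
make_dataset <- function(ctrl, trt, ids = NULL) {
  ctrl <- as.matrix(ctrl); trt <- as.matrix(trt)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(ctrl)))
  expression_dataset(ids, ctrl, trt)
}
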