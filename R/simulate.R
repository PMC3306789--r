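#' Simulation scenario for two-condition expression data
#'
#' Describes one cell of the benchmarking grid. Control replicates are drawn
#' from N(mu_c, sigma2_c) for every gene. A randomly chosen
#' `round(n * p_over / 100)` genes are over-expressed -- their treatment
#' replicates come from N(mu_c + delta * sigma_c, (gamma * sigma_c)^2) --
#' and a disjoint `round(n * p_under / 100)` genes are under-expressed
#' (mean mu_c - delta * sigma_c). All remaining genes draw treatment from
#' the control distribution. The defaults mirror bulk log-expression data:
#' mu_c = -14 and sigma2_c = 0.8 are the average observed log-scale mean and
#' variance of the E. coli control arrays the method was developed on.
#'
#' @param n number of genes.
#' @param n_c,n_t replicate counts per condition.
#' @param mu_c control mean (log-expression units).
#' @param sigma2_c control variance (> 0).
#' @param p_over,p_under percentages of over-/under-expressed genes
#'   (p_over + p_under < 100).
#' @param delta mean-shift multiplier: differential means are
#'   mu_c +/- delta * sigma_c.
#' @param gamma standard-deviation multiplier: differential s.d. is
#'   gamma * sigma_c.
#' @param n_reps number of independent replicate datasets for this cell.
#' @param seed integer seed for this scenario's random stream.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n = 1000, n_c = 4, n_t = 4,
                            mu_c = -14, sigma2_c = 0.8,
                            p_over = 3, p_under = 2,
                            delta = 0, gamma = 1,
                            n_reps = 100, seed = 1L) {
  if (sigma2_c <= 0) stop_validation("`sigma2_c` must be positive")
  if (p_over < 0 || p_under < 0 || p_over + p_under >= 100)
    stop_validation("need p_over, p_under >= 0 and p_over + p_under < 100")
  if (delta < 0) stop_validation("`delta` must be >= 0")
  if (gamma < 0) stop_validation("`gamma` must be >= 0")
  if (n < 2 || n_c < 2 || n_t < 2)
    stop_validation("need n >= 2 genes and >= 2 replicates per condition")
  structure(list(n = as.integer(n), n_c = as.integer(n_c), n_t = as.integer(n_t),
                 mu_c = mu_c, sigma2_c = sigma2_c,
                 p_over = p_over, p_under = p_under,
                 delta = delta, gamma = gamma,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "scenario_config")
}

# Deterministic substream seed below 2^31: one independent seed per
# (stream, index) pair, so any replicate is regenerable in isolation.
derive_seed <- function(seed, index) {
  a <- as.double(seed %% 2147483647L)
  as.integer((a * 48271 + as.double(index) * 9973 + 1) %% 2147483647)
}

#' Simulate one labelled replicate dataset
#'
#' Draws one dataset under a scenario. The number of differential genes is
#' deterministic (exactly the rounded percentages); only the subset
#' membership is random, redrawn independently per replicate. The random
#' stream is fully determined by `(cfg$seed, rep_index)`.
#'
#' @param cfg a [scenario_config()].
#' @param rep_index replicate number (1-based) selecting the substream.
#' @return An object of class `labeled_dataset`: list with `data` (an
#'   [expression_dataset()]), `truth` (0/1 integer vector) and `direction`
#'   (factor in `over`, `under`, `none`).
#' @export
simulate_dataset <- function(cfg, rep_index = 1L) {
  if (!inherits(cfg, "scenario_config"))
    stop_validation("`cfg` must be a scenario_config")
  n <- cfg$n; nc <- cfg$n_c; nt <- cfg$n_t
  sc <- sqrt(cfg$sigma2_c)
  n_over <- round(n * cfg$p_over / 100)
  n_under <- round(n * cfg$p_under / 100)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(cfg$seed, rep_index))

  idx <- sample.int(n, n_over + n_under)
  over <- idx[seq_len(n_over)]
  under <- idx[n_over + seq_len(n_under)]

  ctrl <- matrix(stats::rnorm(n * nc, cfg$mu_c, sc), nrow = n)
  trt <- matrix(stats::rnorm(n * nt, cfg$mu_c, sc), nrow = n)
  if (n_over > 0)
    trt[over, ] <- stats::rnorm(n_over * nt, cfg$mu_c + cfg$delta * sc, cfg$gamma * sc)
  if (n_under > 0)
    trt[under, ] <- stats::rnorm(n_under * nt, cfg$mu_c - cfg$delta * sc, cfg$gamma * sc)

  truth <- integer(n); truth[idx] <- 1L
  direction <- rep("none", n)
  direction[over] <- "over"; direction[under] <- "under"

  structure(list(
    data = expression_dataset(sprintf("g%04d", seq_len(n)), ctrl, trt),
    truth = truth,
    direction = factor(direction, levels = c("over", "under", "none"))),
    class = "labeled_dataset")
}

#' Full factorial benchmark grid
#'
#' Builds one [scenario_config()] per cell of the factorial grid of sample
#' sizes, differential-percentage splits, mean shifts delta and s.d.
#' multipliers gamma (default: 2 x 3 x 9 x 3 = 162 cells, 100 replicates
#' each). Each cell receives a distinct deterministic seed derived from
#' `root_seed`.
#'
#' @param sample_sizes integer vector of per-condition replicate counts
#'   (applied to both conditions).
#' @param p_splits list of `c(p_over, p_under)` percentage pairs.
#' @param deltas,gammas numeric vectors of shift / scale multipliers.
#' @param n genes per dataset; `n_reps` replicates per cell.
#' @param root_seed root of the per-cell seed derivation.
#' @inheritParams scenario_config
#' @return List of `scenario_config` objects.
#' @export
scenario_grid <- function(sample_sizes = c(4, 8),
                          p_splits = list(c(3, 2), c(7, 3), c(5, 15)),
                          deltas = seq(0, 2, by = 0.25),
                          gammas = c(1, 2, 3),
                          n = 1000, n_reps = 100,
                          mu_c = -14, sigma2_c = 0.8,
                          root_seed = 1L) {
  grid <- expand.grid(size = seq_along(sample_sizes),
                      split = seq_along(p_splits),
                      delta = deltas, gamma = gammas,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    sz <- sample_sizes[grid$size[i]]
    sp <- p_splits[[grid$split[i]]]
    scenario_config(n = n, n_c = sz, n_t = sz,
                    mu_c = mu_c, sigma2_c = sigma2_c,
                    p_over = sp[1], p_under = sp[2],
                    delta = grid$delta[i], gamma = grid$gamma[i],
                    n_reps = n_reps, seed = derive_seed(root_seed, i))
  })
}
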