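#' Configuration for a stochastic ecDNA population simulation
#'
#' The simulator is a pure birth process: an exponentially growing population
#' started (by default) from a single founder cell carrying `n0` ecDNA
#' copies. Cells without ecDNA divide at rate 1 (time is measured in
#' generations of ecDNA-free cells); cells carrying at least one copy divide
#' at rate `s`, the selection coefficient (`s = 1` neutral, `s > 1` positive,
#' `0 < s < 1` negative selection). At division the mother's `k` copies are
#' doubled and split `Binomial(2k, 1/2)` between the daughters; a cell with
#' no ecDNA never produces ecDNA+ offspring. The run terminates at population
#' size `n_target`.
#'
#' @param n0 Founder ecDNA copy number (non-negative integer).
#' @param s Selection coefficient (> 0).
#' @param n_target Terminal population size (>= 1).
#' @param snapshot_sizes Optional increasing vector of population sizes at
#'   which the full state is recorded (default: powers of 2 up to
#'   `n_target`).
#' @param seed Optional integer seed; replicate `r` of a replicated run uses
#'   `seed + r - 1`.
#' @return An object of class `sim_config`.
#' @seealso [run_gillespie()]
#' @export
sim_config <- function(n0, s = 1, n_target, snapshot_sizes = NULL,
                       seed = NULL) {
  .check_scalar_number(n0, "n0", 0, integer = TRUE)
  .check_scalar_number(s, "s", 0, strict_lower = TRUE)
  .check_scalar_number(n_target, "n_target", 1, integer = TRUE)
  if (n_target < 1) .stop_param("'n_target' must be >= 1")
  if (is.null(snapshot_sizes)) {
    snapshot_sizes <- 2^seq.int(1, max(1, floor(log2(n_target))))
    snapshot_sizes <- snapshot_sizes[snapshot_sizes <= n_target]
  }
  if (length(snapshot_sizes) && (is.unsorted(snapshot_sizes, strictly = TRUE) ||
                                 any(snapshot_sizes < 1)))
    .stop_param("'snapshot_sizes' must be strictly increasing and >= 1")
  structure(list(n0 = as.integer(n0), s = s, n_target = n_target,
                 snapshot_sizes = as.numeric(snapshot_sizes), seed = seed),
            class = "sim_config")
}

# Build a population_state from (total, scar) class-count vectors.
population_state <- function(counts, t = 0, scar_counts = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) .stop_validation("negative class count")
  structure(list(counts = counts, scar_counts = scar_counts,
                 t = t, n = sum(counts)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state: N = %g cells, t = %.3f, copy classes 0..%d\n",
              x$n, x$t, length(x$counts) - 1L))
  invisible(x)
}

.state_from_record <- function(rec) {
  population_state(rec$counts_noscar + rec$counts_scar, t = rec$t,
                   scar_counts = rec$counts_scar)
}

#' Run the individual-based Gillespie simulation
#'
#' Simulates the birth process described in [sim_config()] until the target
#' population size, recording the full class-count state at each requested
#' snapshot size and at the end.
#'
#' @param config A [sim_config()].
#' @param max_events Guard on the number of division events (default `1e9`).
#' @return A list of class `gillespie_run` with elements `final` (a
#'   `population_state`), `snapshots` (list of `population_state`, one per
#'   recorded size), and `config`.
#' @examples
#' run <- run_gillespie(sim_config(n0 = 1, s = 1, n_target = 100, seed = 1))
#' summarize_population(run$final)$m1
#' @export
run_gillespie <- function(config, max_events = 1e9) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_target < 1) .stop_param("'n_target' below initial size")
  .seed_in(config$seed)
  init <- numeric(config$n0 + 1L)
  init[config$n0 + 1L] <- 1
  res <- cpp_gillespie(init, numeric(length(init)), config$s,
                       t_start = 0, t_end = Inf, n_cap = config$n_target,
                       record_times = numeric(0),
                       snapshot_sizes = config$snapshot_sizes,
                       max_events = max_events)
  final <- population_state(res$counts_noscar + res$counts_scar, t = res$t)
  snaps <- lapply(res$records, .state_from_record)
  structure(list(final = final, snapshots = snaps, config = config),
            class = "gillespie_run")
}

#' Ensemble of simulations recorded at fixed times
#'
#' Runs `replicates` independent trajectories from a single founder with
#' `n0` copies and pools the class counts across replicates at each
#' recording time. Pooling all cells of all replicates estimates
#' `E[N_k(t)] / E[N(t)]`, which is exactly the density solved by the
#' deterministic master equation, so the pooled ensemble is directly
#' comparable to [integrate_density()].
#'
#' @param n0 Founder copy number.
#' @param s Selection coefficient.
#' @param t_max Final time (generations).
#' @param record_times Times at which to record (default `seq(0, t_max)`).
#' @param replicates Number of independent trajectories.
#' @param seed Optional integer seed (replicate `r` uses `seed + r - 1`).
#' @param n_cap Safety cap on the per-replicate population size.
#' @return List of class `gillespie_ensemble`: `times`, `pooled` (matrix,
#'   one row per time, column `k+1` = pooled count of cells with `k`
#'   copies), `moments` (data frame with `t`, `m1`, `m2`, `variance`,
#'   `frac_pos`, `rho0`, `n_cells`), `replicates`.
#' @export
run_gillespie_ensemble <- function(n0, s = 1, t_max, record_times = NULL,
                                   replicates = 100, seed = NULL,
                                   n_cap = 1e7) {
  .check_scalar_number(n0, "n0", 0, integer = TRUE)
  .check_scalar_number(s, "s", 0, strict_lower = TRUE)
  .check_scalar_number(t_max, "t_max", 0, strict_lower = TRUE)
  .check_scalar_number(replicates, "replicates", 1, integer = TRUE)
  if (is.null(record_times)) record_times <- seq(0, t_max)
  record_times <- sort(unique(c(record_times, t_max)))
  nt <- length(record_times)
  pooled <- matrix(0, nrow = nt, ncol = n0 + 2L)
  init <- numeric(n0 + 1L)
  init[n0 + 1L] <- 1
  for (r in seq_len(replicates)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + r - 1L)
    res <- cpp_gillespie(init, numeric(length(init)), s,
                         t_start = 0, t_end = t_max, n_cap = n_cap,
                         record_times = record_times,
                         snapshot_sizes = numeric(0), max_events = 1e9)
    for (j in seq_along(res$records)) {
      cts <- res$records[[j]]$counts_noscar + res$records[[j]]$counts_scar
      if (length(cts) > ncol(pooled))
        pooled <- cbind(pooled, matrix(0, nrow = nt,
                                       ncol = length(cts) - ncol(pooled)))
      pooled[j, seq_along(cts)] <- pooled[j, seq_along(cts)] + cts
    }
  }
  k <- seq_len(ncol(pooled)) - 1
  n_cells <- rowSums(pooled)
  q <- pooled / n_cells
  m1 <- as.numeric(q %*% k)
  m2 <- as.numeric(q %*% k^2)
  moments <- data.frame(t = record_times, m1 = m1, m2 = m2,
                        variance = m2 - m1^2, frac_pos = 1 - q[, 1],
                        rho0 = q[, 1], n_cells = n_cells)
  structure(list(times = record_times, pooled = pooled, moments = moments,
                 replicates = replicates, s = s, n0 = n0),
            class = "gillespie_ensemble")
}

#' Sample the copy-number class of the next dividing cell
#'
#' Draws the class of a dividing cell with probability proportional to
#' `N_k * rate(k)` where `rate(k)` is 1 for `k = 0` and `s` otherwise.
#' Implemented by rejection sampling: a cell is proposed uniformly at random
#' and accepted with probability `rate(k) / max(1, s)`, so the cost per
#' accepted event does not depend on the number of copy-number classes.
#'
#' @param state A `population_state`.
#' @param s Selection coefficient.
#' @param n_draws Number of independent draws.
#' @param seed Optional integer seed.
#' @return Integer vector of sampled copy-number classes.
#' @export
select_dividing_cell <- function(state, s = 1, n_draws = 1, seed = NULL) {
  stopifnot(inherits(state, "population_state"))
  if (state$n < 1) .stop_validation("empty population")
  .check_scalar_number(s, "s", 0, strict_lower = TRUE)
  .seed_in(seed)
  k_vals <- seq_along(state$counts) - 1L
  prob <- state$counts / state$n
  max_rate <- max(1, s)
  rate <- ifelse(k_vals == 0, 1, s)
  out <- integer(0)
  while (length(out) < n_draws) {
    m <- max(16L, 2L * (n_draws - length(out)))
    prop <- sample(k_vals, m, replace = TRUE, prob = prob)
    acc <- runif(m) < rate[prop + 1L] / max_rate
    out <- c(out, prop[acc])
  }
  out[seq_len(n_draws)]
}

#' Copy-number distribution
#'
#' Normalized frequencies `q_k` of cells per ecDNA copy number, either from
#' a class-count vector (`counts[j]` = cells with `j - 1` copies) or from a
#' vector of per-cell copy numbers via [cells_to_distribution()].
#'
#' @param counts Numeric vector of class counts indexed by `k + 1`.
#' @return Object of class `copy_number_distribution`: list with integer
#'   `k`, frequencies `q` (summing to 1) and `n_sample`.
#' @export
copy_number_distribution <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0 || any(counts < 0) || sum(counts) <= 0)
    .stop_validation("class counts must be non-negative with positive total")
  structure(list(k = seq_along(counts) - 1L, q = counts / sum(counts),
                 n_sample = sum(counts)),
            class = "copy_number_distribution")
}

#' @rdname copy_number_distribution
#' @param cells Integer vector of per-cell copy numbers.
#' @export
cells_to_distribution <- function(cells) {
  if (length(cells) == 0 || any(cells < 0) || any(cells != floor(cells)))
    .stop_validation("'cells' must be non-negative integer copy numbers")
  copy_number_distribution(tabulate(cells + 1L, nbins = max(cells) + 1L))
}

#' Draw per-cell copy numbers from a copy-number distribution
#'
#' @param dist A `copy_number_distribution`.
#' @param n_cells Number of cells to draw.
#' @param seed Optional integer seed.
#' @return Integer vector of copy numbers.
#' @export
sample_cells <- function(dist, n_cells, seed = NULL) {
  stopifnot(inherits(dist, "copy_number_distribution"))
  .check_scalar_number(n_cells, "n_cells", 1, integer = TRUE)
  .seed_in(seed)
  sample(dist$k, n_cells, replace = TRUE, prob = dist$q)
}

#' @export
print.copy_number_distribution <- function(x, ...) {
  m1 <- sum(x$k * x$q)
  cat(sprintf("Copy-number distribution: %g cells, classes 0..%d, mean %.3f\n",
              x$n_sample, max(x$k), m1))
  invisible(x)
}

#' Summary statistics of a population state
#'
#' Computes the copy-number distribution `q_k = N_k / N`, the first two raw
#' moments `M1 = sum k q_k` and `M2 = sum k^2 q_k`, the variance, the
#' fraction of ecDNA+ cells `1 - q_0`, and the Shannon diversity index
#' `-sum q_k log q_k` over occupied classes.
#'
#' @param state A `population_state` or `copy_number_distribution`.
#' @return List with `distribution`, `m1`, `m2`, `variance`, `frac_pos`,
#'   `shannon`.
#' @export
summarize_population <- function(state) {
  if (inherits(state, "population_state")) {
    if (state$n < 1) .stop_validation("empty population state")
    dist <- copy_number_distribution(state$counts)
  } else if (inherits(state, "copy_number_distribution")) {
    dist <- state
  } else .stop_validation("need a population_state or copy_number_distribution")
  q <- dist$q
  k <- dist$k
  m1 <- sum(k * q)
  m2 <- sum(k^2 * q)
  pos <- q[q > 0]
  list(distribution = dist, m1 = m1, m2 = m2,
       variance = m2 - m1^2, frac_pos = 1 - q[1],
       shannon = -sum(pos * log(pos)))
}

#' Power-law exponent of the copy-number distribution tail
#'
#' Fits a least-squares line to `log CCDF(k)` versus `log k` over the upper
#' `tail_fraction` of the distinct occupied copy-number classes, where
#' `CCDF(k) = P(K >= k)`. A heavy (power-law) tail gives a stable negative
#' slope; for geometrically decaying tails the estimate steepens as the
#' window shrinks.
#'
#' @param dist A `copy_number_distribution`.
#' @param tail_fraction Fraction (0, 1] of distinct positive classes used.
#' @return The fitted slope (scaling exponent of the CCDF).
#' @export
tail_exponent <- function(dist, tail_fraction = 0.1) {
  stopifnot(inherits(dist, "copy_number_distribution"))
  .check_scalar_number(tail_fraction, "tail_fraction", 0, 1,
                       strict_lower = TRUE)
  occ <- dist$k[dist$q > 0 & dist$k > 0]
  m <- ceiling(tail_fraction * length(occ))
  if (length(occ) < 2 || m < 10)
    stop(errorCondition(
      sprintf("tail not estimable: %d distinct classes in the upper tail (need >= 10)", m),
      class = c("ecdnadyn_estimation_error", "error", "condition")))
  kk <- sort(occ, decreasing = TRUE)[seq_len(m)]
  ccdf_all <- rev(cumsum(rev(dist$q)))
  ccdf <- ccdf_all[kk + 1L]
  keep <- ccdf > 0
  unname(coef(lm(log(ccdf[keep]) ~ log(kk[keep])))[2])
}
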