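# Shared fixtures, built in code at test time.

# Total-variation distance between two discrete distributions given as
# (possibly different-length) probability vectors indexed by k + 1.
tv_distance <- function(p, q) {
  L <- max(length(p), length(q))
  p <- c(p, rep(0, L - length(p)))
  q <- c(q, rep(0, L - length(q)))
  0.5 * sum(abs(p - q))
}

# Discrete Pareto sample with exact CCDF (kmin/k)^2 for k >= kmin:
# K = floor(kmin * U^(-1/2)).
rpareto_discrete <- function(n, kmin = 20) {
  floor(kmin * runif(n)^(-1 / 2))
}

# Independent sup-ECDF-difference oracle used against ks_two_sample.
brute_force_ks_d <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  dmax <- 0
  for (g in grid) {
    d <- abs(mean(x <= g) - mean(y <= g))
    if (d > dmax) dmax <- d
  }
  dmax
}

# Mean copy number of a gillespie_run final state.
final_mean_copy <- function(run) summarize_population(run$final)$m1
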