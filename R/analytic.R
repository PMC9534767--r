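#' Fraction of ecDNA-positive cells under neutral dynamics
#'
#' Closed form for the fraction of cells carrying at least one ecDNA copy in
#' an exponentially growing population started from a single ecDNA+ founder
#' under neutral selection: `f+(t) = 2 / (2 + t)`. Neutral ecDNA is
#' progressively diluted into an ever smaller subpopulation, decaying like
#' `1/t`.
#'
#' @param t Time(s) in generations, `t >= 0`.
#' @return `2 / (2 + t)`, vectorized.
#' @examples
#' neutral_fraction_positive(c(0, 2, 98))
#' @export
neutral_fraction_positive <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    .stop_param("'t' must be non-negative")
  2 / (2 + t)
}

# Redistribution kernel of random binomial segregation:
# A[k+1, i+1] = C(2i, k) 2^(-2i) = dbinom(k, 2i, 1/2), the probability that a
# daughter of a mother with i copies inherits k. dbinom works in log space,
# so no overflow for large i.
.binomial_kernel <- function(k_max) {
  k <- 0:k_max
  vapply(0:k_max, function(i) stats::dbinom(k, size = 2L * i, prob = 0.5),
         numeric(k_max + 1L))
}

#' Right-hand side of the copy-number density master equation
#'
#' Time derivative of the normalized density `rho_k` of cells with `k` ecDNA
#' copies. Under neutral dynamics,
#' `d rho_k / dt = -2 rho_k + 2 sum_i rho_i C(2i, k) 2^(-2i)`,
#' the sum running over mothers `i >= ceiling(k/2)` (the binomial coefficient
#' vanishes below that, so the full sum is used). With selection `s != 1`
#' the ecDNA+ classes gain a growth-coupling term:
#' `d rho_k / dt = s (d rho_k / dt)|_{s=1} + (s - 1) rho_0 rho_k` for
#' `k >= 1`, while the ecDNA-free class follows
#' `d rho_0 / dt = s (d rho_0 / dt)|_{s=1} - (s - 1) rho_0 (1 - rho_0)`,
#' the sign of the coupling term fixed by conservation of total density
#' (see the methods vignette for the derivation; this form reproduces the
#' moment solution `M1(t) = exp((s-1) int rho_0)`).
#'
#' @param rho Density vector indexed by `k + 1`, non-negative, summing to 1
#'   (up to truncation leak).
#' @param s Selection coefficient (> 0).
#' @param kernel Optional precomputed kernel from an earlier call (matched
#'   to `length(rho)`); computed on the fly if `NULL`.
#' @return Numeric vector `d rho / dt` of the same length as `rho`.
#' @export
density_rhs <- function(rho, s = 1, kernel = NULL) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho < -1e-12))
    .stop_validation("'rho' must be a non-negative density vector")
  .check_scalar_number(s, "s", 0, strict_lower = TRUE)
  if (is.null(kernel)) kernel <- .binomial_kernel(length(rho) - 1L)
  neutral <- -2 * rho + 2 * as.numeric(kernel %*% rho)
  if (s == 1) return(neutral)
  rho0 <- rho[1]
  out <- s * neutral + (s - 1) * rho0 * rho
  out[1] <- s * neutral[1] - (s - 1) * rho0 * (1 - rho0)
  out
}

#' Integrate the copy-number density master equation
#'
#' Numerically integrates [density_rhs()] from an initial density on a
#' truncated copy-number lattice `k = 0..k_max`, with automatic doubling of
#' `k_max` (up to `k_max_limit`) whenever the mass reaching the truncation
#' boundary exceeds `leak_bound`. Uses the non-stiff Adams integrator from
#' \pkg{deSolve}.
#'
#' @param init Either a single non-negative integer `k` (all density starts
#'   in class `k`) or a normalized density vector indexed by `k + 1`.
#' @param s Selection coefficient.
#' @param t_max Final time; output times default to `seq(0, t_max,
#'   length.out = 101)`.
#' @param times Optional explicit output times (must start at 0).
#' @param k_max Initial truncation (default 512).
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param leak_bound Maximum tolerated density at the truncation boundary.
#' @param k_max_limit Upper bound for automatic truncation doubling.
#' @return Object of class `density_series`: `times`, `rho` (matrix, one row
#'   per time, column `k + 1`), `moments` (data frame with `t`, `m1`, `m2`,
#'   `m3`, `variance`, `frac_pos`, `rho0`), `k_max`, `leaked_mass`
#'   (worst-case `|1 - sum(rho)|` over the trajectory) and `s`.
#' @examples
#' sol <- integrate_density(init = 1, s = 1, t_max = 5, k_max = 64)
#' range(sol$moments$m1) # conserved at 1 under neutrality
#' @export
integrate_density <- function(init = 1, s = 1, t_max = 10, times = NULL,
                              k_max = 512, rtol = 1e-8, atol = 1e-12,
                              leak_bound = 1e-10, k_max_limit = 8192) {
  .check_scalar_number(s, "s", 0, strict_lower = TRUE)
  .check_scalar_number(t_max, "t_max", 0, strict_lower = TRUE)
  if (is.null(times)) times <- seq(0, t_max, length.out = 101)
  if (times[1] != 0) .stop_param("'times' must start at 0")
  if (length(init) == 1L) {
    .check_scalar_number(init, "init", 0, integer = TRUE)
    init_k <- as.integer(init)
    make_rho0 <- function(km) { r <- numeric(km + 1L); r[init_k + 1L] <- 1; r }
    if (init_k > k_max) .stop_param("'init' class exceeds 'k_max'")
  } else {
    if (any(init < 0) || abs(sum(init) - 1) > 1e-8)
      .stop_validation("initial density must be non-negative and normalized")
    make_rho0 <- function(km) {
      if (length(init) > km + 1L)
        .stop_param("initial density longer than truncation")
      c(init, numeric(km + 1L - length(init)))
    }
  }

  repeat {
    kernel <- .binomial_kernel(k_max)
    rhs <- function(t, y, parms) list(density_rhs(y, s = parms, kernel = kernel))
    sol <- deSolve::ode(y = make_rho0(k_max), times = times, func = rhs,
                        parms = s, method = "adams", rtol = rtol, atol = atol)
    rho <- unname(sol[, -1, drop = FALSE])
    tail_mass <- max(rho[, k_max + 1L])
    if (tail_mass <= leak_bound || k_max >= k_max_limit) break
    k_max <- min(2L * k_max, k_max_limit)
  }
  if (tail_mass > leak_bound)
    stop(errorCondition(
      sprintf("truncation leak %.3g above bound at k_max_limit = %d",
              tail_mass, k_max_limit),
      class = c("ecdnadyn_truncation_error", "error", "condition")))

  k <- 0:k_max
  m1 <- as.numeric(rho %*% k)
  m2 <- as.numeric(rho %*% k^2)
  m3 <- as.numeric(rho %*% k^3)
  moments <- data.frame(t = times, m1 = m1, m2 = m2, m3 = m3,
                        variance = m2 - m1^2,
                        frac_pos = 1 - rho[, 1], rho0 = rho[, 1])
  structure(list(times = times, rho = rho, moments = moments, k_max = k_max,
                 leaked_mass = max(abs(1 - rowSums(rho))), s = s),
            class = "density_series")
}

#' @export
print.density_series <- function(x, ...) {
  cat(sprintf(
    "Density series: s = %g, t in [0, %g], k_max = %d, leaked mass %.2e\n",
    x$s, max(x$times), x$k_max, x$leaked_mass))
  invisible(x)
}

#' First moment under selection from the ecDNA-free density path
#'
#' Closed form for the mean copy number under selection:
#' `M1(t) = exp((s - 1) * int_0^t rho_0(tau) d tau)`, evaluated by
#' trapezoidal quadrature of a supplied `rho_0` time series. For `s = 1`
#' this reduces to the neutral conservation law `M1 = M1(0)`.
#'
#' @param s Selection coefficient.
#' @param times Increasing time grid.
#' @param rho0 Values of the ecDNA-free density on `times`, each in
#'   `[0, 1]`.
#' @return Numeric vector `M1(times)`.
#' @export
selection_m1 <- function(s, times, rho0) {
  .check_scalar_number(s, "s", 0, strict_lower = TRUE)
  if (length(times) != length(rho0))
    .stop_validation("'times' and 'rho0' must be aligned")
  if (any(rho0 < 0 | rho0 > 1))
    .stop_validation("'rho0' values must lie in [0, 1]")
  integral <- as.numeric(pracma::cumtrapz(times, rho0))
  exp((s - 1) * integral)
}

#' Second moment from the first-moment series
#'
#' The second raw moment satisfies `M2(t) = t * M1(t)` (asymptotic,
#' offset-free form; the assertable differential statement under neutrality
#' is `dM2/dt = M1`).
#'
#' @param times Time grid.
#' @param m1 First-moment series aligned with `times`.
#' @return `times * m1`.
#' @export
selection_m2 <- function(times, m1) {
  if (length(times) != length(m1))
    .stop_validation("'times' and 'm1' must be aligned")
  times * m1
}

#' Two-population solution under positive selection
#'
#' Coarse two-compartment model tracking only ecDNA+ versus ecDNA-free
#' cells. Given the path of the ecDNA-free fraction `f-(t)`, the ecDNA+
#' compartment grows as
#' `N+(t) = (1 - f-(0)) * exp(s t - (1 - s) int_0^t f-(tau) d tau)`;
#' under positive selection (`s > 1`) the ecDNA+ fraction tends to 1 and
#' the tumor becomes dominated by ecDNA-carrying cells.
#'
#' @param s Selection coefficient, strictly > 1 (this solution branch).
#' @param times Increasing time grid.
#' @param f_minus Path of the ecDNA-free fraction on `times` (e.g. the
#'   `rho0` column of an [integrate_density()] run), values in `[0, 1]`.
#' @return Data frame with `t`, `f_minus`, `f_plus = 1 - f_minus`,
#'   `n_plus`.
#' @export
two_population_selection <- function(s, times, f_minus) {
  if (!is.numeric(s) || length(s) != 1L || s <= 1)
    .stop_param("'s' must be > 1 for the positive-selection branch")
  if (length(times) != length(f_minus))
    .stop_validation("'times' and 'f_minus' must be aligned")
  if (any(f_minus < 0 | f_minus > 1))
    .stop_validation("'f_minus' values must lie in [0, 1]")
  integral <- as.numeric(pracma::cumtrapz(times, f_minus))
  n_plus <- (1 - f_minus[1]) * exp(s * times - (1 - s) * integral)
  data.frame(t = times, f_minus = f_minus, f_plus = 1 - f_minus,
             n_plus = n_plus)
}

#' Late-time scaling exponent of a moment series
#'
#' All raw moments of the neutral density scale as `M^(l)(t) ~ t^(l-1)` at
#' late times. This fits the log-log slope of a moment series over a
#' late-time window (default: the last decade of the grid, `t` in
#' `[t_max / 10, t_max]`).
#'
#' @param times Time grid (positive within the window).
#' @param values Moment values aligned with `times`.
#' @param window Optional `c(lo, hi)` time window; must span at least a
#'   factor 10 unless overridden.
#' @param min_span Minimum `hi / lo` ratio of the window (default 10).
#' @return Fitted log-log slope.
#' @export
moment_scaling_check <- function(times, values, window = NULL,
                                 min_span = 10) {
  if (length(times) != length(values))
    .stop_validation("'times' and 'values' must be aligned")
  if (is.null(window)) window <- c(max(times) / 10, max(times))
  keep <- times >= window[1] & times <= window[2] & times > 0 & values > 0
  if (sum(keep) < 3 || max(times[keep]) / min(times[keep]) < min_span * 0.999)
    stop(errorCondition(
      "insufficient time range: the scaling window must span a decade",
      class = c("ecdnadyn_estimation_error", "error", "condition")))
  v <- values[keep]
  if (stats::sd(v) == 0) return(0)
  unname(coef(lm(log(v) ~ log(times[keep])))[2])
}
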