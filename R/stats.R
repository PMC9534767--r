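#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Computes `D = sup |ECDF_x - ECDF_y|` and the asymptotic p-value based on
#' the Kolmogorov distribution at effective sample size
#' `n_x n_y / (n_x + n_y)` (via [stats::ks.test()] with `exact = FALSE`).
#' Copy-number data are discrete, so the asymptotic p-value is conservative
#' in the presence of ties; an optional permutation p-value is available for
#' tie-heavy data.
#'
#' @param x,y Non-empty numeric samples.
#' @param permutation_p If `TRUE`, additionally estimate the p-value by
#'   permuting sample labels.
#' @param n_perm Number of permutations (default `1e4`).
#' @param seed Optional integer seed (permutation only).
#' @return Object of class `ks_result`: list with `D`, `p`, `n_x`, `n_y`
#'   and, when requested, `p_perm`.
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50))
#' @export
ks_two_sample <- function(x, y, permutation_p = FALSE, n_perm = 1e4,
                          seed = NULL) {
  if (length(x) < 1 || length(y) < 1)
    .stop_validation("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  out <- list(D = unname(kt$statistic), p = min(1, max(0, kt$p.value)),
              n_x = length(x), n_y = length(y))
  if (permutation_p) {
    .seed_in(seed)
    pooled <- c(x, y)
    nx <- length(x)
    d_obs <- out$D
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), nx)
      d_b <- .ks_statistic(pooled[idx], pooled[-idx])
      if (d_b >= d_obs - 1e-12) hits <- hits + 1L
    }
    out$p_perm <- (hits + 1) / (n_perm + 1)
  }
  structure(out, class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.4g (n = %d vs %d)\n",
              x$D, x$p, x$n_x, x$n_y))
  if (!is.null(x$p_perm))
    cat(sprintf("  permutation p = %.4g\n", x$p_perm))
  invisible(x)
}

# sup-|ECDF difference| evaluated over the pooled support
.ks_statistic <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  max(abs(fx - fy))
}

# Asymptotic Kolmogorov survival function Q(lambda) = P(sqrt(n) D > lambda)
.kolmogorov_q <- function(lambda) {
  if (lambda < 0.05) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
}

#' Shapiro-Wilk test of normality
#'
#' Thin validated wrapper around [stats::shapiro.test()] (Royston's
#' approximation of the order-statistic weights), used to test segregation
#' fraction distributions for deviation from the Gaussian bell expected
#' under random segregation.
#'
#' @param x Numeric sample with `3 <= n <= 5000` and non-zero spread.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000)
    .stop_param("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0)
    .stop_validation("W is undefined for a constant sample")
  st <- shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Subsampling resolution analysis of a copy-number distribution
#'
#' How many cells must be scored to resolve the true copy-number
#' distribution? For each sample size, draws `n_resamples` random subsets
#' (without replacement) from a large reference sample of per-cell copy
#' numbers, computes the KS distance of each subset to the full reference
#' distribution, and reports the mean distance and the rejection rate at
#' level `alpha`. The distance shrinks with sample size; on the order of
#' 100-500 cells suffices in practice.
#'
#' @param cells Integer vector of per-cell copy numbers (the reference
#'   sample; typically `>= 1e5` cells from a simulation), or a
#'   `copy_number_distribution` with a large `n_sample`.
#' @param sizes Strictly increasing subsample sizes (default
#'   `c(25, 50, 100, 500)`).
#' @param n_resamples Resamples per size (default 500).
#' @param alpha Rejection level (default 0.05, the conventional `P > 0.05`
#'   acceptance threshold).
#' @param seed Optional integer seed.
#' @return Object of class `subsample_report`: data frame with `size`,
#'   `mean_D`, `rejection_rate`, plus attributes `n_resamples`, `alpha`,
#'   `n_source`.
#' @export
subsample_convergence <- function(cells, sizes = c(25, 50, 100, 500),
                                  n_resamples = 500, alpha = 0.05,
                                  seed = NULL) {
  if (inherits(cells, "copy_number_distribution"))
    cells <- sample_cells(cells, cells$n_sample, seed = seed)
  if (length(cells) < 2 || any(cells < 0) || any(cells != floor(cells)))
    .stop_validation("'cells' must be non-negative integer copy numbers")
  if (is.unsorted(sizes, strictly = TRUE))
    .stop_param("'sizes' must be strictly increasing")
  if (max(sizes) >= length(cells))
    .stop_param("subsample sizes must be smaller than the source sample")
  .check_scalar_number(n_resamples, "n_resamples", 1, integer = TRUE)
  .check_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE,
                       strict_upper = TRUE)
  .seed_in(seed)
  n_src <- length(cells)
  kmax <- max(cells)
  full_cdf <- cumsum(tabulate(cells + 1L, nbins = kmax + 1L)) / n_src
  res <- lapply(sizes, function(m) {
    d <- numeric(n_resamples)
    rej <- logical(n_resamples)
    ne <- m * n_src / (m + n_src)
    # Stephens' finite-n correction of the asymptotic Kolmogorov p-value:
    # markedly better calibrated than plain sqrt(ne) * D at n ~ 25
    lam_scale <- sqrt(ne) + 0.12 + 0.11 / sqrt(ne)
    for (b in seq_len(n_resamples)) {
      sub <- cells[sample.int(n_src, m)]
      sub_cdf <- cumsum(tabulate(sub + 1L, nbins = kmax + 1L)) / m
      d[b] <- max(abs(sub_cdf - full_cdf))
      rej[b] <- .kolmogorov_q(lam_scale * d[b]) < alpha
    }
    c(mean_D = mean(d), rejection_rate = mean(rej))
  })
  out <- data.frame(size = sizes, do.call(rbind, res))
  attr(out, "n_resamples") <- n_resamples
  attr(out, "alpha") <- alpha
  attr(out, "n_source") <- n_src
  class(out) <- c("subsample_report", "data.frame")
  out
}
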