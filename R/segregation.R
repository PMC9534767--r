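#' Segregation model for a single cell division
#'
#' ecDNA elements lack centromeres, so at mitosis the replicated copies are
#' partitioned between daughter cells at random: a mother with `n` copies
#' replicates to `2n` and daughter 1 receives `n1 ~ Binomial(2n, p)` copies,
#' `p = 1/2` being unbiased random segregation. The chromosomal comparator
#' models centromeric inheritance: both daughters receive exactly `n` copies,
#' except with mis-segregation probability `u` one daughter gains a copy at
#' the expense of the other (`n1 = n + 1` or `n - 1`, each direction equally
#' likely).
#'
#' @param kind `"ecdna_binomial"` or `"chromosomal"`.
#' @param p Per-copy probability that a copy enters daughter 1
#'   (ecdna_binomial only); must lie strictly in (0, 1).
#' @param u Mis-segregation probability per division (chromosomal only),
#'   in `[0, 1]`.
#' @return An object of class `segregation_model`.
#' @examples
#' segregation_model("ecdna_binomial", p = 0.5)
#' segregation_model("chromosomal", u = 0.05)
#' @export
segregation_model <- function(kind = c("ecdna_binomial", "chromosomal"),
                              p = 0.5, u = 0.05) {
  kind <- match.arg(kind)
  if (kind == "ecdna_binomial") {
    .check_scalar_number(p, "p", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
    out <- list(kind = kind, p = p)
  } else {
    .check_scalar_number(u, "u", 0, 1)
    out <- list(kind = kind, u = u)
  }
  structure(out, class = "segregation_model")
}

#' @export
print.segregation_model <- function(x, ...) {
  if (x$kind == "ecdna_binomial")
    cat(sprintf("Segregation model: binomial ecDNA segregation, p = %g\n", x$p))
  else
    cat(sprintf("Segregation model: chromosomal, mis-segregation u = %g\n", x$u))
  invisible(x)
}

.division_outcome <- function(n1, n2) {
  tot <- n1 + n2
  f1 <- ifelse(tot > 0, n1 / tot, NA_real_)
  data.frame(n1 = n1, n2 = n2, f1 = f1, f2 = ifelse(tot > 0, 1 - f1, NA_real_))
}

#' Binomial ecDNA division
#'
#' Doubles the mother's `n` copies and draws daughter 1's share from
#' `Binomial(2n, p)`; daughter 2 receives the remainder. A mother with no
#' copies yields two copy-free daughters. Vectorized over `n`.
#'
#' @param n Non-negative integer founder copy number(s).
#' @param p Segregation probability in (0, 1).
#' @param seed Optional integer seed.
#' @return A data frame with columns `n1`, `n2`, `f1`, `f2` (one row per
#'   division). Inherited fractions are `NA` when both daughters are empty.
#' @examples
#' divide_ecdna(50, p = 0.5, seed = 1)
#' @export
divide_ecdna <- function(n, p = 0.5, seed = NULL) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0) || any(n != floor(n)))
    .stop_param("'n' must contain non-negative integers")
  .check_scalar_number(p, "p", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  .seed_in(seed)
  n1 <- rbinom(length(n), size = 2L * as.integer(n), prob = p)
  .division_outcome(n1, 2L * as.integer(n) - n1)
}

#' Chromosomal division with rare mis-segregation
#'
#' With probability `1 - u` the division is perfect (`n1 = n2 = n`, so
#' `f1 = f2 = 1/2`); with probability `u` one daughter ends up with
#' `n + 1` and the other with `n - 1` copies, the direction chosen with
#' equal probability. Vectorized over `n`.
#'
#' @param n Positive integer copy number(s); chromosomal content is assumed
#'   positive.
#' @param u Mis-segregation probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A data frame with columns `n1`, `n2`, `f1`, `f2`.
#' @examples
#' divide_chromosomal(10, u = 0.05, seed = 1)
#' @export
divide_chromosomal <- function(n, u = 0.05, seed = NULL) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1) || any(n != floor(n)))
    .stop_param("'n' must contain positive integers (chromosomal content)")
  .check_scalar_number(u, "u", 0, 1)
  .seed_in(seed)
  m <- length(n)
  mis <- runif(m) < u
  dir <- ifelse(runif(m) < 0.5, 1L, -1L)
  n1 <- as.integer(n) + ifelse(mis, dir, 0L)
  .division_outcome(n1, 2L * as.integer(n) - n1)
}

.default_founder_sampler <- function(founder_min, founder_max) {
  if (founder_min > founder_max || founder_min < 0)
    .stop_param("degenerate founder range: need 0 <= founder_min <= founder_max")
  force(founder_min); force(founder_max)
  function(m) sample(seq.int(founder_min, founder_max), m, replace = TRUE)
}

.model_fractions <- function(model, n_divisions, founder_sampler) {
  founders <- founder_sampler(n_divisions)
  out <- switch(model$kind,
    ecdna_binomial = divide_ecdna(founders, p = model$p),
    chromosomal = divide_chromosomal(founders, u = model$u))
  # both daughters enter the sample, mirroring paired experimental histograms
  f <- c(out$f1, out$f2)
  f[!is.na(f)]
}

#' Expected distribution of segregated ecDNA fractions
#'
#' Repeats single divisions under a segregation model, each started from a
#' founder copy number drawn from `founder_sampler` (default: discrete
#' uniform on `[20, 200]`, typical of ecDNA-amplified cell lines), and
#' histograms the inherited fractions `f1 = n1/(n1+n2)` of *both* daughters.
#' Recording both daughters makes the distribution exactly symmetric about
#' 1/2 by construction. For unbiased binomial segregation the result is the
#' wide, approximately Gaussian bell centred at 1/2 expected of random
#' segregation; perfect chromosomal segregation concentrates all mass at 1/2.
#'
#' @param model A [segregation_model()].
#' @param n_divisions Number of simulated divisions (default `1e5`).
#' @param founder_sampler Function taking a count and returning that many
#'   integer founder copy numbers; `NULL` for the default uniform sampler.
#' @param founder_min,founder_max Bounds of the default founder sampler.
#' @param bins Number of equal-width histogram bins on `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An object of class `fraction_distribution`: list with `breaks`
#'   (bin edges), `masses` (summing to 1), `fractions` (the raw sample),
#'   `n_divisions` and `model`.
#' @examples
#' fd <- fraction_distribution(segregation_model("ecdna_binomial"),
#'                             n_divisions = 1000, seed = 1)
#' sum(fd$masses)
#' @export
fraction_distribution <- function(model, n_divisions = 1e5,
                                  founder_sampler = NULL,
                                  founder_min = 20, founder_max = 200,
                                  bins = 50, seed = NULL) {
  stopifnot(inherits(model, "segregation_model"))
  .check_scalar_number(n_divisions, "n_divisions", 1, integer = TRUE)
  .check_scalar_number(bins, "bins", 1, integer = TRUE)
  if (is.null(founder_sampler))
    founder_sampler <- .default_founder_sampler(founder_min, founder_max)
  .seed_in(seed)
  f <- .model_fractions(model, n_divisions, founder_sampler)
  breaks <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(findInterval(f, breaks, rightmost.closed = TRUE), 1L), bins)
  masses <- tabulate(idx, nbins = bins) / length(f)
  structure(list(breaks = breaks, masses = masses, fractions = f,
                 n_divisions = n_divisions, model = model),
            class = "fraction_distribution")
}

#' @export
print.fraction_distribution <- function(x, ...) {
  cat(sprintf("Fraction distribution: %d divisions, %d bins, mean f = %.4f\n",
              x$n_divisions, length(x$masses), mean(x$fractions)))
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of observed daughter pairs with a model
#'
#' Converts an observed daughter-pair table to inherited fractions (both
#' daughters pooled), simulates a null fraction sample of size `n_null`
#' under the segregation model, and runs a two-sample Kolmogorov-Smirnov
#' test. Pairs with `n1 + n2 = 0` carry no fraction information and are
#' dropped with a warning.
#'
#' @param observed A daughter-pair table: data frame with integer columns
#'   `n1`, `n2` (see [read_daughter_pairs()] / [make_daughter_pairs()]).
#' @param model A [segregation_model()].
#' @param n_null Size of the simulated null sample (number of divisions).
#' @param founder_sampler,founder_min,founder_max Founder copy-number
#'   sampler for the null sample, as in [fraction_distribution()].
#' @param seed Optional integer seed.
#' @return A `ks_result` (see [ks_two_sample()]).
#' @export
compare_segregation <- function(observed, model, n_null = 1e5,
                                founder_sampler = NULL,
                                founder_min = 20, founder_max = 200,
                                seed = NULL) {
  if (!is.data.frame(observed) || !all(c("n1", "n2") %in% names(observed)))
    .stop_validation("'observed' must be a data frame with columns n1 and n2")
  if (nrow(observed) < 2)
    .stop_validation("need at least 2 observed daughter pairs")
  stopifnot(inherits(model, "segregation_model"))
  tot <- observed$n1 + observed$n2
  if (any(tot == 0)) {
    warning(sprintf("excluding %d daughter pair(s) with zero total signal",
                    sum(tot == 0)))
    observed <- observed[tot > 0, , drop = FALSE]
    if (nrow(observed) < 2)
      .stop_validation("fewer than 2 pairs remain after excluding zero totals")
  }
  f_obs <- c(observed$n1 / (observed$n1 + observed$n2),
             observed$n2 / (observed$n1 + observed$n2))
  if (is.null(founder_sampler))
    founder_sampler <- .default_founder_sampler(founder_min, founder_max)
  .seed_in(seed)
  f_null <- .model_fractions(model, n_null, founder_sampler)
  ks_two_sample(f_obs, f_null)
}
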