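#' Synthetic daughter-pair table
#'
#' Emulates the paired post-mitotic daughter-cell counts obtained by scoring
#' FISH signals in late-mitosis cell pairs (on the order of 100 pairs per
#' cell line). Each pair starts from a founder copy number drawn from
#' `founder_sampler` and is divided once under the segregation model.
#'
#' @param model A [segregation_model()].
#' @param n_pairs Number of daughter pairs (default 100).
#' @param founder_sampler Optional sampler function; default discrete
#'   uniform on `[founder_min, founder_max]`.
#' @param founder_min,founder_max Default founder bounds (20, 200).
#' @param seed Optional integer seed.
#' @return Data frame of class `daughter_pair_table` with columns
#'   `pair_id`, `n1`, `n2`; attributes `model` and `seed`.
#' @export
make_daughter_pairs <- function(model, n_pairs = 100, founder_sampler = NULL,
                                founder_min = 20, founder_max = 200,
                                seed = NULL) {
  stopifnot(inherits(model, "segregation_model"))
  .check_scalar_number(n_pairs, "n_pairs", 1, integer = TRUE)
  if (is.null(founder_sampler))
    founder_sampler <- .default_founder_sampler(founder_min, founder_max)
  .seed_in(seed)
  founders <- founder_sampler(n_pairs)
  div <- switch(model$kind,
    ecdna_binomial = divide_ecdna(founders, p = model$p),
    chromosomal = divide_chromosomal(founders, u = model$u))
  out <- data.frame(pair_id = sprintf("pair_%04d", seq_len(n_pairs)),
                    n1 = div$n1, n2 = div$n2)
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  class(out) <- c("daughter_pair_table", "data.frame")
  out
}

#' Synthetic interphase FISH count table
#'
#' Emulates scoring FISH spots in single interphase nuclei: cells are drawn
#' from a source copy-number distribution and each true copy is detected
#' independently with probability `detection_efficiency` (binomial
#' thinning; no false-positive spots).
#'
#' @param source A `copy_number_distribution` (e.g. from [run_cellline()])
#'   or an integer vector of per-cell copy numbers to resample from.
#' @param n_cells Number of cells to score.
#' @param detection_efficiency Per-copy detection probability in `(0, 1]`
#'   (default 1).
#' @param seed Optional integer seed.
#' @return Data frame of class `cell_count_table` with columns `cell_id`,
#'   `copy_count`; attributes `detection_efficiency` and `seed`.
#' @export
make_fish_table <- function(source, n_cells, detection_efficiency = 1,
                            seed = NULL) {
  .check_scalar_number(n_cells, "n_cells", 1, integer = TRUE)
  .check_scalar_number(detection_efficiency, "detection_efficiency", 0, 1,
                       strict_lower = TRUE)
  .seed_in(seed)
  if (inherits(source, "copy_number_distribution")) {
    true_counts <- sample(source$k, n_cells, replace = TRUE, prob = source$q)
  } else {
    if (!is.numeric(source) || any(source < 0) || any(source != floor(source)))
      .stop_validation("'source' must be a copy_number_distribution or integer counts")
    true_counts <- sample(source, n_cells, replace = TRUE)
  }
  observed <- rbinom(n_cells, size = true_counts, prob = detection_efficiency)
  out <- data.frame(cell_id = sprintf("cell_%06d", seq_len(n_cells)),
                    copy_count = observed)
  attr(out, "detection_efficiency") <- detection_efficiency
  attr(out, "seed") <- seed
  class(out) <- c("cell_count_table", "data.frame")
  out
}

# Droplet-partition concentration estimate: with mean lambda copies per
# droplet, a droplet is positive with probability 1 - exp(-lambda); the
# Poisson estimator inverts the observed negative fraction.
.ddpcr_lambda_hat <- function(lambda, droplets) {
  pos <- rbinom(1, droplets, 1 - exp(-lambda))
  if (pos == droplets)
    .stop_param("ddPCR saturated (all droplets positive); dilute the target (lower lambda_ref)")
  -log((droplets - pos) / droplets)
}

#' Synthetic droplet digital PCR series
#'
#' Adds droplet-counting noise to a true junction-frequency time course.
#' Each measurement partitions the sample into `droplets` droplets; target
#' and reference amplicons get Poisson occupancy at concentrations
#' proportional to the true frequency and to 1, respectively, and the
#' observed frequency is the ratio of the two Poisson concentration
#' estimates `-log(fraction negative)` (normalization to a housekeeping
#' reference amplicon).
#'
#' @param truth Data frame with column `t` plus one or more frequency
#'   columns (e.g. `ecdna_junction_frequency`, `scar_frequency`), such as
#'   the `junction_series` of [run_crispr_c()].
#' @param droplets Droplets per measurement (default 20000, minimum 100).
#' @param lambda_ref Reference-amplicon concentration in copies per droplet
#'   (default 0.25); target concentration is `truth * lambda_ref`.
#' @param seed Optional integer seed.
#' @return Data frame shaped like `truth` with noisy frequency columns;
#'   attributes `droplets`, `lambda_ref`, `seed`.
#' @export
make_ddpcr_series <- function(truth, droplets = 20000, lambda_ref = 0.25,
                              seed = NULL) {
  if (!is.data.frame(truth) || !"t" %in% names(truth))
    .stop_validation("'truth' must be a data frame with a 't' column")
  if (droplets < 100) .stop_param("'droplets' must be >= 100")
  .check_scalar_number(lambda_ref, "lambda_ref", 0, strict_lower = TRUE)
  freq_cols <- setdiff(names(truth), "t")
  if (any(!vapply(truth[freq_cols], is.numeric, logical(1))) ||
      any(vapply(truth[freq_cols], function(v) any(!is.finite(v) | v < 0),
                 logical(1))))
    .stop_validation("frequency columns must be finite and non-negative")
  .seed_in(seed)
  out <- truth
  for (cl in freq_cols) {
    obs <- numeric(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      lam_t <- truth[[cl]][i] * lambda_ref
      ref_hat <- .ddpcr_lambda_hat(lambda_ref, droplets)
      tgt_hat <- if (lam_t == 0) {
        # all-negative droplets (zero positives almost surely at lambda 0)
        0
      } else .ddpcr_lambda_hat(lam_t, droplets)
      obs[i] <- tgt_hat / ref_hat
    }
    out[[cl]] <- obs
  }
  attr(out, "droplets") <- droplets
  attr(out, "lambda_ref") <- lambda_ref
  attr(out, "seed") <- seed
  out
}
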