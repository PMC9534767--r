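#' Piecewise-constant selection schedule
#'
#' Defines the selection coefficient `s(t)` as contiguous segments starting
#' at `t = 0`, e.g. 4 generations of negative selection after ecDNA
#' induction followed by 14 generations of drug selection.
#'
#' @param s Selection coefficient per segment (all > 0).
#' @param durations Segment lengths in generations (all > 0), same length
#'   as `s`.
#' @return Object of class `selection_schedule`: data frame with columns
#'   `t_start`, `t_end`, `s`.
#' @examples
#' selection_schedule(s = c(0.5, 2), durations = c(4, 14))
#' @export
selection_schedule <- function(s, durations) {
  if (length(s) != length(durations) || length(s) == 0)
    .stop_param("'s' and 'durations' must be non-empty and aligned")
  if (any(!is.finite(s)) || any(s <= 0)) .stop_param("all 's' must be > 0")
  if (any(!is.finite(durations)) || any(durations <= 0))
    .stop_param("all 'durations' must be > 0")
  t_end <- cumsum(durations)
  out <- data.frame(t_start = c(0, head(t_end, -1)), t_end = t_end, s = s)
  class(out) <- c("selection_schedule", "data.frame")
  out
}

# Multivariate-hypergeometric downsample of a class-count vector to m cells.
.downsample_counts <- function(counts, m) {
  out <- numeric(length(counts))
  total <- sum(counts)
  for (j in seq_along(counts)) {
    if (m <= 0) break
    x <- stats::rhyper(1, counts[j], total - counts[j], m)
    out[j] <- x
    m <- m - x
    total <- total - counts[j]
  }
  out
}

# Evolve a (no-scar, scar) count pair through a selection schedule with
# culture passaging: on reaching passage_cap the population is randomly
# downsampled (without replacement, jointly over all classes) to passage_to
# and the clock continues. Returns the list of recorded states.
.evolve_schedule <- function(ns, sc, schedule, record_times,
                             passage_cap = Inf, passage_to = NULL,
                             max_events = 1e9) {
  pending <- sort(record_times)
  records <- list()
  t_cur <- 0
  for (i in seq_len(nrow(schedule))) {
    seg_end <- schedule$t_end[i]
    s_seg <- schedule$s[i]
    repeat {
      rts <- pending[pending <= seg_end]
      res <- cpp_gillespie(ns, sc, s_seg, t_start = t_cur, t_end = seg_end,
                           n_cap = passage_cap, record_times = rts,
                           snapshot_sizes = numeric(0),
                           max_events = max_events)
      records <- c(records, res$records)
      if (length(res$records))
        pending <- pending[-seq_along(res$records)]
      ns <- res$counts_noscar
      sc <- res$counts_scar
      t_cur <- res$t
      if (res$reason == "size") {
        joint <- .downsample_counts(c(ns, sc), passage_to)
        ns <- joint[seq_along(ns)]
        sc <- joint[seq_along(sc) + length(ns)]
      } else break
    }
  }
  list(records = records, counts_noscar = ns, counts_scar = sc, t = t_cur)
}

.records_to_series <- function(records) {
  rows <- lapply(records, function(rec) {
    cts <- rec$counts_noscar + rec$counts_scar
    n <- sum(cts)
    k <- seq_along(cts) - 1
    q <- cts / n
    m1 <- sum(k * q)
    m2 <- sum(k^2 * q)
    data.frame(t = rec$t, m1 = m1, m2 = m2, variance = m2 - m1^2,
               frac_pos = 1 - q[1], scar_frequency = sum(rec$counts_scar) / n,
               n = n)
  })
  do.call(rbind, rows)
}

#' Configuration of a CRISPR-derived ecDNA induction experiment
#'
#' In the modelled experiment a CRISPR excision-religation event circularizes
#' a chromosomal segment into an ecDNA in a fraction `q_ecdna` of founder
#' cells (each carrying exactly 1 copy) and leaves a neutral chromosomal
#' "scar" in a fraction `q_scar` of founders. Scar and ecDNA status are
#' assigned independently. The scar is inherited by both daughters at every
#' division, so its population frequency is a martingale whenever division
#' rates do not depend on scar status; ecDNA follows binomial segregation
#' and responds to the selection schedule.
#'
#' @param n0 Founder population size (default `1e4`).
#' @param q_ecdna Fraction of founders carrying the 1-copy ecDNA
#'   (default 0.15).
#' @param q_scar Fraction of founders carrying the chromosomal scar
#'   (default 0.15).
#' @param schedule A [selection_schedule()].
#' @param passage_cap Population size at which the culture is passaged
#'   (randomly downsampled back to `n0`); default `4 * n0`.
#' @param seed Optional integer seed.
#' @return Object of class `crispr_config`.
#' @export
crispr_config <- function(n0 = 1e4, q_ecdna = 0.15, q_scar = 0.15,
                          schedule, passage_cap = 4 * n0, seed = NULL) {
  .check_scalar_number(n0, "n0", 1, integer = TRUE)
  .check_scalar_number(q_ecdna, "q_ecdna", 0, 1)
  .check_scalar_number(q_scar, "q_scar", 0, 1)
  stopifnot(inherits(schedule, "selection_schedule"))
  .check_scalar_number(passage_cap, "passage_cap", n0 + 1)
  structure(list(n0 = as.integer(n0), q_ecdna = q_ecdna, q_scar = q_scar,
                 schedule = schedule, passage_cap = passage_cap, seed = seed),
            class = "crispr_config")
}

#' Simulate a CRISPR-derived ecDNA induction time course
#'
#' Assigns ecDNA (exactly 1 copy) and scar flags to the founder population,
#' evolves it through the selection schedule with the stochastic population
#' model (division rate `s(t)` for ecDNA+ cells, 1 otherwise; scar inert),
#' and reports the two quantities a junction ddPCR assay would measure:
#' the mean number of ecDNA junctions per cell (equal to the mean copy
#' number) and the chromosomal scar frequency.
#'
#' @param config A [crispr_config()].
#' @param record_dt Spacing of recording times (generations, default 0.5).
#' @return List of class `crispr_c_result` with `junction_series` (data
#'   frame: `t`, `ecdna_junction_frequency`, `scar_frequency`), `moments`
#'   (data frame: `t`, `m1`, `m2`, `variance`, `frac_pos`,
#'   `scar_frequency`, `n`) and `config`.
#' @export
run_crispr_c <- function(config, record_dt = 0.5) {
  stopifnot(inherits(config, "crispr_config"))
  .seed_in(config$seed)
  horizon <- max(config$schedule$t_end)
  record_times <- seq(0, horizon, by = record_dt)
  n_ec <- rbinom(1, config$n0, config$q_ecdna)
  scar_ec <- rbinom(1, n_ec, config$q_scar)
  scar_free <- rbinom(1, config$n0 - n_ec, config$q_scar)
  ns <- c(config$n0 - n_ec - scar_free, n_ec - scar_ec)
  sc <- c(scar_free, scar_ec)
  ev <- .evolve_schedule(ns, sc, config$schedule, record_times,
                         passage_cap = config$passage_cap,
                         passage_to = config$n0)
  moments <- .records_to_series(ev$records)
  junction <- data.frame(t = moments$t,
                         ecdna_junction_frequency = moments$m1,
                         scar_frequency = moments$scar_frequency)
  structure(list(junction_series = junction, moments = moments,
                 config = config),
            class = "crispr_c_result")
}

#' @export
print.crispr_c_result <- function(x, ...) {
  m <- x$moments
  cat(sprintf(
    "CRISPR-C scenario: %d time points to t = %g; mean copy %.3f -> %.3f; scar %.3f -> %.3f\n",
    nrow(m), max(m$t), m$m1[1], m$m1[nrow(m)],
    m$scar_frequency[1], m$scar_frequency[nrow(m)]))
  invisible(x)
}

#' Simulate a cell line expansion from a single founder
#'
#' Expands a single founder carrying `k_mean` ecDNA copies (the mean copy
#' number of the cell line being emulated) to `n_target` cells and returns
#' the final copy-number distribution, the object compared against
#' interphase FISH count tables. Under neutrality the distribution is
#' extremely wide: many cells carry few copies and a few cells carry
#' hundreds.
#'
#' @param k_mean Founder copy number (>= 1).
#' @param s Selection coefficient.
#' @param n_target Final population size (default `1e6`).
#' @param seed Optional integer seed.
#' @return A `copy_number_distribution`.
#' @export
run_cellline <- function(k_mean, s = 1, n_target = 1e6, seed = NULL) {
  .check_scalar_number(k_mean, "k_mean", 1, integer = TRUE)
  run <- run_gillespie(sim_config(n0 = k_mean, s = s, n_target = n_target,
                                  snapshot_sizes = numeric(0), seed = seed))
  copy_number_distribution(run$final$counts)
}

#' Drug adaptation and withdrawal of ecDNA copy number
#'
#' Applies a drug phase in which ecDNA+ cells are at a proliferative
#' disadvantage (`s_drug < 1`) followed by a withdrawal phase in which the
#' advantage returns (`s_off > 1`), mirroring the rapid, reversible
#' copy-number shifts seen under targeted therapy. The population-mean
#' copy number drops during the drug phase and recovers after withdrawal.
#'
#' @param init Initial population: a `population_state`, a class-count
#'   vector indexed by `k + 1`, or a `copy_number_distribution` (converted
#'   to expected counts for `n_init` cells).
#' @param s_drug Selection coefficient during the drug phase.
#' @param t_drug Drug phase duration (generations).
#' @param s_off Selection coefficient after withdrawal.
#' @param t_off Withdrawal phase duration.
#' @param n_init Number of cells when `init` is a distribution.
#' @param passage_cap,record_dt As in [run_crispr_c()].
#' @param seed Optional integer seed.
#' @return Data frame of class `drug_shift_series`: the moment series with
#'   an added `phase` column (`"drug"` / `"withdrawal"`).
#' @export
run_drug_shift <- function(init, s_drug = 0.5, t_drug = 4, s_off = 2,
                           t_off = 7, n_init = 1e4, passage_cap = NULL,
                           record_dt = 0.5, seed = NULL) {
  if (inherits(init, "population_state")) counts <- init$counts
  else if (inherits(init, "copy_number_distribution"))
    counts <- round(init$q * n_init)
  else counts <- as.numeric(init)
  if (sum(counts) < 1) .stop_validation("initial population is empty")
  .check_scalar_number(s_drug, "s_drug", 0, strict_lower = TRUE)
  .check_scalar_number(s_off, "s_off", 0, strict_lower = TRUE)
  if (is.null(passage_cap)) passage_cap <- 4 * sum(counts)
  .seed_in(seed)
  sched <- selection_schedule(s = c(s_drug, s_off),
                              durations = c(t_drug, t_off))
  record_times <- seq(0, t_drug + t_off, by = record_dt)
  ev <- .evolve_schedule(counts, numeric(length(counts)), sched,
                         record_times, passage_cap = passage_cap,
                         passage_to = sum(counts))
  out <- .records_to_series(ev$records)
  out$phase <- ifelse(out$t <= t_drug, "drug", "withdrawal")
  class(out) <- c("drug_shift_series", "data.frame")
  out
}
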