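# Plain-text table I/O: tab-separated, header row, UTF-8, Unix newlines.
# Readers validate loudly and raise ecdnadyn_validation_error conditions
# naming the offending row.

.read_tsv_checked <- function(path, expected_cols) {
  if (!file.exists(path)) .stop_validation(sprintf("file not found: %s", path))
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!identical(names(df), expected_cols))
    .stop_validation(sprintf(
      "unexpected columns in %s: got [%s], expected [%s]",
      path, paste(names(df), collapse = ", "),
      paste(expected_cols, collapse = ", ")))
  if (nrow(df) == 0)
    .stop_validation(sprintf("empty table (header only): %s", path))
  df
}

.check_count_column <- function(x, col, path) {
  bad <- which(!is.finite(suppressWarnings(as.numeric(x))) |
                 as.numeric(x) < 0 | as.numeric(x) != floor(as.numeric(x)))
  if (length(bad))
    .stop_validation(sprintf(
      "column '%s' of %s must hold non-negative integers; first offending row: %d",
      col, path, bad[1]))
  as.integer(x)
}

#' Read a per-cell copy-number table
#'
#' Reads a TSV with header `cell_id<TAB>copy_count` (the format of
#' FISH-style per-cell counts) and validates that cell ids are unique and
#' counts are non-negative integers.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `cell_count_table` with columns `cell_id`,
#'   `copy_count`.
#' @export
read_cell_counts <- function(path) {
  df <- .read_tsv_checked(path, c("cell_id", "copy_count"))
  df$copy_count <- .check_count_column(df$copy_count, "copy_count", path)
  df$cell_id <- as.character(df$cell_id)
  dup <- which(duplicated(df$cell_id))
  if (length(dup))
    .stop_validation(sprintf("duplicate cell_id '%s' at row %d of %s",
                             df$cell_id[dup[1]], dup[1], path))
  class(df) <- c("cell_count_table", "data.frame")
  df
}

#' Write a per-cell copy-number table
#'
#' @param table Data frame with columns `cell_id`, `copy_count`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_cell_counts <- function(table, path) {
  if (!all(c("cell_id", "copy_count") %in% names(table)))
    .stop_validation("'table' must have columns cell_id and copy_count")
  write.table(table[, c("cell_id", "copy_count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n",
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a daughter-pair segregation table
#'
#' Reads a TSV with header `pair_id<TAB>n1<TAB>n2` holding the integer copy
#' counts of paired post-mitotic daughter cells. Pairs with
#' `n1 + n2 = 0` carry no segregation information; they are accepted but
#' flagged (attribute `zero_total_rows`) and excluded later by
#' [compare_segregation()].
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `daughter_pair_table` with columns
#'   `pair_id`, `n1`, `n2`.
#' @export
read_daughter_pairs <- function(path) {
  df <- .read_tsv_checked(path, c("pair_id", "n1", "n2"))
  df$n1 <- .check_count_column(df$n1, "n1", path)
  df$n2 <- .check_count_column(df$n2, "n2", path)
  df$pair_id <- as.character(df$pair_id)
  dup <- which(duplicated(df$pair_id))
  if (length(dup))
    .stop_validation(sprintf("duplicate pair_id '%s' at row %d of %s",
                             df$pair_id[dup[1]], dup[1], path))
  zero <- which(df$n1 + df$n2 == 0)
  if (length(zero)) attr(df, "zero_total_rows") <- zero
  class(df) <- c("daughter_pair_table", "data.frame")
  df
}

#' Write a daughter-pair segregation table
#'
#' @param table Data frame with columns `pair_id`, `n1`, `n2` (fractions
#'   are computed downstream, never stored).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_daughter_pairs <- function(table, path) {
  if (!all(c("pair_id", "n1", "n2") %in% names(table)))
    .stop_validation("'table' must have columns pair_id, n1 and n2")
  write.table(table[, c("pair_id", "n1", "n2")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n",
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a scenario configuration file
#'
#' Reads a JSON or YAML file describing a CRISPR-derived induction scenario
#' and builds a [crispr_config()]. Recognized keys: `n0`, `q_ecdna`,
#' `q_scar`, `passage_cap`, `seed`, and `schedule` as a list of segments
#' each with `s` and `duration`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `crispr_config`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) .stop_validation(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    .stop_validation(sprintf("unsupported config format '.%s'", ext)))
  if (is.null(cfg$schedule))
    .stop_validation("config must contain a 'schedule' list")
  seg <- cfg$schedule
  if (is.data.frame(seg)) {
    s_vec <- seg$s
    d_vec <- seg$duration
  } else {
    s_vec <- vapply(seg, function(x) as.numeric(x$s), numeric(1))
    d_vec <- vapply(seg, function(x) as.numeric(x$duration), numeric(1))
  }
  sched <- selection_schedule(s = s_vec, durations = d_vec)
  args <- list(schedule = sched)
  for (key in c("n0", "q_ecdna", "q_scar", "passage_cap", "seed"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  do.call(crispr_config, args)
}
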