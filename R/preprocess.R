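#' Remove ESVs with a low total read count
#'
#' Keeps ESVs whose total count over all samples is at least `min_total`
#' (the keep at equality is inclusive). Applied to the full table before the
#' environment split.
#'
#' @param table An [abundance_table()].
#' @param min_total Minimum total reads per ESV.
#' @return A list with elements `table` (filtered) and `report` (one-row
#'   tibble: `n_esvs_in`, `n_esvs_out`, `n_removed_by_total_reads`).
#' @export
filter_min_total_reads <- function(table, min_total = 25) {
  keep <- rowSums(table$counts) >= min_total
  out <- subset_table(table, esvs = which(keep))
  list(table = out,
       report = tibble(n_esvs_in = n_esvs(table),
                       n_esvs_out = n_esvs(out),
                       n_removed_by_total_reads = sum(!keep)))
}

#' Remove rare and low-prevalence ESVs within an environment table
#'
#' An ESV is removed when its overall relative abundance (row sum over the
#' table's grand total) is below `min_rel_abund` *or* it is present
#' (count > 0) in fewer than `min_prevalence` of the samples; ESVs exactly at
#' either threshold are kept. Intended to run per environment, after
#' [split_by_environment()].
#'
#' @param table An [abundance_table()] restricted to one environment.
#' @param min_rel_abund Minimum overall relative abundance (fraction; the
#'   default 1e-5 is 0.001%).
#' @param min_prevalence Minimum fraction of samples with a nonzero count.
#' @return A list with elements `table` and `report` (removal counts
#'   attributed in order: abundance first, then prevalence).
#' @export
filter_abundance_prevalence <- function(table, min_rel_abund = 1e-5,
                                        min_prevalence = 0.10) {
  grand <- sum(table$counts)
  if (grand == 0) abort("Cannot filter a table with grand total 0.")
  rel <- rowSums(table$counts) / grand
  prev <- rowMeans(table$counts > 0)
  fail_abund <- rel < min_rel_abund
  fail_prev <- prev < min_prevalence
  keep <- !(fail_abund | fail_prev)
  out <- subset_table(table, esvs = which(keep))
  list(table = out,
       report = tibble(
         n_esvs_in = n_esvs(table),
         n_esvs_out = n_esvs(out),
         n_removed_by_abundance = sum(fail_abund),
         n_removed_by_prevalence = sum(fail_prev & !fail_abund)))
}

#' Split an abundance table by environment
#'
#' Partitions the samples by their environment label; ESV rows are retained
#' in every part (per-environment filtering happens after the split).
#'
#' @param table An [abundance_table()] with environment labels.
#' @return A named list of [abundance_table()]s, one per environment, in
#'   order of first appearance.
#' @export
split_by_environment <- function(table) {
  if (is.null(table$environments))
    abort("`table` has no environment labels; attach metadata first.")
  envs <- unique(unname(table$environments))
  setNames(lapply(envs, function(e) {
    subset_table(table, samples = which(table$environments == e))
  }), envs)
}

#' Trim an environment table to a uniform size
#'
#' Keeps the `n_esvs` ESVs with the largest total counts (ties at the cutoff
#' broken by lexicographic ESV id) and a uniformly random subset of
#' `n_samples` samples drawn with `seed`. An environment with fewer than
#' `n_samples` samples cannot be trimmed and raises a classed condition
#' (`coocnet_trim_exclusion`) rather than silently truncating; see
#' [trim_all()] for the convenience wrapper that drops such environments.
#'
#' @param table An [abundance_table()].
#' @param n_esvs Number of top-abundant ESVs to keep (all if fewer exist).
#' @param n_samples Number of samples to keep.
#' @param seed Integer seed for the sample draw.
#' @return A trimmed [abundance_table()].
#' @export
trim_dataset <- function(table, n_esvs = 400, n_samples = 360, seed = 1) {
  if (n_samples(table) < n_samples)
    abort(sprintf(
      "Environment has %d samples, fewer than the %d required for trimming.",
      n_samples(table), n_samples),
      class = "coocnet_trim_exclusion")
  tot <- rowSums(table$counts)
  ord <- order(-tot, rownames(table$counts))
  keep_esvs <- sort(ord[seq_len(min(n_esvs, length(ord)))])
  set.seed(seed)
  keep_samples <- sort(sample.int(n_samples(table), n_samples))
  subset_table(table, esvs = keep_esvs, samples = keep_samples)
}

#' Trim several environment tables, dropping the too-small ones
#'
#' @param tables Named list of [abundance_table()]s (as from
#'   [split_by_environment()]).
#' @inheritParams trim_dataset
#' @return A named list of trimmed tables; environments with too few samples
#'   are dropped with a message.
#' @export
trim_all <- function(tables, n_esvs = 400, n_samples = 360, seed = 1) {
  out <- list()
  for (env in names(tables)) {
    res <- tryCatch(
      trim_dataset(tables[[env]], n_esvs, n_samples, seed = seed),
      coocnet_trim_exclusion = function(cnd) NULL)
    if (is.null(res)) {
      message(sprintf("Excluding environment '%s': %d samples < %d.",
                      env, n_samples(tables[[env]]), n_samples))
    } else {
      out[[env]] <- res
    }
  }
  out
}

#' Run the standard preprocessing chain
#'
#' Total-read filter on the full table, split by environment, then the
#' per-environment abundance/prevalence filter.
#'
#' @param table An [abundance_table()] with environment labels.
#' @inheritParams filter_min_total_reads
#' @inheritParams filter_abundance_prevalence
#' @return A list with `tables` (named list of per-environment filtered
#'   tables) and `report` (per-environment tibble of filter counts).
#' @export
preprocess_pipeline <- function(table, min_total = 25, min_rel_abund = 1e-5,
                                min_prevalence = 0.10) {
  step1 <- filter_min_total_reads(table, min_total)
  parts <- split_by_environment(step1$table)
  filtered <- lapply(parts, filter_abundance_prevalence,
                     min_rel_abund = min_rel_abund,
                     min_prevalence = min_prevalence)
  report <- dplyr::bind_rows(lapply(names(filtered), function(e) {
    dplyr::mutate(filtered[[e]]$report, environment = e,
                  n_samples = n_samples(filtered[[e]]$table),
                  .before = 1)
  }))
  list(tables = lapply(filtered, `[[`, "table"), report = report,
       total_reads_report = step1$report)
}
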