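#' Construct an ESV-by-sample abundance table
#'
#' The package's core container: a non-negative integer count matrix with
#' exact sequence variants (ESVs) as rows and samples as columns, optionally
#' carrying one environment label per sample.
#'
#' @param counts Numeric matrix of non-negative integer counts with unique
#'   rownames (ESV ids) and colnames (sample ids).
#' @param environments Either `NULL`, a named character vector mapping sample
#'   id to environment label, or a two-column data frame with columns
#'   `sample_id` and `environment`.
#' @return An object of class `abundance_table`: a list with elements
#'   `counts` (integer matrix) and `environments` (named character vector or
#'   `NULL`).
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("esv1", "esv2"), c("s1", "s2")))
#' abundance_table(m, c(s1 = "soil", s2 = "soil"))
#' @export
abundance_table <- function(counts, environments = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    abort("`counts` must have rownames (ESV ids).")
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    abort("`counts` must have colnames (sample ids).")
  if (anyDuplicated(rownames(counts)))
    abort("Duplicated ESV ids in `counts` rownames.")
  if (anyDuplicated(colnames(counts)))
    abort("Duplicated sample ids in `counts` colnames.")
  if (length(counts) > 0) {
    if (anyNA(counts)) abort("`counts` must not contain NA.")
    if (any(counts < 0)) abort("`counts` must be non-negative.")
    if (any(counts != round(counts)))
      abort("`counts` must be integral (read counts).")
  }
  storage.mode(counts) <- "double"
  env <- normalize_environments(environments, colnames(counts))
  structure(list(counts = counts, environments = env),
            class = "abundance_table")
}

normalize_environments <- function(environments, sample_ids) {
  if (is.null(environments)) return(NULL)
  if (is.data.frame(environments)) {
    if (!all(c("sample_id", "environment") %in% names(environments)))
      abort("Metadata must have columns `sample_id` and `environment`.")
    environments <- setNames(as.character(environments$environment),
                             as.character(environments$sample_id))
  }
  if (is.null(names(environments)))
    abort("`environments` must be named by sample id.")
  dup <- duplicated(names(environments))
  if (any(dup)) {
    # consistent duplicates collapse, conflicting ones are an error
    split_env <- split(unname(environments), names(environments))
    bad <- names(split_env)[vapply(split_env, function(v)
      length(unique(v)) > 1, logical(1))]
    if (length(bad) > 0)
      abort(paste0("Conflicting environment labels for sample(s): ",
                   paste(bad, collapse = ", ")))
    environments <- environments[!dup]
  }
  missing <- setdiff(sample_ids, names(environments))
  if (length(missing) > 0)
    abort(paste0("Samples without environment label: ",
                 paste(head(missing, 5), collapse = ", ")))
  setNames(as.character(environments[sample_ids]), sample_ids)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d ESVs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$environments)) {
    tab <- table(x$environments)
    cat("environments:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as_tibble.abundance_table <- function(x, ...) {
  if (length(x$counts) == 0)
    return(tibble(esv_id = character(), sample_id = character(),
                  count = double(), environment = character()))
  out <- tibble(
    esv_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
  if (!is.null(x$environments))
    out$environment <- unname(x$environments[out$sample_id])
  out
}

n_esvs <- function(table) nrow(table$counts)
n_samples <- function(table) ncol(table$counts)

#' Relative abundances of an abundance table
#'
#' Columns (samples) are scaled to sum to one; all-zero samples stay zero.
#'
#' @param table An [abundance_table()].
#' @return A numeric matrix of the same shape as `table$counts`.
#' @export
relative_abundances <- function(table) {
  tot <- colSums(table$counts)
  tot[tot == 0] <- 1
  sweep(table$counts, 2, tot, "/")
}

subset_table <- function(table, esvs = NULL, samples = NULL) {
  counts <- table$counts
  if (!is.null(esvs)) counts <- counts[esvs, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  env <- table$environments
  if (!is.null(env)) env <- env[colnames(counts)]
  abundance_table(counts, env)
}

#' Read an abundance table from TSV or BIOM
#'
#' The TSV dialect is: first column ESV id (any header), remaining header
#' fields are sample ids, cells are tab-separated integer counts. BIOM files
#' (HDF5 or JSON) are read through the biomformat package.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @param metadata Optional metadata: a path to a metadata TSV (see
#'   [read_metadata()]), a data frame, or a named character vector of
#'   environment labels.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom"),
                                 metadata = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    ids <- df[[1]]
    m <- suppressWarnings(
      vapply(df[-1], as.numeric, numeric(nrow(df))))
    if (nrow(df) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(df)[-1]))
    if (nrow(df) == 0) m <- matrix(0, 0, ncol(df) - 1,
                                   dimnames = list(NULL, names(df)[-1]))
    rownames(m) <- ids
    if (length(m) > 0 && any(is.na(m) | m < 0 | m != round(m))) {
      bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "Malformed abundance TSV '%s': bad count at row %d (ESV '%s'), column '%s'.",
        path, bad[1], ids[bad[1]], colnames(m)[bad[2]]))
    }
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      abort("Reading BIOM requires the biomformat package.")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
  }
  env <- NULL
  if (!is.null(metadata)) {
    if (is.character(metadata) && length(metadata) == 1 && is.null(names(metadata)))
      metadata <- read_metadata(metadata)
    env <- metadata
  }
  abundance_table(m, env)
}

#' Write an abundance table as TSV
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  df <- as.data.frame(table$counts)
  df <- cbind(esv_id = rownames(table$counts), df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata (environment labels)
#'
#' Expects a TSV with columns `sample_id` and `environment`. Duplicate rows
#' with identical labels are deduplicated; conflicting duplicates are an
#' error. Unknown environment strings are accepted verbatim.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with columns `sample_id` and `environment`.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (!all(c("sample_id", "environment") %in% names(df)))
    abort(sprintf("Metadata '%s' must have columns sample_id, environment.",
                  path))
  df <- dplyr::distinct(df[, c("sample_id", "environment")])
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0)
    abort(paste0("Conflicting environment labels for sample(s): ",
                 paste(unique(dup), collapse = ", ")))
  df
}

#' Write sample metadata as TSV
#'
#' @param metadata A tibble with columns `sample_id` and `environment`, or a
#'   named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  if (!is.data.frame(metadata))
    metadata <- tibble(sample_id = names(metadata),
                       environment = unname(metadata))
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with column `esv_id` followed by ranked lineage columns
#' (domain, phylum, class, order, family, genus); missing ranks may be the
#' string `"unclassified"` or empty.
#'
#' @param path Path to the taxonomy TSV.
#' @return A tibble with `esv_id` and whatever rank columns the file has;
#'   empty cells become `"unclassified"`.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (!"esv_id" %in% names(df))
    abort(sprintf("Taxonomy '%s' must have an esv_id column.", path))
  dplyr::mutate(df, dplyr::across(-"esv_id",
    ~ dplyr::if_else(is.na(.x) | .x == "", "unclassified", .x)))
}
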