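#' Standard columns of a long-format trial table
#'
#' A trial dataset is a long-format table with one row per individual:
#' `individual_id`, `cluster_id` (opaque labels), `arm` (0 = control,
#' 1 = intervention), `x` (individual-level covariate), `w` (cluster-level
#' covariate, constant within cluster), the two partially observed outcomes
#' `y1`, `y2`, and non-response indicators `r1`, `r2` (1 = missing).
#'
#' @keywords internal
trial_columns <- c(
  "individual_id", "cluster_id", "arm", "x", "w", "y1", "y2", "r1", "r2"
)

#' Validate a trial dataset
#'
#' Checks the invariants of the long-format trial table: required columns,
#' arm codes in \{0, 1\}, `arm` and `w` constant within each cluster, `y1`/`y2`
#' missing exactly where `r1`/`r2` equal 1, and at least one cluster per arm.
#' Missing `r1`/`r2` columns are derived from `is.na(y1)`/`is.na(y2)`.
#'
#' @param data A data frame of individual records.
#' @return The validated data as a tibble (invisibly usable in pipes).
#' @examples
#' d <- tibble::tibble(
#'   individual_id = as.character(1:4), cluster_id = c("a", "a", "b", "b"),
#'   arm = c(0, 0, 1, 1), x = rnorm(4), w = c(1, 1, -1, -1),
#'   y1 = rnorm(4), y2 = rnorm(4)
#' )
#' validate_trial(d)
#' @export
validate_trial <- function(data) {
  data <- tibble::as_tibble(data)
  need <- setdiff(c("individual_id", "cluster_id", "arm", "x", "w", "y1", "y2"),
                  names(data))
  if (length(need) > 0) {
    abort(sprintf("trial data is missing column(s): %s",
                  paste(need, collapse = ", ")))
  }
  if (!("r1" %in% names(data))) data$r1 <- as.integer(is.na(data$y1))
  if (!("r2" %in% names(data))) data$r2 <- as.integer(is.na(data$y2))
  data$individual_id <- as.character(data$individual_id)
  data$cluster_id <- as.character(data$cluster_id)
  if (nrow(data) == 0) abort("trial data has no records")

  arm_num <- suppressWarnings(as.numeric(data$arm))
  if (anyNA(arm_num) || !all(arm_num %in% c(0, 1))) {
    abort("`arm` codes must be coercible to {0, 1}")
  }
  data$arm <- as.integer(arm_num)

  for (col in c("x", "w", "y1", "y2")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  for (col in c("r1", "r2")) {
    if (!all(data[[col]] %in% c(0, 1))) {
      abort(sprintf("`%s` must be 0/1", col))
    }
    data[[col]] <- as.integer(data[[col]])
  }
  if (!identical(is.na(data$y1), data$r1 == 1L) ||
      !identical(is.na(data$y2), data$r2 == 1L)) {
    abort("outcome must be absent exactly where its non-response flag is 1")
  }

  by_cl <- split(seq_len(nrow(data)), factor(data$cluster_id,
                                             levels = unique(data$cluster_id)))
  for (cl in names(by_cl)) {
    rows <- by_cl[[cl]]
    if (length(unique(data$arm[rows])) > 1) {
      abort(sprintf("`arm` varies within cluster '%s'", cl))
    }
    if (length(unique(data$w[rows])) > 1) {
      abort(sprintf("cluster-level covariate `w` varies within cluster '%s'", cl))
    }
  }
  arms <- vapply(by_cl, function(rows) data$arm[rows[1]], integer(1))
  if (!all(c(0L, 1L) %in% arms)) {
    abort("each arm must contain at least one cluster")
  }
  data
}

#' Read a long-format trial CSV
#'
#' Reads a per-individual trial table. Empty outcome cells (or any value in
#' `na`) become missing values with the corresponding non-response flag set.
#' Column names may be remapped through `schema`, a named character vector
#' `c(standard_name = "file_column")`.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector remapping file columns onto
#'   the standard names `individual_id`, `cluster_id`, `arm`, `x`, `w`,
#'   `y1`, `y2`.
#' @param na Strings read as missing (default empty string and `"NA"`).
#' @return A validated trial tibble.
#' @seealso [write_trial_csv()], [validate_trial()]
#' @export
read_trial_csv <- function(path, schema = NULL, na = c("", "NA")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, na = na, show_col_types = FALSE,
                         progress = FALSE)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0) {
      abort(sprintf("schema column(s) not in file: %s",
                    paste(missing_src, collapse = ", ")))
    }
    for (std in names(schema)) {
      raw[[std]] <- raw[[schema[[std]]]]
    }
  }
  # non-response flags are derived from cell emptiness, the file's own
  # r columns (if any) are ignored
  raw$r1 <- NULL
  raw$r2 <- NULL
  validate_trial(raw[intersect(trial_columns, names(raw))])
}

#' Write a trial dataset to CSV
#'
#' Writes the standard long format; absent outcome values are written as empty
#' fields, so `read_trial_csv(write_trial_csv(d))` reproduces `d` record for
#' record.
#'
#' @param data A valid trial data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  data <- validate_trial(data)
  readr::write_csv(data[trial_columns], path, na = "", progress = FALSE)
  invisible(path)
}

#' Restrict to complete cases
#'
#' Keeps exactly the records with both outcomes observed (`r1 = 0` and
#' `r2 = 0`) -- the complete cases of the bivariate substantive model; records
#' with either outcome missing are dropped, as are clusters left empty.
#'
#' @param data A valid trial data frame.
#' @return A trial tibble of fully observed records.
#' @examples
#' d <- generate_trial(scenario(J = 4, sizes = fixed_sizes(5)), seed = 1)
#' nrow(complete_cases(d)) # no missingness: identical record count
#' @export
complete_cases <- function(data) {
  data <- validate_trial(data)
  kept <- data[data$r1 == 0L & data$r2 == 0L, , drop = FALSE]
  if (nrow(kept) == 0 || length(unique(kept$arm)) < 2) {
    abort(paste("complete-case restriction leaves an arm with no clusters;",
                "the complete-case analysis is degenerate"))
  }
  kept
}
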