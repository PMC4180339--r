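#' Construct a response matrix
#'
#' The persons-by-items integer matrix of observed category codes
#' (0-based), optionally carrying per-person categorical covariates.
#' Analyses operate on complete cases only: missing cells are rejected at
#' construction time, mirroring a complete-responders analysis set.
#'
#' @param responses integer matrix, persons x items, entries in `0..m`.
#' @param person_ids unique person identifiers (default `1..n`).
#' @param covariates optional data.frame of per-person categorical
#'   covariates (e.g. `gender`, `age_band`, `education`, `mode`).
#' @param n_categories number of response categories `m + 1` (default:
#'   inferred as `max(responses) + 1`, at least 2).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(responses, person_ids = NULL, covariates = NULL,
                            n_categories = NULL) {
  responses <- as.matrix(responses)
  if (nrow(responses) == 0L) stop("empty dataset: no persons")
  if (any(is.na(responses)))
    stop("missing responses are not accepted (complete cases only); ",
         "first missing cell at row ",
         which(rowSums(is.na(responses)) > 0)[1])
  if (any(responses != round(responses)))
    stop("responses must be integer category codes")
  storage.mode(responses) <- "integer"
  if (is.null(n_categories)) n_categories <- max(2L, max(responses) + 1L)
  bad <- which(responses < 0L | responses >= n_categories, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("response out of range 0..%d at row %d, column %d",
                 n_categories - 1L, bad[1, 1], bad[1, 2]))
  n <- nrow(responses)
  if (is.null(person_ids)) person_ids <- seq_len(n)
  if (anyDuplicated(person_ids)) stop("person_ids must be unique")
  if (length(person_ids) != n) stop("person_ids length mismatch")
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item_", seq_len(ncol(responses)))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != n) stop("covariates row count mismatch")
    covariates[] <- lapply(covariates, as.character)
  }
  structure(list(responses = responses, person_ids = person_ids,
                 covariates = covariates,
                 n_persons = n, n_items = ncol(responses),
                 n_categories = as.integer(n_categories)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d persons x %d items (categories 0..%d)\n",
              x$n_persons, x$n_items, x$n_categories - 1L))
  if (!is.null(x$covariates))
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

.known_covariates <- c("gender", "age_band", "education", "mode")

#' Load a response matrix from CSV
#'
#' Expected layout: one row per person with a `person_id` column, one
#' `item_<id>` column per bank item, and optional covariate columns
#' (`gender`, `age_band`, `education`, `mode`). Entries must be complete
#' integer category codes in `0..m`.
#'
#' @param path CSV path.
#' @param bank an [item_bank()]; item columns are matched against its ids
#'   and category range.
#' @return A [response_matrix()].
#' @export
load_response_matrix <- function(path, bank) {
  stopifnot(inherits(bank, "item_bank"))
  if (!file.exists(path)) stop("response file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  item_cols <- paste0("item_", bank$id)
  missing <- setdiff(item_cols, names(df))
  if (length(missing))
    stop("response format error: missing item column(s) ",
         paste(missing, collapse = ", "))
  resp <- as.matrix(df[, item_cols])
  if (any(is.na(resp))) {
    bad <- which(is.na(resp), arr.ind = TRUE)[1, ]
    stop(sprintf("missing response at row %d, column %s (complete cases only)",
                 bad[1], item_cols[bad[2]]))
  }
  m <- bank$n_categories - 1L
  out <- which(resp < 0 | resp > m, arr.ind = TRUE)
  if (nrow(out) > 0)
    stop(sprintf("response out of range 0..%d at row %d, column %s",
                 m, out[1, 1], item_cols[out[1, 2]]))
  covs <- intersect(.known_covariates, names(df))
  covariates <- if (length(covs)) {
    cv <- df[, covs, drop = FALSE]
    cv[] <- lapply(cv, function(z) tolower(trimws(as.character(z))))
    cv
  } else NULL
  ids <- if ("person_id" %in% names(df)) df$person_id else seq_len(nrow(df))
  response_matrix(resp, person_ids = ids, covariates = covariates,
                  n_categories = bank$n_categories)
}

#' Write a response matrix to CSV
#'
#' Canonical dialect: comma separator, `.` decimal, header row, UTF-8.
#' Reading the file back with [load_response_matrix()] reproduces the
#' object exactly.
#'
#' @param x a [response_matrix()]; @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(x, path) {
  stopifnot(inherits(x, "response_matrix"))
  df <- data.frame(person_id = x$person_ids, x$responses,
                   check.names = FALSE)
  if (!is.null(x$covariates)) df <- cbind(df, x$covariates)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pre-fit validation report
#'
#' Tabulates per-item category counts and flags items with empty
#' categories, which cannot support threshold estimation without
#' collapsing. Report-only: no error is raised for flagged items.
#'
#' @param x a [response_matrix()]; @param bank an [item_bank()].
#' @return list with `counts` (items x categories), `flags` (item ids with
#'   at least one empty category), `n_persons`.
#' @export
validate_dataset <- function(x, bank) {
  stopifnot(inherits(x, "response_matrix"), inherits(bank, "item_bank"))
  if (x$n_items != bank$n_items)
    stop(sprintf("matrix has %d items but bank has %d", x$n_items,
                 bank$n_items))
  m <- bank$n_categories - 1L
  counts <- t(apply(x$responses, 2, function(col)
    tabulate(col + 1L, nbins = m + 1L)))
  dimnames(counts) <- list(paste0("item_", bank$id), paste0("cat_", 0:m))
  flags <- bank$id[rowSums(counts == 0) > 0]
  structure(list(counts = counts, flags = flags, n_persons = x$n_persons),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation: %d persons\n", x$n_persons))
  print(x$counts)
  if (length(x$flags))
    cat("items with empty categories:", paste(x$flags, collapse = ", "), "\n")
  else cat("no empty categories\n")
  invisible(x)
}
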