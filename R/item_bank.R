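#' Construct an item bank
#'
#' An item bank holds the graded-response-model parameters of an ordered
#' polytomous scale: one discrimination `alpha` and a strictly increasing
#' vector of threshold parameters `beta` per item. All items in a bank must
#' share the same number of response categories (`m + 1` where `m` is the
#' number of thresholds).
#'
#' @param id integer item ids, unique and contiguous from 1.
#' @param label character item labels.
#' @param alpha positive numeric discriminations.
#' @param betas numeric matrix (items x thresholds), strictly increasing
#'   within each row.
#' @return An object of class `item_bank`: a list with elements `id`,
#'   `label`, `alpha`, `betas`, `n_items`, `n_categories`.
#' @examples
#' b <- item_bank(1:2, c("a", "b"), c(1.2, 2), rbind(c(-1, 0.5), c(0, 1)))
#' b$n_categories
#' @export
item_bank <- function(id, label, alpha, betas) {
  betas <- as.matrix(betas)
  id <- as.integer(id)
  k <- length(id)
  if (k == 0L) stop("item bank is empty")
  if (anyDuplicated(id) || !identical(sort(id), seq_len(k)))
    stop("item ids must be unique and contiguous from 1")
  if (length(label) != k || length(alpha) != k || nrow(betas) != k)
    stop("id, label, alpha and betas must describe the same number of items")
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be positive for every item; offending item(s): ",
         paste(id[!is.finite(alpha) | alpha <= 0], collapse = ", "))
  if (any(!is.finite(betas))) stop("betas must be finite")
  if (ncol(betas) >= 2) {
    bad <- which(apply(betas, 1, function(b) any(diff(b) <= 0)))
    if (length(bad))
      stop("betas must be strictly increasing; offending item(s): ",
           paste(id[bad], collapse = ", "))
  }
  ord <- order(id)
  structure(list(id = id[ord], label = as.character(label)[ord],
                 alpha = as.numeric(alpha)[ord],
                 betas = betas[ord, , drop = FALSE],
                 n_items = k, n_categories = ncol(betas) + 1L),
            class = "item_bank")
}

#' Load an item bank from CSV or JSON
#'
#' CSV files must carry a header row with columns `id,label,alpha,beta1,
#' beta2[,beta3...]` (comma separator, `.` decimal). JSON files mirror the
#' same fields as an array of item records.
#'
#' @param path path to a `.csv` or `.json` file.
#' @return An [item_bank()].
#' @export
load_item_bank <- function(path) {
  if (!file.exists(path)) stop("item bank file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path)
    df <- as.data.frame(rec, stringsAsFactors = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  beta_cols <- grep("^beta[0-9]+$", names(df), value = TRUE)
  need <- c("id", "label", "alpha")
  missing <- setdiff(need, names(df))
  if (length(missing) || length(beta_cols) == 0)
    stop("item bank format error: missing column(s) ",
         paste(c(missing, if (!length(beta_cols)) "beta1"), collapse = ", "))
  beta_cols <- beta_cols[order(as.integer(sub("beta", "", beta_cols)))]
  item_bank(df$id, df$label, df$alpha,
            as.matrix(df[, beta_cols, drop = FALSE]))
}

#' Write an item bank to CSV or JSON
#'
#' @param bank an [item_bank()].
#' @param path destination; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  df <- as.data.frame(bank)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE, quote = which(names(df) == "label"))
  }
  invisible(path)
}

#' @export
as.data.frame.item_bank <- function(x, ...) {
  b <- x$betas
  colnames(b) <- paste0("beta", seq_len(ncol(b)))
  data.frame(id = x$id, label = x$label, alpha = x$alpha, b,
             stringsAsFactors = FALSE)
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Item bank: %d items, %d response categories (0..%d)\n",
              x$n_items, x$n_categories, x$n_categories - 1L))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Subset an item bank (re-indexing is NOT performed; ids are preserved)
#' @param x an `item_bank`; @param i item ids to keep.
#' @return list with the selected items' parameters (not a full bank, since
#'   ids would no longer be contiguous).
#' @keywords internal
#' @noRd
bank_items <- function(x, i) {
  idx <- match(i, x$id)
  if (anyNA(idx)) stop("item id(s) not in bank: ",
                       paste(i[is.na(idx)], collapse = ", "))
  list(id = x$id[idx], alpha = x$alpha[idx],
       betas = x$betas[idx, , drop = FALSE])
}

#' The default 19-item suicide-ideation bank
#'
#' Returns the bank of 19 ordered polytomous items (categories 0/1/2) with
#' published graded-response-model discriminations and thresholds that the
#' package uses as its default instrument.
#'
#' @return An [item_bank()] with 19 items and 3 categories.
#' @examples
#' default_item_bank()$alpha[7]  # 4.117, the most discriminating item
#' @export
default_item_bank <- function() {
  load_item_bank(system.file("extdata", "bss_nl_bank.csv",
                             package = "grmcat", mustWork = TRUE))
}
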