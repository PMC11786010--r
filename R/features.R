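#' Engineered ratio features
#'
#' The sum and product of the two vertebral ratios are carried as additional
#' features: the sum behaves like a pooled size-independent maturation index
#' and the product amplifies the joint growth signal.
#'
#' @param c3,c4 Positive dimensionless ratios (vectorised).
#' @return Tibble with columns `sum` (`c3 + c4`) and `prod` (`c3 * c4`).
#' @export
#' @examples
#' engineer_features(0.74, 0.68)
engineer_features <- function(c3, c4) {
  if (length(c3) != length(c4)) {
    abort("`c3` and `c4` must have equal length.")
  }
  if (any(!is.finite(c3)) || any(!is.finite(c4)) ||
      any(c3 <= 0) || any(c4 <= 0)) {
    abort("Ratios must be finite and strictly positive.")
  }
  tibble::tibble(sum = c3 + c4, prod = c3 * c4)
}

#' Add engineered feature columns to a dataset table
#'
#' Recomputes `SumC3C4` and `C3C4` from the `C3` and `C4` columns.
#'
#' @param data Data frame with columns `C3` and `C4`.
#' @return `data` as a tibble with `SumC3C4` and `C3C4` (re)computed.
#' @export
add_ratio_features <- function(data) {
  if (!all(c("C3", "C4") %in% names(data))) {
    abort("`data` must contain columns C3 and C4.")
  }
  f <- engineer_features(data$C3, data$C4)
  data <- tibble::as_tibble(data)
  data$SumC3C4 <- f$sum
  data$C3C4 <- f$prod
  data
}

#' Collapse six cervical vertebral maturation stages to three classes
#'
#' The six-stage visual classification (CVS1-CVS6) is grouped into the
#' clinically relevant three-class scheme: pre-peak of mandibular growth
#' (CVS1-2, class 1), peak (CVS3-4, class 2), post-peak (CVS5-6, class 3).
#'
#' @param cvs Integer vector of stages in 1..6.
#' @return Integer vector of classes in 1..3.
#' @export
#' @examples
#' map_cvm_stage(1:6)
map_cvm_stage <- function(cvs) {
  if (any(!is.finite(cvs)) || any(cvs != as.integer(cvs)) ||
      any(cvs < 1) || any(cvs > 6)) {
    abort("CVM stages must be integers in 1..6.")
  }
  as.integer(ceiling(cvs / 2))
}

.dataset_cols <- c("id", "age", "gender", "C3", "C4", "SumC3C4", "C3C4",
                   "Maturation")

.validate_dataset <- function(data, arg = "data") {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort(sprintf("`%s` must be a non-empty data frame.", arg))
  }
  missing <- setdiff(.dataset_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Dataset is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyNA(data[.dataset_cols])) {
    bad <- .dataset_cols[vapply(data[.dataset_cols], anyNA, logical(1))]
    abort(paste0("Dataset has missing values in: ",
                 paste(bad, collapse = ", ")))
  }
  if (!all(data$Maturation %in% 1:3)) {
    abort("`Maturation` must contain only classes 1, 2, 3.")
  }
  if (anyDuplicated(data$id)) {
    abort("Dataset ids must be unique.")
  }
  invisible(data)
}

#' Split a dataset table into training and test partitions
#'
#' By default the split is stratified by maturation class so that every class
#' appears in both partitions in its original proportion (within one row per
#' class); `stratify = FALSE` gives a plain random split.
#'
#' @param data Dataset table (columns `id`, `age`, `gender`, `C3`, `C4`,
#'   `SumC3C4`, `C3C4`, `Maturation`).
#' @param test_fraction Proportion of rows held out for testing.
#' @param seed Integer seed; identical seed gives an identical partition.
#' @param stratify Stratify by `Maturation`?
#' @return An object of class `cvd_split`: a list with tibbles `train` and
#'   `test` plus the `seed` and `test_fraction` used.
#' @export
split_dataset <- function(data, test_fraction = 0.2, seed = 1,
                          stratify = TRUE) {
  .validate_dataset(data)
  if (!is.numeric(test_fraction) || length(test_fraction) != 1 ||
      test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie strictly between 0 and 1.")
  }
  if (nrow(data) < 5) {
    abort("Dataset must have at least 5 rows to split.")
  }
  data <- tibble::as_tibble(data)
  test_idx <- with_seed(seed, {
    if (stratify) {
      unlist(lapply(split(seq_len(nrow(data)), data$Maturation), function(ix) {
        n_test <- round(test_fraction * length(ix))
        sample(ix, n_test)
      }), use.names = FALSE)
    } else {
      sample(seq_len(nrow(data)), round(test_fraction * nrow(data)))
    }
  })
  structure(
    list(
      train = data[-test_idx, , drop = FALSE],
      test = data[test_idx, , drop = FALSE],
      seed = seed,
      test_fraction = test_fraction
    ),
    class = "cvd_split"
  )
}

#' @export
print.cvd_split <- function(x, ...) {
  cat(sprintf(
    "<cvd_split> train: %d rows, test: %d rows (fraction %.2f, seed %d)\n",
    nrow(x$train), nrow(x$test), x$test_fraction, x$seed))
  invisible(x)
}

.label_text_map <- c("pre-peak" = 1L, "prepeak" = 1L, "pre peak" = 1L,
                     "peak" = 2L,
                     "post-peak" = 3L, "postpeak" = 3L, "post peak" = 3L)

#' Read or write a dataset table as CSV
#'
#' The CSV dialect is comma-separated with a header row, UTF-8, `.` decimal
#' mark, and columns `id`, `age`, `gender`, `C3`, `C4`, `SumC3C4`, `C3C4`,
#' `Maturation` (header matching is case-insensitive for the lowercase
#' columns). Text maturation labels (`pre-peak`, `peak`, `post-peak`) are
#' mapped to classes 1/2/3 on read. Missing columns, missing values and
#' unmapped labels raise schema errors naming the offending column or value.
#'
#' @param path CSV file path.
#' @return For `read_dataset`, a validated dataset tibble.
#' @export
read_dataset <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  nm <- names(raw)
  for (col in .dataset_cols) {
    hit <- which(tolower(nm) == tolower(col))
    if (length(hit) == 1) names(raw)[hit] <- col
  }
  missing <- setdiff(.dataset_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Dataset file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (is.character(raw$Maturation)) {
    key <- tolower(trimws(raw$Maturation))
    mapped <- .label_text_map[key]
    numeric_ok <- suppressWarnings(as.integer(key))
    mapped[is.na(mapped)] <- numeric_ok[is.na(mapped)]
    if (anyNA(mapped)) {
      bad <- unique(raw$Maturation[is.na(mapped)])
      abort(paste0("Unmapped maturation label(s): ",
                   paste(bad, collapse = ", ")))
    }
    raw$Maturation <- as.integer(mapped)
  }
  if (is.numeric(raw$Maturation) && !anyNA(raw$Maturation) &&
      all(raw$Maturation == as.integer(raw$Maturation))) {
    raw$Maturation <- as.integer(raw$Maturation)
  }
  raw$id <- as.character(raw$id)
  .validate_dataset(raw)
  tibble::as_tibble(raw[.dataset_cols])
}

#' @rdname read_dataset
#' @param data Dataset table to write.
#' @export
write_dataset <- function(data, path) {
  .validate_dataset(data)
  readr::write_csv(data[.dataset_cols], path)
  invisible(path)
}
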