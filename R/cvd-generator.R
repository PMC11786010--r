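#' Per-class generative ranges fitted from training data
#'
#' For each maturation class, records the observed minimum and maximum of the
#' `C3` and `C4` ratios (the support of the augmentation sampler) together
#' with the class age distribution (mean, SD, observed range), the male
#' proportion, and the class size. Ranges are derived exclusively from the
#' rows supplied, so pass training data only.
#'
#' @param train Training dataset table; every class in 1..3 needs at least
#'   two rows.
#' @return A tibble with one row per class, columns `Maturation`, `n`,
#'   `c3_min`, `c3_max`, `c4_min`, `c4_max`, `c3_mean`, `c3_sd`, `c4_mean`,
#'   `c4_sd`, `age_mean`, `age_sd`, `age_min`, `age_max`, `male_prop`.
#' @export
fit_class_ranges <- function(train) {
  .validate_dataset(train, "train")
  counts <- table(factor(train$Maturation, levels = 1:3))
  if (any(counts < 2)) {
    missing <- names(counts)[counts < 2]
    abort(paste0("Insufficient data: class(es) ",
                 paste(missing, collapse = ", "),
                 " have fewer than 2 training rows."))
  }
  train |>
    dplyr::group_by(.data$Maturation) |>
    dplyr::summarise(
      n = dplyr::n(),
      c3_min = min(.data$C3), c3_max = max(.data$C3),
      c4_min = min(.data$C4), c4_max = max(.data$C4),
      c3_mean = mean(.data$C3), c3_sd = stats::sd(.data$C3),
      c4_mean = mean(.data$C4), c4_sd = stats::sd(.data$C4),
      age_mean = mean(.data$age), age_sd = stats::sd(.data$age),
      age_min = min(.data$age), age_max = max(.data$age),
      male_prop = mean(.data$gender == "M"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$Maturation)
}

# Truncated-normal sampler by inverse CDF; degenerate sd collapses to the mean.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (!is.finite(sd) || sd <= 0) {
    return(rep(mean, n))
  }
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Class-conditional tabular data augmentation
#'
#' Expands a training table by `n_per_class` synthetic rows per maturation
#' class. For each new row, `C3` and `C4` are drawn independently within the
#' class's observed \[min, max\] range — uniformly by default
#' (`mode = "uniform"`), or from a truncated normal with the class mean and
#' SD (`mode = "matched"`) — and `SumC3C4`/`C3C4` are recomputed from the
#' drawn values. Age is drawn from a truncated normal with the class age mean
#' and SD (truncated at the observed class range) and gender from a Bernoulli
#' with the class male proportion. Augmentation is meant for training data
#' only; never augment a test partition.
#'
#' @param train Training dataset table.
#' @param n_per_class Number of synthetic rows generated per class.
#' @param seed Integer seed; identical seed and input give an identical
#'   augmented table.
#' @param mode Sampling law for `C3`/`C4` within the class range.
#' @return A tibble: `train` followed by `3 * n_per_class` generated rows
#'   whose ids (`aug_<class>_<k>`) are distinct from the originals.
#' @export
cvd_generate <- function(train, n_per_class = 1000, seed = 1,
                         mode = c("uniform", "matched")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_per_class) || length(n_per_class) != 1 ||
      n_per_class < 0 || n_per_class != as.integer(n_per_class)) {
    abort("`n_per_class` must be a single non-negative integer.")
  }
  train <- tibble::as_tibble(train)
  if (n_per_class == 0) {
    .validate_dataset(train, "train")
    return(train)
  }
  ranges <- fit_class_ranges(train)
  n_per_class <- as.integer(n_per_class)
  seeds <- fan_out_seeds(seed, nrow(ranges))

  new_rows <- purrr::map2(seq_len(nrow(ranges)), seeds, function(i, s) {
    r <- ranges[i, ]
    with_seed(s, {
      if (mode == "uniform") {
        c3 <- runif(n_per_class, r$c3_min, r$c3_max)
        c4 <- runif(n_per_class, r$c4_min, r$c4_max)
      } else {
        c3 <- .rtruncnorm(n_per_class, r$c3_mean, r$c3_sd, r$c3_min, r$c3_max)
        c4 <- .rtruncnorm(n_per_class, r$c4_mean, r$c4_sd, r$c4_min, r$c4_max)
      }
      age <- .rtruncnorm(n_per_class, r$age_mean, r$age_sd, r$age_min,
                         r$age_max)
      gender <- ifelse(runif(n_per_class) < r$male_prop, "M", "F")
      tibble::tibble(
        id = sprintf("aug_%d_%0*d", r$Maturation,
                     nchar(as.character(n_per_class)), seq_len(n_per_class)),
        age = age,
        gender = gender,
        C3 = c3,
        C4 = c4,
        SumC3C4 = c3 + c4,
        C3C4 = c3 * c4,
        Maturation = rep(as.integer(r$Maturation), n_per_class)
      )
    })
  })
  out <- dplyr::bind_rows(c(list(train[.dataset_cols]), new_rows))
  .validate_dataset(out)
  out
}
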