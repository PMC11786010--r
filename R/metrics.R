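#' Multiclass evaluation metrics
#'
#' Computes the full evaluation suite for three-class maturation
#' predictions: accuracy, precision, recall, F1 and Jaccard (per class and
#' aggregated, support-weighted by default), log loss, and the confusion
#' matrix (rows = true class, columns = predicted class).
#'
#' Per class, with TP/FP/FN tallied one-vs-rest: precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = harmonic mean of the two, Jaccard =
#' TP/(TP+FP+FN); 0/0 cases score 0. Log loss is
#' `-mean(log p[true class])`, with probabilities clipped to
#' `[1e-15, 1 - 1e-15]` so it is defined at p = 0.
#'
#' @param truth Integer vector of true classes in 1..3.
#' @param estimate Integer vector of predicted classes, same length.
#' @param prob Optional numeric matrix of predicted probabilities (columns =
#'   classes 1..3, rows normalised to 1 within 1e-6); required for log loss.
#' @param average `"weighted"` (by class support) or `"macro"` aggregation.
#' @return A `cvd_metrics` object; `tidy()` gives the per-class table and
#'   `glance()` the one-row summary.
#' @export
#' @examples
#' m <- compute_metrics(c(1, 1, 2, 2, 3, 3), c(1, 2, 2, 2, 3, 3))
#' glance(m)
compute_metrics <- function(truth, estimate, prob = NULL,
                            average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length.")
  }
  if (length(truth) == 0) {
    abort("Cannot evaluate zero predictions.")
  }
  classes <- 1:3
  if (!all(truth %in% classes) || !all(estimate %in% classes)) {
    abort("Labels must lie in {1, 2, 3}.")
  }
  n <- length(truth)
  confusion <- table(
    true = factor(truth, levels = classes),
    predicted = factor(estimate, levels = classes)
  )
  confusion <- matrix(as.integer(confusion), nrow = 3,
                      dimnames = list(true = classes, predicted = classes))

  tp <- unname(diag(confusion))
  fp <- unname(colSums(confusion)) - tp
  fn <- unname(rowSums(confusion)) - tp
  support <- unname(rowSums(confusion))
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  jaccard <- safe_div(tp, tp + fp + fn)

  w <- if (average == "weighted") support / sum(support) else
    rep(1 / length(classes), length(classes))

  log_loss <- NA_real_
  if (!is.null(prob)) {
    prob <- as.matrix(prob)
    if (nrow(prob) != n || ncol(prob) != 3) {
      abort("`prob` must be an n x 3 probability matrix.")
    }
    if (any(abs(rowSums(prob) - 1) > 1e-6)) {
      abort("Probability rows must sum to 1 (within 1e-6).")
    }
    eps <- 1e-15
    p_true <- pmin(pmax(prob[cbind(seq_len(n), truth)], eps), 1 - eps)
    log_loss <- -mean(log(p_true))
  }

  structure(
    list(
      accuracy = sum(tp) / n,
      precision = sum(w * precision),
      recall = sum(w * recall),
      f1 = sum(w * f1),
      jaccard = sum(w * jaccard),
      log_loss = log_loss,
      confusion = confusion,
      per_class = tibble::tibble(
        class = classes, support = as.integer(support),
        precision = precision, recall = recall, f1 = f1, jaccard = jaccard
      ),
      average = average,
      n = n
    ),
    class = "cvd_metrics"
  )
}

#' @export
print.cvd_metrics <- function(x, ...) {
  cat(sprintf(
    "<cvd_metrics> n = %d (%s average)\n  accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f | Jaccard %.4f | log loss %s\n",
    x$n, x$average, x$accuracy, x$precision, x$recall, x$f1, x$jaccard,
    if (is.na(x$log_loss)) "-" else sprintf("%.4f", x$log_loss)))
  cat("  confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.cvd_metrics <- function(x, ...) {
  x$per_class
}

#' @export
glance.cvd_metrics <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, precision = x$precision, recall = x$recall,
    f1 = x$f1, jaccard = x$jaccard, log_loss = x$log_loss, n = x$n,
    average = x$average
  )
}

#' Midpoint cutoffs between adjacent class ranges of one feature
#'
#' The cutoff between two adjacent maturation classes is the midpoint
#' between the maximum observed feature value in the lower class and the
#' minimum in the upper class. A warning is raised when the adjacent ranges
#' overlap (lower class maximum above upper class minimum); the midpoint
#' formula is still applied verbatim.
#'
#' @param data Dataset table with all three classes; by convention the full
#'   non-augmented dataset.
#' @param feature Name of the feature column.
#' @return Tibble with columns `boundary` (`"1|2"`, `"2|3"`), `cut_point`,
#'   `lower_max`, `upper_min`, `overlap`.
#' @export
#' @examples
#' d <- simulate_cohort(seed = 3)
#' class_cutoffs(d, "SumC3C4")
class_cutoffs <- function(data, feature) {
  .validate_dataset(data)
  if (!feature %in% names(data)) {
    abort(paste0("Feature column not found: ", feature))
  }
  present <- sort(unique(data$Maturation))
  if (!identical(as.integer(present), 1:3)) {
    abort("Insufficient data: all three classes are required for cutoffs.")
  }
  vals <- split(data[[feature]], data$Maturation)
  out <- purrr::map(1:2, function(b) {
    lower_max <- max(vals[[as.character(b)]])
    upper_min <- min(vals[[as.character(b + 1)]])
    overlap <- lower_max > upper_min
    if (overlap) {
      warn(sprintf(
        "Classes %d and %d overlap on %s (max %.4g > min %.4g); midpoint still reported.",
        b, b + 1, feature, lower_max, upper_min))
    }
    tibble::tibble(
      boundary = sprintf("%d|%d", b, b + 1),
      cut_point = (lower_max + upper_min) / 2,
      lower_max = lower_max, upper_min = upper_min, overlap = overlap
    )
  })
  dplyr::bind_rows(out)
}

#' Combined (final) cutoff from the product and sum cutoffs
#'
#' A single boundary value that couples both engineered features:
#' `100 * cut_c3c4 / cut_sum`, where the two arguments are the `C3C4` and
#' `SumC3C4` cutoffs for the same class boundary.
#'
#' @param cut_c3c4 Cutoff(s) on the `C3C4` (product) feature.
#' @param cut_sum Cutoff(s) on the `SumC3C4` (sum) feature; must be nonzero.
#' @return Dimensionless combined cutoff(s), on a 0-100 scale.
#' @export
#' @examples
#' final_cutoff(0.62, 1.56)
final_cutoff <- function(cut_c3c4, cut_sum) {
  if (any(!is.finite(cut_c3c4)) || any(!is.finite(cut_sum))) {
    abort("Cutoffs must be finite.")
  }
  if (any(cut_sum == 0)) {
    abort("`cut_sum` must be nonzero.")
  }
  100 * cut_c3c4 / cut_sum
}

#' Full cutoff report over the engineered features
#'
#' Per-feature midpoint cutoffs for both class boundaries plus the combined
#' final cutoffs coupling `C3C4` and `SumC3C4`.
#'
#' @param data Dataset table (conventionally the full non-augmented data).
#' @param features Feature columns to report cutoffs for; must include
#'   `SumC3C4` and `C3C4` for the final cutoffs.
#' @return A `cvd_cutoffs` object: list with tibble `cut_points` (feature,
#'   boundary, cut_point, overlap) and tibble `final` (boundary,
#'   final_cutoff).
#' @export
cutoff_report <- function(data, features = c("SumC3C4", "C3C4")) {
  cuts <- purrr::map(features, function(f) {
    dplyr::mutate(class_cutoffs(data, f), feature = f, .before = 1)
  })
  cuts <- dplyr::bind_rows(cuts)
  final <- NULL
  if (all(c("SumC3C4", "C3C4") %in% features)) {
    sum_cut <- cuts$cut_point[cuts$feature == "SumC3C4"]
    prod_cut <- cuts$cut_point[cuts$feature == "C3C4"]
    final <- tibble::tibble(
      boundary = c("1|2", "2|3"),
      final_cutoff = final_cutoff(prod_cut, sum_cut)
    )
  }
  structure(list(cut_points = cuts, final = final), class = "cvd_cutoffs")
}

#' @export
print.cvd_cutoffs <- function(x, ...) {
  cat("<cvd_cutoffs>\n")
  print(x$cut_points)
  if (!is.null(x$final)) {
    cat("final (100 * C3C4 cutoff / SumC3C4 cutoff):\n")
    print(x$final)
  }
  invisible(x)
}

#' @export
tidy.cvd_cutoffs <- function(x, ...) {
  x$cut_points
}

#' @export
glance.cvd_cutoffs <- function(x, ...) {
  if (is.null(x$final)) {
    return(tibble::tibble(final_cutoff_1 = NA_real_,
                          final_cutoff_2 = NA_real_))
  }
  tibble::tibble(
    final_cutoff_1 = x$final$final_cutoff[x$final$boundary == "1|2"],
    final_cutoff_2 = x$final$final_cutoff[x$final$boundary == "2|3"]
  )
}
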