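#' Landmark geometry and error-reduced vertebral ratio measurement
#'
#' A landmark table holds, per cephalogram, the pixel coordinates of the four
#' body corners of the third (C3) and fourth (C4) cervical vertebrae together
#' with the source image width. Corners are identified by role, not by
#' coordinate order, so flipped radiographs are handled transparently:
#' `as` = anterior-superior, `ps` = posterior-superior, `ai` =
#' anterior-inferior, `pi` = posterior-inferior. Coordinates use the raster
#' convention (origin top-left, y increasing downward).
#'
#' The expected columns are `id`, `image_width`, and `<v>_<corner>_<axis>`
#' for `v` in `c3`, `c4`, corner in `as`, `ps`, `ai`, `pi`, axis in `x`, `y`
#' (16 coordinate columns in total).
#'
#' @name landmark-table
NULL

.landmark_points <- function() {
  as.vector(outer(c("c3", "c4"), c("as", "ps", "ai", "pi"), paste, sep = "_"))
}

.landmark_coord_cols <- function() {
  as.vector(t(outer(.landmark_points(), c("x", "y"), paste, sep = "_")))
}

.validate_landmarks <- function(lm) {
  if (!is.data.frame(lm)) {
    abort("`lm` must be a data frame of landmark records.")
  }
  needed <- c("image_width", .landmark_coord_cols())
  missing <- setdiff(needed, names(lm))
  if (length(missing) > 0) {
    abort(paste0("Landmark table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  coords <- as.matrix(lm[, .landmark_coord_cols()])
  if (!all(is.finite(coords))) {
    abort("Landmark coordinates must be finite.")
  }
  if (any(!is.finite(lm$image_width)) || any(lm$image_width <= 0)) {
    abort("`image_width` must be positive and finite.")
  }
  invisible(lm)
}

#' Rescale landmark coordinates to a uniform image width
#'
#' Cephalograms from different devices arrive at different resolutions;
#' measuring on a common pixel scale standardises the subsequent perturbation
#' radius. All coordinates (x and y alike) are multiplied by
#' `target_width / image_width`, preserving the aspect ratio.
#'
#' @param lm Landmark table (see [landmark-table]).
#' @param target_width Width, in pixels, of the normalised frame.
#' @return The landmark table with rescaled coordinates and
#'   `image_width == target_width`.
#' @export
#' @examples
#' lm <- simulate_landmarks(0.5, 0.5, image_width = 4000, seed = 1)
#' scale_to_width(lm, 2000)
scale_to_width <- function(lm, target_width = 2000) {
  .validate_landmarks(lm)
  if (!is.numeric(target_width) || length(target_width) != 1 ||
      !is.finite(target_width) || target_width <= 0) {
    abort("`target_width` must be a single positive number.")
  }
  factor <- target_width / lm$image_width
  out <- lm
  for (col in .landmark_coord_cols()) {
    out[[col]] <- out[[col]] * factor
  }
  out$image_width <- rep(target_width, nrow(out))
  tibble::as_tibble(out)
}

#' Euclidean distance between two landmarks
#'
#' @param p1,p2 Numeric vectors `c(x, y)`, or two-column matrices of points
#'   (rows paired between `p1` and `p2`).
#' @return Distance(s) in pixels.
#' @export
#' @examples
#' euclidean_length(c(0, 0), c(3, 4)) # 5
euclidean_length <- function(p1, p2) {
  p1 <- rbind(p1)
  p2 <- rbind(p2)
  if (ncol(p1) != 2 || ncol(p2) != 2 || nrow(p1) != nrow(p2)) {
    abort("`p1` and `p2` must be x,y pairs (or matrices of them, row-paired).")
  }
  if (!all(is.finite(p1)) || !all(is.finite(p2))) {
    abort("Coordinates must be finite.")
  }
  unname(sqrt((p2[, 1] - p1[, 1])^2 + (p2[, 2] - p1[, 2])^2))
}

#' Anterior-height to anteroposterior-length ratio of one vertebra
#'
#' AH is the anterior border length (anterior-superior to anterior-inferior
#' corner); AP is the inferior border length (anterior-inferior to
#' posterior-inferior corner). The ratio AH/AP is dimensionless and invariant
#' under uniform scaling, which removes magnification differences between
#' radiographic devices.
#'
#' @param lm Landmark table.
#' @param vertebra `"c3"` or `"c4"`.
#' @return Numeric vector of ratios, one per row of `lm`.
#' @export
vertebra_ratio <- function(lm, vertebra = c("c3", "c4")) {
  vertebra <- match.arg(vertebra)
  .validate_landmarks(lm)
  p <- function(corner, axis) lm[[paste(vertebra, corner, axis, sep = "_")]]
  ah <- euclidean_length(cbind(p("as", "x"), p("as", "y")),
                         cbind(p("ai", "x"), p("ai", "y")))
  ap <- euclidean_length(cbind(p("ai", "x"), p("ai", "y")),
                         cbind(p("pi", "x"), p("pi", "y")))
  if (any(ap == 0)) {
    abort("Degenerate landmarks: anteroposterior distance is zero.")
  }
  ah / ap
}

# Draw per-axis integer displacements: magnitude uniform on {1, ..., max_disp}
# with an independent random sign, for a n x k matrix of perturbations.
.draw_displacements <- function(n, k, max_disp) {
  if (max_disp == 0) {
    return(matrix(0, nrow = n, ncol = k))
  }
  mag <- matrix(sample.int(max_disp, n * k, replace = TRUE), nrow = n)
  sign <- matrix(sample(c(-1, 1), n * k, replace = TRUE), nrow = n)
  mag * sign
}

# Perturbed ratios for one record: coords is the named 16-vector of
# coordinates, disp an n_iter x 16 displacement matrix with matching columns.
.perturbed_ratios <- function(coords, disp, vertebra) {
  cn <- colnames(disp)
  g <- function(corner, axis) {
    col <- paste(vertebra, corner, axis, sep = "_")
    coords[[col]] + disp[, match(col, cn)]
  }
  ah <- sqrt((g("as", "x") - g("ai", "x"))^2 + (g("as", "y") - g("ai", "y"))^2)
  ap <- sqrt((g("ai", "x") - g("pi", "x"))^2 + (g("ai", "y") - g("pi", "y"))^2)
  list(ah = ah, ap = ap, ratio = ah / ap)
}

#' Error-reduced C3/C4 ratios by Monte-Carlo landmark perturbation
#'
#' Operator placement of vertebral corner landmarks carries a few pixels of
#' error. The error-reduction procedure perturbs every landmark independently
#' on each axis by an integer displacement of 1 to `max_disp` pixels (random
#' sign), recomputes both ratios, repeats `n_iter` times, and returns the
#' arithmetic mean of each ratio — a probabilistic average over the
#' neighbourhood of the clicked points.
#'
#' Iterations in which a perturbed anteroposterior distance collapses to zero
#' are redrawn; after 100 consecutive failed redraws an error is raised
#' (this cannot occur for realistically sized vertebrae).
#'
#' @param lm Landmark table; displacements are applied to the coordinates as
#'   given, so normalise with [scale_to_width()] first (see
#'   [measure_landmarks()] for the full convention).
#' @param n_iter Number of perturbation iterations (>= 1).
#' @param max_disp Maximum per-axis displacement in pixels; `0` disables
#'   perturbation and reproduces the deterministic ratios exactly.
#' @param seed Integer seed; identical seed and input give identical output.
#' @return A tibble with columns `id` (if present in `lm`), `c3`, `c4`.
#' @export
aer_ratios <- function(lm, n_iter = 1000, max_disp = 4, seed = 1) {
  .validate_landmarks(lm)
  if (!is.numeric(n_iter) || length(n_iter) != 1 || n_iter < 1) {
    abort("`n_iter` must be a single integer >= 1.")
  }
  if (!is.numeric(max_disp) || length(max_disp) != 1 || max_disp < 0) {
    abort("`max_disp` must be a single non-negative integer.")
  }
  n_iter <- as.integer(n_iter)
  max_disp <- as.integer(max_disp)
  cols <- .landmark_coord_cols()

  if (max_disp == 0) {
    c3 <- vertebra_ratio(lm, "c3")
    c4 <- vertebra_ratio(lm, "c4")
  } else {
    seeds <- fan_out_seeds(seed, nrow(lm))
    c3 <- numeric(nrow(lm))
    c4 <- numeric(nrow(lm))
    for (i in seq_len(nrow(lm))) {
      coords <- as.list(lm[i, cols])
      res <- with_seed(seeds[i], {
        disp <- .draw_displacements(n_iter, length(cols), max_disp)
        colnames(disp) <- cols
        r3 <- .perturbed_ratios(coords, disp, "c3")
        r4 <- .perturbed_ratios(coords, disp, "c4")
        bad <- which(r3$ap == 0 | r4$ap == 0)
        tries <- 0L
        while (length(bad) > 0) {
          tries <- tries + 1L
          if (tries > 100L) {
            abort("Degenerate perturbed landmarks: 100 consecutive redraws failed.")
          }
          redraw <- .draw_displacements(length(bad), length(cols), max_disp)
          colnames(redraw) <- cols
          n3 <- .perturbed_ratios(coords, redraw, "c3")
          n4 <- .perturbed_ratios(coords, redraw, "c4")
          r3$ratio[bad] <- n3$ratio
          r4$ratio[bad] <- n4$ratio
          bad <- bad[n3$ap == 0 | n4$ap == 0]
        }
        c(mean(r3$ratio), mean(r4$ratio))
      })
      c3[i] <- res[1]
      c4[i] <- res[2]
    }
  }
  out <- tibble::tibble(c3 = c3, c4 = c4)
  if ("id" %in% names(lm)) {
    out <- tibble::tibble(id = lm$id, c3 = c3, c4 = c4)
  }
  out
}

#' Measure error-reduced ratio features from raw landmark records
#'
#' Convenience wrapper over the full measurement convention: normalise each
#' record to a common image width, run the perturbation-averaged measurement,
#' and return the engineered feature columns ready for the dataset table.
#'
#' @inheritParams aer_ratios
#' @param target_width Normalised frame width in pixels.
#' @return Tibble with columns `id`, `C3`, `C4`, `SumC3C4`, `C3C4`.
#' @export
measure_landmarks <- function(lm, target_width = 2000, n_iter = 1000,
                              max_disp = 4, seed = 1) {
  lm <- scale_to_width(lm, target_width)
  r <- aer_ratios(lm, n_iter = n_iter, max_disp = max_disp, seed = seed)
  feats <- engineer_features(r$c3, r$c4)
  tibble::tibble(
    id = if ("id" %in% names(r)) r$id else seq_len(nrow(r)),
    C3 = r$c3, C4 = r$c4,
    SumC3C4 = feats$sum, C3C4 = feats$prod
  )
}

#' Read and write landmark records
#'
#' Landmark files are accepted as JSON (a single object or an array of
#' objects with fields `id`, `image_width`, and nested `c3`/`c4` corner
#' objects or flat `c3_as_x`-style fields) or as wide CSV with one column per
#' coordinate.
#'
#' @param path File path; format is inferred from the `.json` / `.csv`
#'   extension.
#' @return A landmark tibble (see [landmark-table]).
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!is.data.frame(raw)) raw <- .landmark_record_to_df(raw)
    lm <- .flatten_landmark_json(raw)
  } else {
    lm <- readr::read_csv(path, show_col_types = FALSE)
  }
  .validate_landmarks(lm)
  tibble::as_tibble(lm)
}

# A single JSON object parses to a named list; flatten it to a one-row frame.
.landmark_record_to_df <- function(rec) {
  out <- list()
  for (nm in names(rec)) {
    val <- rec[[nm]]
    if (nm %in% c("c3", "c4") && is.list(val)) {
      for (corner in names(val)) {
        out[[paste(nm, corner, "x", sep = "_")]] <- val[[corner]][["x"]]
        out[[paste(nm, corner, "y", sep = "_")]] <- val[[corner]][["y"]]
      }
    } else {
      out[[nm]] <- val
    }
  }
  tibble::as_tibble(out)
}

.flatten_landmark_json <- function(raw) {
  raw <- tibble::as_tibble(raw)
  for (v in c("c3", "c4")) {
    if (v %in% names(raw) && is.data.frame(raw[[v]])) {
      nested <- raw[[v]]
      for (corner in c("as", "ps", "ai", "pi")) {
        pt <- nested[[corner]]
        raw[[paste(v, corner, "x", sep = "_")]] <- pt$x
        raw[[paste(v, corner, "y", sep = "_")]] <- pt$y
      }
      raw[[v]] <- NULL
    }
  }
  raw
}

#' @rdname read_landmarks
#' @param lm Landmark table to write.
#' @export
write_landmarks <- function(lm, path) {
  .validate_landmarks(lm)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lm, path, digits = NA)
  } else {
    readr::write_csv(lm, path)
  }
  invisible(path)
}
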