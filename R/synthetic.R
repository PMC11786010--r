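#' Default per-class cohort profiles
#'
#' Generative parameters for the three maturation classes of a typical
#' orthodontic cohort of 980 lateral cephalograms: per-class means and SDs of
#' the C3 and C4 ratios and of chronological age, male counts, and class
#' sizes (pre-peak n = 326, peak n = 326, post-peak n = 328). These defaults
#' drive [simulate_cohort()] so the rest of the pipeline can be exercised
#' without radiographs.
#'
#' @return Tibble with columns `Maturation`, `n`, `c3_mean`, `c3_sd`,
#'   `c4_mean`, `c4_sd`, `age_mean`, `age_sd`, `male_prop`.
#' @export
class_profiles <- function() {
  tibble::tibble(
    Maturation = 1:3,
    n = c(326L, 326L, 328L),
    c3_mean = c(0.52, 0.74, 1.01),
    c3_sd = c(0.08, 0.08, 0.14),
    c4_mean = c(0.49, 0.68, 0.94),
    c4_sd = c(0.08, 0.08, 0.12),
    age_mean = c(8.61, 11.53, 16.1),
    age_sd = c(1.65, 1.37, 1.23),
    male_prop = c(192 / 326, 178 / 326, 194 / 328)
  )
}

#' Simulate a maturation cohort feature table
#'
#' Draws, per class, `n` subjects with `C3` and `C4` from class-specific
#' Gaussians coupled through a Gaussian copula with correlation `rho`
#' (vertebral ratios co-grow, so they are strongly positively correlated) and
#' truncated below at `lower` to keep ratios physical. Age is Gaussian with
#' the class mean/SD and gender Bernoulli with the class male proportion.
#' `SumC3C4` and `C3C4` are computed from the drawn ratios.
#'
#' @param profiles Profile tibble as returned by [class_profiles()].
#' @param seed Integer seed.
#' @param rho Latent correlation between `C3` and `C4` within class.
#' @param lower Lower truncation bound for the ratios.
#' @return A dataset tibble with `sum(profiles$n)` rows.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 42)
#' dplyr::count(cohort, Maturation)
simulate_cohort <- function(profiles = class_profiles(), seed = 1,
                            rho = 0.9, lower = 0.05) {
  stopifnot(is.data.frame(profiles))
  needed <- c("Maturation", "n", "c3_mean", "c3_sd", "c4_mean", "c4_sd",
              "age_mean", "age_sd", "male_prop")
  missing <- setdiff(needed, names(profiles))
  if (length(missing) > 0) {
    abort(paste0("Profiles are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(profiles$c3_sd <= 0) || any(profiles$c4_sd <= 0) ||
      any(profiles$age_sd <= 0)) {
    abort("Profile SDs must be positive.")
  }
  if (any(profiles$male_prop < 0) || any(profiles$male_prop > 1)) {
    abort("`male_prop` must lie in [0, 1].")
  }
  if (abs(rho) >= 1) {
    abort("`rho` must lie strictly inside (-1, 1).")
  }
  seeds <- fan_out_seeds(seed, nrow(profiles))
  rows <- purrr::map2(seq_len(nrow(profiles)), seeds, function(i, s) {
    p <- profiles[i, ]
    n <- as.integer(p$n)
    if (n == 0) {
      return(NULL)
    }
    with_seed(s, {
      # Gaussian copula: correlated standard normals -> uniforms -> truncated
      # normal marginals, preserving rank correlation.
      z1 <- rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      u1 <- pnorm(z1)
      u2 <- pnorm(z2)
      q_trunc <- function(u, mean, sd) {
        p_lo <- pnorm(lower, mean, sd)
        qnorm(p_lo + u * (1 - p_lo), mean, sd)
      }
      c3 <- q_trunc(u1, p$c3_mean, p$c3_sd)
      c4 <- q_trunc(u2, p$c4_mean, p$c4_sd)
      tibble::tibble(
        id = sprintf("sim_%d_%03d", p$Maturation, seq_len(n)),
        age = rnorm(n, p$age_mean, p$age_sd),
        gender = ifelse(runif(n) < p$male_prop, "M", "F"),
        C3 = c3,
        C4 = c4,
        SumC3C4 = c3 + c4,
        C3C4 = c3 * c4,
        Maturation = rep(as.integer(p$Maturation), n)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::as_tibble(
      setNames(rep(list(logical(0)), length(.dataset_cols)), .dataset_cols)))
  }
  out
}

#' Simulate landmark sets with prescribed true ratios
#'
#' Constructs, for each pair of target ratios, rectangular vertebral bodies
#' whose anterior border is `target * scale` pixels and inferior border
#' `scale` pixels, so that [vertebra_ratio()] recovers the target exactly
#' when `jitter = 0`. Optional uniform corner jitter (± `jitter` pixels per
#' axis) adds placement realism.
#'
#' @param target_c3,target_c4 Positive target ratios (vectorised, recycled
#'   to a common length).
#' @param scale Anteroposterior border length in pixels.
#' @param jitter Half-width of uniform corner jitter in pixels.
#' @param seed Integer seed (used only when `jitter > 0`).
#' @param image_width Declared source image width in pixels.
#' @return A landmark tibble with one row per target pair.
#' @export
#' @examples
#' lm <- simulate_landmarks(0.5, 0.75, scale = 100)
#' vertebra_ratio(lm, "c3")
simulate_landmarks <- function(target_c3, target_c4, scale = 100,
                               jitter = 0, seed = 1, image_width = 2000) {
  n <- max(length(target_c3), length(target_c4))
  target_c3 <- rep_len(target_c3, n)
  target_c4 <- rep_len(target_c4, n)
  if (any(target_c3 <= 0) || any(target_c4 <= 0) || scale <= 0) {
    abort("Targets and `scale` must be strictly positive.")
  }
  if (jitter < 0) {
    abort("`jitter` must be non-negative.")
  }
  # Anchor each vertebra well inside the frame; C4 sits below C3, as on a
  # lateral view. Anterior is towards x = 0.
  x0 <- image_width / 4
  rect <- function(y0, h) {
    list(
      as = cbind(x0, y0),
      ps = cbind(x0 + scale, y0),
      ai = cbind(x0, y0 + h),
      pi = cbind(x0 + scale, y0 + h)
    )
  }
  h3 <- target_c3 * scale
  h4 <- target_c4 * scale
  c3 <- rect(rep(scale, n), h3)
  c4 <- rect(rep(scale, n) + h3 + scale / 2, h4)
  out <- tibble::tibble(
    id = sprintf("lmk_%03d", seq_len(n)),
    image_width = rep(image_width, n)
  )
  for (v in c("c3", "c4")) {
    pts <- if (v == "c3") c3 else c4
    for (corner in c("as", "ps", "ai", "pi")) {
      out[[paste(v, corner, "x", sep = "_")]] <- as.numeric(pts[[corner]][, 1])
      out[[paste(v, corner, "y", sep = "_")]] <- as.numeric(pts[[corner]][, 2])
    }
  }
  if (jitter > 0) {
    cols <- .landmark_coord_cols()
    out[cols] <- with_seed(seed, {
      lapply(out[cols], function(col) col + runif(n, -jitter, jitter))
    })
  }
  out
}
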