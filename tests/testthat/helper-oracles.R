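# Independent oracles and fixture builders shared across the suite.

# Brute-force metric tally: everything computed by explicit loops over
# one-vs-rest counts, independent of the package's vectorised path.
oracle_metrics <- function(truth, estimate, prob = NULL) {
  classes <- 1:3
  n <- length(truth)
  conf <- matrix(0L, 3, 3)
  for (i in seq_len(n)) {
    conf[truth[i], estimate[i]] <- conf[truth[i], estimate[i]] + 1L
  }
  prec <- rec <- f1 <- jac <- supp <- numeric(3)
  for (k in classes) {
    tp <- fp <- fn <- 0L
    for (i in seq_len(n)) {
      if (truth[i] == k && estimate[i] == k) tp <- tp + 1L
      if (truth[i] != k && estimate[i] == k) fp <- fp + 1L
      if (truth[i] == k && estimate[i] != k) fn <- fn + 1L
    }
    supp[k] <- sum(truth == k)
    prec[k] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[k] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[k] <- if (prec[k] + rec[k] == 0) 0 else
      2 * prec[k] * rec[k] / (prec[k] + rec[k])
    jac[k] <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
  }
  w <- supp / n
  ll <- NA_real_
  if (!is.null(prob)) {
    acc_ll <- 0
    for (i in seq_len(n)) {
      p <- min(max(prob[i, truth[i]], 1e-15), 1 - 1e-15)
      acc_ll <- acc_ll - log(p)
    }
    ll <- acc_ll / n
  }
  list(
    accuracy = sum(diag(conf)) / n,
    precision = sum(w * prec), recall = sum(w * rec),
    f1 = sum(w * f1), jaccard = sum(w * jac),
    log_loss = ll, confusion = conf
  )
}

# Independently coded Monte-Carlo perturbation sampler: plain loop, sign and
# magnitude drawn through sample() on the composite set of displacements,
# one landmark at a time — deliberately nothing shared with aer_ratios().
oracle_mc_ratios <- function(lm_row, n_iter, max_disp, seed) {
  set.seed(seed)
  corners <- c("as", "ps", "ai", "pi")
  disp_set <- setdiff(-max_disp:max_disp, 0)
  c3 <- c4 <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    pt <- list()
    for (v in c("c3", "c4")) {
      for (corner in corners) {
        x <- lm_row[[paste(v, corner, "x", sep = "_")]] +
          sample(disp_set, 1)
        y <- lm_row[[paste(v, corner, "y", sep = "_")]] +
          sample(disp_set, 1)
        pt[[paste(v, corner, sep = "_")]] <- c(x, y)
      }
    }
    ratio1 <- function(v) {
      ah <- sqrt(sum((pt[[paste0(v, "_as")]] - pt[[paste0(v, "_ai")]])^2))
      ap <- sqrt(sum((pt[[paste0(v, "_ai")]] - pt[[paste0(v, "_pi")]])^2))
      ah / ap
    }
    c3[it] <- ratio1("c3")
    c4[it] <- ratio1("c4")
  }
  list(c3_mean = mean(c3), c3_se = sd(c3) / sqrt(n_iter),
       c4_mean = mean(c4), c4_se = sd(c4) / sqrt(n_iter))
}

# Small well-separated three-class table for fast model tests.
toy_dataset <- function(n_per_class = 20, seed = 123, gap = 6) {
  set.seed(seed)
  rows <- lapply(1:3, function(k) {
    c3 <- runif(n_per_class, k * gap, k * gap + 1)
    c4 <- runif(n_per_class, k * gap, k * gap + 1)
    tibble::tibble(
      id = sprintf("toy_%d_%02d", k, seq_len(n_per_class)),
      age = runif(n_per_class, 8, 16),
      gender = sample(c("M", "F"), n_per_class, replace = TRUE),
      C3 = c3, C4 = c4, SumC3C4 = c3 + c4, C3C4 = c3 * c4,
      Maturation = rep(k, n_per_class)
    )
  })
  dplyr::bind_rows(rows)
}

# One landmark record with hand-chosen, non-axis-aligned corners.
fixture_landmarks <- function() {
  tibble::tibble(
    id = "fix_1", image_width = 2000,
    c3_as_x = 510, c3_as_y = 410, c3_ps_x = 612, c3_ps_y = 416,
    c3_ai_x = 513, c3_ai_y = 480, c3_pi_x = 615, c3_pi_y = 488,
    c4_as_x = 508, c4_as_y = 530, c4_ps_x = 611, c4_ps_y = 535,
    c4_ai_x = 511, c4_ai_y = 596, c4_pi_x = 613, c4_pi_y = 603
  )
}
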