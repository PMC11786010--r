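test_that("scale_to_width rescales both axes by the same factor", {
  lm <- fixture_landmarks()
  lm$image_width <- 4000
  lm$c3_as_x <- 400
  lm$c3_as_y <- 200
  out <- scale_to_width(lm, 2000)
  expect_equal(out$image_width, 2000)
  expect_equal(out$c3_as_x, 200)
  expect_equal(out$c3_as_y, 100)

  lm2 <- fixture_landmarks() # already at width 2000
  expect_equal(scale_to_width(lm2, 2000), tibble::as_tibble(lm2))

  lm3 <- fixture_landmarks()
  lm3$image_width <- 1000
  lm3$c4_pi_x <- 10
  lm3$c4_pi_y <- 7
  out3 <- scale_to_width(lm3, 2000)
  expect_equal(out3$c4_pi_x, 20)
  expect_equal(out3$c4_pi_y, 14)

  lm_bad <- fixture_landmarks()
  lm_bad$image_width <- 0
  expect_error(scale_to_width(lm_bad), "image_width")
  expect_error(scale_to_width(fixture_landmarks(), -5), "positive")
})

test_that("euclidean_length matches Pythagoras and is symmetric", {
  expect_equal(euclidean_length(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_length(c(5, 5), c(5, 5)), 0)
  expect_equal(euclidean_length(c(2, 1), c(5, 5)), 5)
  expect_equal(euclidean_length(c(5, 5), c(2, 1)), 5)
  expect_error(euclidean_length(c(Inf, 0), c(0, 0)), "finite")
})

test_that("vertebra_ratio computes AH/AP from the role-named corners", {
  # unit square: AH == AP
  square <- simulate_landmarks(1, 1, scale = 50)
  expect_equal(vertebra_ratio(square, "c3"), 1)

  # AH endpoints (0,0)-(0,50), AP endpoints (0,50)-(100,50) -> 0.5
  lm <- fixture_landmarks()
  lm[, c("c3_as_x", "c3_as_y")] <- list(0, 0)
  lm[, c("c3_ai_x", "c3_ai_y")] <- list(0, 50)
  lm[, c("c3_pi_x", "c3_pi_y")] <- list(100, 50)
  expect_equal(vertebra_ratio(lm, "c3"), 0.5)

  # hand-computed non-axis-aligned case: AH = sqrt(4904), AP = sqrt(10217)
  lm2 <- fixture_landmarks()
  lm2[, c("c3_as_x", "c3_as_y")] <- list(10, 10)
  lm2[, c("c3_ps_x", "c3_ps_y")] <- list(110, 12)
  lm2[, c("c3_ai_x", "c3_ai_y")] <- list(12, 80)
  lm2[, c("c3_pi_x", "c3_pi_y")] <- list(113, 84)
  expect_equal(vertebra_ratio(lm2, "c3"), 0.692809021178, tolerance = 1e-10)

  # scale invariance under uniform coordinate scaling (up to fp rounding)
  lm3 <- fixture_landmarks()
  r1 <- vertebra_ratio(lm3, "c4")
  cols <- grep("_(x|y)$", names(lm3), value = TRUE)
  lm3[cols] <- lapply(lm3[cols], function(v) v * 3.7)
  lm3$image_width <- lm3$image_width * 3.7
  expect_equal(vertebra_ratio(lm3, "c4"), r1, tolerance = 1e-12)

  # degenerate AP
  lm4 <- fixture_landmarks()
  lm4[, c("c3_pi_x", "c3_pi_y")] <- list(lm4$c3_ai_x, lm4$c3_ai_y)
  expect_error(vertebra_ratio(lm4, "c3"), "Degenerate")
})

test_that("error-reduced ratios are deterministic and exact at zero displacement", {
  lm <- fixture_landmarks()
  r0 <- aer_ratios(lm, n_iter = 50, max_disp = 0, seed = 1)
  expect_identical(r0$c3, vertebra_ratio(lm, "c3"))
  expect_identical(r0$c4, vertebra_ratio(lm, "c4"))

  r1 <- aer_ratios(lm, n_iter = 300, max_disp = 4, seed = 42)
  r2 <- aer_ratios(lm, n_iter = 300, max_disp = 4, seed = 42)
  expect_identical(r1, r2)
  r3 <- aer_ratios(lm, n_iter = 300, max_disp = 4, seed = 43)
  expect_false(identical(r1$c3, r3$c3))

  expect_error(aer_ratios(lm, n_iter = 0), "n_iter")
  expect_error(aer_ratios(lm, max_disp = -1), "max_disp")
})

test_that("error-reduced mean agrees with an independent Monte-Carlo oracle", {
  lm <- fixture_landmarks()
  got <- aer_ratios(lm, n_iter = 100000, max_disp = 4, seed = 7)
  oracle <- oracle_mc_ratios(lm[1, ], n_iter = 100000, max_disp = 4,
                             seed = 2024)
  # both estimates carry MC error; compare within 3 combined standard errors
  expect_lt(abs(got$c3 - oracle$c3_mean), 3 * sqrt(2) * oracle$c3_se)
  expect_lt(abs(got$c4 - oracle$c4_mean), 3 * sqrt(2) * oracle$c4_se)
})

test_that("ratio measurement is scale-stable through width normalisation", {
  lm <- fixture_landmarks()
  lm_large <- lm
  cols <- grep("_(x|y)$", names(lm), value = TRUE)
  lm_large[cols] <- lapply(lm_large[cols], function(v) v * 2)
  lm_large$image_width <- 4000
  norm <- scale_to_width(lm_large, 2000)
  expect_equal(vertebra_ratio(norm, "c3"), vertebra_ratio(lm, "c3"))
  # perturbation-averaged ratios agree within sampling error after rescaling
  a <- aer_ratios(scale_to_width(lm, 2000), n_iter = 4000, seed = 5)
  b <- aer_ratios(norm, n_iter = 4000, seed = 6)
  expect_equal(a$c3, b$c3, tolerance = 0.01)
})

test_that("Monte-Carlo standard error shrinks as 1/sqrt(n_iter)", {
  lm <- fixture_landmarks()
  reps <- 200
  small <- vapply(seq_len(reps), function(i) {
    aer_ratios(lm, n_iter = 100, max_disp = 4, seed = 1000 + i)$c3
  }, numeric(1))
  large <- vapply(seq_len(reps), function(i) {
    aer_ratios(lm, n_iter = 10000, max_disp = 4, seed = 5000 + i)$c3
  }, numeric(1))
  ratio <- var(small) / var(large)
  expect_gt(ratio, 50)
  expect_lt(ratio, 200)
})

test_that("landmark files round-trip through CSV and JSON", {
  lm <- fixture_landmarks()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, csv)
  expect_equal(read_landmarks(csv), lm)

  json <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, json)
  back <- read_landmarks(json)
  expect_equal(back[names(lm)], lm)

  # nested single-object JSON is accepted too
  nested <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    id = "n1", image_width = 2000,
    c3 = list(as = list(x = 1, y = 2), ps = list(x = 50, y = 2),
              ai = list(x = 1, y = 30), pi = list(x = 50, y = 31)),
    c4 = list(as = list(x = 1, y = 60), ps = list(x = 50, y = 61),
              ai = list(x = 1, y = 90), pi = list(x = 50, y = 92))
  ), auto_unbox = TRUE), nested)
  got <- read_landmarks(nested)
  expect_equal(got$c3_ai_y, 30)
  expect_equal(nrow(got), 1)
})

test_that("measure_landmarks produces the engineered feature columns", {
  lm <- simulate_landmarks(c(0.5, 0.8), c(0.6, 0.9), scale = 120)
  out <- measure_landmarks(lm, n_iter = 500, max_disp = 2, seed = 3)
  expect_named(out, c("id", "C3", "C4", "SumC3C4", "C3C4"))
  expect_equal(out$SumC3C4, out$C3 + out$C4)
  expect_equal(out$C3C4, out$C3 * out$C4)
  expect_equal(out$C3, c(0.5, 0.8), tolerance = 0.05)
})
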