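test_that("metrics match a hand tally on a small prediction vector", {
  truth <- c(1, 1, 2, 2, 3, 3)
  est <- c(1, 2, 2, 2, 3, 3)
  m <- compute_metrics(truth, est)
  expect_equal(m$accuracy, 5 / 6)
  # hand tally: class 1 TP=1 FP=0 FN=1; class 2 TP=2 FP=1 FN=0; class 3 clean
  expect_equal(m$per_class$precision, c(1, 2 / 3, 1))
  expect_equal(m$per_class$recall, c(1 / 2, 1, 1))
  expect_equal(m$per_class$f1, c(2 / 3, 4 / 5, 1))
  expect_equal(m$per_class$jaccard, c(1 / 2, 2 / 3, 1))
  # support-weighted aggregates (equal supports of 2)
  expect_equal(m$precision, (1 + 2 / 3 + 1) / 3)
  expect_equal(m$f1, (2 / 3 + 4 / 5 + 1) / 3)
  expect_equal(sum(m$confusion), 6)
  expect_equal(diag(m$confusion), setNames(c(1, 2, 2), 1:3))
})

test_that("log loss has its closed forms and clipping floor", {
  truth <- c(1, 2, 3)
  est <- truth
  uniform <- matrix(1 / 3, 3, 3)
  expect_equal(compute_metrics(truth, est, uniform)$log_loss, log(3))

  onehot <- diag(3)
  m <- compute_metrics(truth, est, onehot)
  expect_equal(m$accuracy, 1)
  expect_lte(m$log_loss, -log(1 - 1e-15) + 1e-12)

  # one-hot on the correct class minimises log loss over candidate matrices
  set.seed(5)
  candidates <- replicate(50, {
    p <- matrix(rexp(9), 3, 3)
    p / rowSums(p)
  }, simplify = FALSE)
  losses <- vapply(candidates, function(p) {
    compute_metrics(truth, est, p)$log_loss
  }, numeric(1))
  expect_true(all(losses >= m$log_loss))

  # wrong confident prediction is heavily penalised via clipping
  bad <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_gt(compute_metrics(truth, est, bad)$log_loss, 20)

  expect_error(compute_metrics(truth, est, matrix(1, 3, 3)), "sum to 1")
  expect_error(compute_metrics(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(compute_metrics(c(1, 4), c(1, 2)), "\\{1, 2, 3\\}")
})

test_that("metrics agree with the brute-force oracle on random vectors", {
  set.seed(314)
  for (rep in seq_len(100)) {
    n <- sample(5:60, 1)
    truth <- sample(1:3, n, replace = TRUE)
    est <- sample(1:3, n, replace = TRUE)
    prob <- matrix(rexp(n * 3), n, 3)
    prob <- prob / rowSums(prob)
    got <- compute_metrics(truth, est, prob)
    want <- oracle_metrics(truth, est, prob)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(got$jaccard, want$jaccard, tolerance = 1e-12)
    expect_equal(got$log_loss, want$log_loss, tolerance = 1e-12)
    expect_equal(unname(got$confusion), want$confusion,
                 ignore_attr = TRUE)
  }
})

test_that("class cutoffs are midpoints of adjacent range boundaries", {
  d <- toy_dataset(2)
  d$C3 <- c(1, 2, 4, 6, 8, 10) # rows are class-ordered in the toy table
  d <- add_ratio_features(d)
  cuts <- class_cutoffs(d, "C3")
  expect_equal(cuts$cut_point, c(3, 7))
  expect_false(any(cuts$overlap))

  # overlapping ranges: formula applied verbatim, with a warning
  d2 <- d
  d2$C3 <- c(1, 5, 4, 6, 8, 10)
  d2 <- add_ratio_features(d2)
  expect_warning(cuts2 <- class_cutoffs(d2, "C3"), "overlap")
  expect_equal(cuts2$cut_point[1], 4.5)
  expect_true(cuts2$overlap[1])

  # identical adjacent boundary values collapse to that value
  d3 <- d
  d3$C3 <- c(1, 4, 4, 6, 8, 10)
  d3 <- add_ratio_features(d3)
  expect_equal(class_cutoffs(d3, "C3")$cut_point[1], 4)

  expect_error(class_cutoffs(d, "nope"), "not found")
  expect_error(class_cutoffs(d[d$Maturation != 2, ], "C3"), "three classes")
})

test_that("raising the middle class raises both cutoffs monotonically", {
  d <- toy_dataset(4, seed = 2)
  base <- class_cutoffs(d, "C3")
  d_up <- d
  d_up$C3[d_up$Maturation == 2] <- d_up$C3[d_up$Maturation == 2] + 0.5
  d_up <- add_ratio_features(d_up)
  up <- class_cutoffs(d_up, "C3")
  expect_gt(up$cut_point[1], base$cut_point[1])
  expect_gt(up$cut_point[2], base$cut_point[2])
})

test_that("the combined final cutoff couples the product and sum cutoffs", {
  expect_equal(round(final_cutoff(0.62, 1.56), 2), 39.74)
  expect_equal(final_cutoff(0.365, 1.22), 29.9180327869, tolerance = 1e-10)
  expect_equal(final_cutoff(1, 1), 100)
  expect_error(final_cutoff(1, 0), "nonzero")

  d <- toy_dataset(5, seed = 31)
  rep <- cutoff_report(d)
  expect_s3_class(rep, "cvd_cutoffs")
  sum_cuts <- rep$cut_points$cut_point[rep$cut_points$feature == "SumC3C4"]
  prod_cuts <- rep$cut_points$cut_point[rep$cut_points$feature == "C3C4"]
  expect_equal(rep$final$final_cutoff, 100 * prod_cuts / sum_cuts)
  gl <- glance(rep)
  expect_named(gl, c("final_cutoff_1", "final_cutoff_2"))
})
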