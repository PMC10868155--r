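test_that("window points are mean score and local precision per window", {
  pts <- window_points(c(0.9, 0.8, 0.7, 0.6),
                       c("TP", "TP", "FP", "FP"),
                       window = 2L, step = 2L)
  expect_equal(pts$x, c(0.85, 0.65))
  expect_equal(pts$y, c(1, 0))
  # all-TP stream has precision 1 in every window
  pts1 <- window_points(seq(1, 0, length.out = 30),
                        rep("TP", 30), window = 10L, step = 5L)
  expect_true(all(pts1$y == 1))
})

test_that("windowing skips excluded labels and matches brute force", {
  set.seed(51)
  n <- 200L
  scores <- sort(runif(n, -1, 1), decreasing = TRUE)
  labels <- sample(c("TP", "FP", "EXCLUDED"), n, TRUE,
                   prob = c(0.4, 0.4, 0.2))
  w <- 25L; s <- 7L
  pts <- window_points(scores, labels, window = w, step = s)
  ev_scores <- scores[labels != "EXCLUDED"]
  ev_tp <- labels[labels != "EXCLUDED"] == "TP"
  starts <- seq(1L, length(ev_scores) - w + 1L, by = s)
  expect_equal(nrow(pts), length(starts))
  for (k in seq_along(starts)) {
    win <- starts[k]:(starts[k] + w - 1L)
    expect_equal(pts$x[k], mean(ev_scores[win]))
    expect_equal(pts$y[k], mean(ev_tp[win]))
  }
  expect_error(window_points(scores[1:10], labels[1:10], window = 50L),
               "window")
})

test_that("calibration function evaluation matches the scalar formula", {
  expect_equal(eval_calibration(c(-1, 0, 2), c(0.5, 0, 0, 3, 0.1)),
               calib_oracle(c(-1, 0, 2), c(0.5, 0, 0, 3, 0.1)))
  # steep logistic approaches a step without overflowing
  expect_equal(eval_calibration(1, c(0, 0, 1, -1e4, 0)), 1)
  expect_equal(eval_calibration(-1, c(0, 0, 1, -1e4, 0)), 0)
  expect_true(all(is.finite(eval_calibration(seq(-1, 1, 0.01),
                                             c(0, 0, 1, 800, 0)))))
  set.seed(52)
  for (rep in 1:20) {
    a <- c(runif(1, -0.2, 0.2), runif(1, -0.5, 0.5), runif(1, 0, 1),
           runif(1, -30, 30), runif(1, -1, 1))
    x <- seq(-1, 1, length.out = 41)
    expect_equal(eval_calibration(x, a), calib_oracle(x, a),
                 tolerance = 1e-12)
  }
})

test_that("simplex fit recovers a known calibration curve", {
  truth <- c(0.05, 0.1, 0.8, -8, 0.5)
  x <- seq(-1, 1, length.out = 60)
  pts <- data.frame(x = x, y = calib_oracle(x, truth), n = 100L)
  fit <- fit_calibration(pts)
  dev <- max(abs(eval_calibration(x, fit) - calib_oracle(x, truth)))
  expect_lt(dev, 1e-3)
  # determinism: same points, same parameters
  expect_identical(fit_calibration(pts)$params, fit$params)
  # noisy recovery stays close to the true curve
  set.seed(53)
  noisy <- pts
  noisy$y <- noisy$y + rnorm(nrow(pts), sd = 0.02)
  fit_n <- fit_calibration(noisy)
  expect_lt(max(abs(eval_calibration(x, fit_n) - calib_oracle(x, truth))),
            0.05)
})

test_that("degenerate point sets fit cleanly", {
  pts <- data.frame(x = seq(-1, 1, length.out = 20), y = 0.3)
  fit <- fit_calibration(pts)
  expect_lt(max(abs(eval_calibration(pts$x, fit) - 0.3)), 1e-6)
  expect_error(fit_calibration(pts[1:5, ]), "at least 10")
})

test_that("network calibration clamps to [0,1] and preserves ranking", {
  fx <- tiny_fixture()
  net <- pairwise_pcc(preprocess_matrix(fx$matrix))
  # monotone increasing curve over scores
  params <- c(0.1, 0.05, 0.8, -10, 0.3)
  cal <- calibrate_network(net, params)
  expect_equal(cal$probability,
               pmin(pmax(eval_calibration(net$score, params), 0), 1))
  expect_true(all(cal$probability >= 0 & cal$probability <= 1))
  expect_equal(cor(rank(cal$probability), rank(cal$score),
                   method = "spearman"), 1, tolerance = 1e-12)
  # a decreasing-in-score curve is flagged as reordering
  expect_warning(calibrate_network(net, c(0.5, -0.4, 0, 1, 0)),
                 "non-monotone")
  iso <- suppressWarnings(
    calibrate_network(net, c(0.5, -0.4, 0, 1, 0), isotonic = TRUE))
  expect_true(all(diff(iso$probability) <= 1e-12))
})
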