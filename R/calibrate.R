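#' Sliding-window precision points along a ranked label stream
#'
#' Slides a window down the score-ranked, gold-standard-labeled pair list
#' and records, for each window, the mean raw score (x) and the local
#' precision TP/(TP+FP) (y). These points are what the calibration
#' function is fitted to. EXCLUDED labels are removed before windowing.
#'
#' @param scores Numeric scores, sorted descending; alternatively a
#'   `vaenet_curve` from [cumulative_curve()], in which case `labels` is
#'   ignored.
#' @param labels Parallel character labels (`"TP"`, `"FP"`, `"EXCLUDED"`).
#' @param window Window size in evaluable pairs (>= 2; at least 10 is
#'   recommended for usable precision estimates). Default 1000,
#'   suited to atlas-scale networks; use smaller values for small inputs.
#' @param step Offset between consecutive window starts. Default 100.
#' @return Data frame with columns `x` (mean score), `y` (precision), `n`
#'   (window size), ordered as the windows were taken (x non-increasing).
#' @export
window_points <- function(scores, labels, window = 1000L, step = 100L) {
  if (inherits(scores, "vaenet_curve")) {
    curve <- scores
    scores <- curve$scores
    labels <- curve$labels[curve$labels != "EXCLUDED"]
  }
  stopifnot(length(scores) == length(labels), window >= 2L, step >= 1L)
  keep <- labels != "EXCLUDED"
  scores <- scores[keep]; labels <- labels[keep]
  if (is.unsorted(rev(scores))) {
    stop("scores must be sorted in descending order", call. = FALSE)
  }
  n <- length(scores)
  if (n < window) {
    stop("only ", n, " evaluable pairs but window = ", window, call. = FALSE)
  }
  is_tp <- labels == "TP"
  starts <- seq(1L, n - window + 1L, by = step)
  cs_tp <- c(0, cumsum(is_tp))
  cs_sc <- c(0, cumsum(scores))
  ends <- starts + window - 1L
  data.frame(
    x = (cs_sc[ends + 1L] - cs_sc[starts]) / window,
    y = (cs_tp[ends + 1L] - cs_tp[starts]) / window,
    n = window)
}

#' Evaluate the five-parameter calibration function
#'
#' The calibration curve maps a raw similarity score x to a local
#' precision estimate:
#' `y = a0 + a1 * x + a2 / (1 + exp(a3 * (x - a4)))` —
#' a linear trend plus a logistic step whose location (a4), steepness (a3)
#' and height (a2) are fitted. Overflow in the exponential saturates the
#' logistic term at 0 or a2 rather than producing NaN. The raw function is
#' unbounded; it is clamped to [0, 1] only where it is used as a
#' probability (see [calibrate_network()]).
#'
#' @param x Numeric vector of scores.
#' @param params Numeric vector `c(a0, a1, a2, a3, a4)` or a
#'   `vaenet_calibration` object.
#' @return Numeric vector of fitted values (unclamped).
#' @export
eval_calibration <- function(x, params) {
  if (inherits(params, "vaenet_calibration")) params <- params$params
  stopifnot(length(params) == 5L, all(is.finite(params)))
  a <- as.numeric(params)
  t <- a[4L] * (x - a[5L])
  # stable logistic: never exponentiates a large positive number
  logi <- ifelse(t >= 0, exp(-pmin(t, 700)) / (1 + exp(-pmin(t, 700))),
                 1 / (1 + exp(pmax(t, -700))))
  a[1L] + a[2L] * x + a[3L] * logi
}

#' Fit the calibration function to window-precision points
#'
#' Minimizes the sum of squared errors between the window points and the
#' five-parameter curve of [eval_calibration()] with Nelder-Mead simplex
#' optimization, restarted from a small deterministic grid of starting
#' values (a2 in \{0.5, 1\}, a3 in \{-20, -5, 5\}, a4 = median x,
#' a0 = min y, a1 = 0); the best SSE wins, ties going to the first start
#' in grid order. No randomness is involved, so identical inputs always
#' give identical parameters.
#'
#' @param points Data frame from [window_points()] (columns `x`, `y`);
#'   at least 10 points.
#' @param maxit Maximum simplex iterations per start (default 5000).
#' @return A list of class `vaenet_calibration`: `params` (named a0..a4),
#'   `sse`, `converged` (logical), and the fitted `points`.
#' @export
fit_calibration <- function(points, maxit = 5000L) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% colnames(points)))
  if (nrow(points) < 10L) {
    stop("need at least 10 window points to fit the calibration curve",
         call. = FALSE)
  }
  x <- points$x; y <- points$y
  sse_fn <- function(a) {
    r <- y - eval_calibration(x, a)
    sum(r * r)
  }
  starts <- expand.grid(a2 = c(0.5, 1), a3 = c(-20, -5, 5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    init <- c(min(y), 0, starts$a2[i], starts$a3[i], stats::median(x))
    fit <- stats::optim(init, sse_fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$convergence != 0L) {
    warning("calibration fit did not fully converge; returning best-so-far")
  }
  params <- best$par
  names(params) <- paste0("a", 0:4)
  structure(list(params = params, sse = best$value,
                 converged = best$convergence == 0L, points = points),
            class = "vaenet_calibration")
}

#' @export
print.vaenet_calibration <- function(x, ...) {
  cat("Calibration curve y = a0 + a1*x + a2/(1 + exp(a3*(x - a4)))\n")
  print(round(x$params, 5L))
  cat("SSE:", format(x$sse, digits = 5L),
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' Attach calibrated probabilities to a scored network
#'
#' Applies the fitted calibration curve to every pair's raw score and
#' stores the result, clamped to [0, 1], in a `probability` column. The
#' ranking is unchanged: when the fitted curve is monotone non-decreasing
#' over the observed score range — the usual case — ranking by probability
#' equals ranking by score. An unconstrained fit can come out locally
#' non-monotone; this is detected on the observed scores and reported as a
#' warning, and `isotonic = TRUE` replaces the fitted values by their
#' isotonic (monotone non-decreasing in score) regression instead.
#'
#' @param net A scored network.
#' @param calibration A `vaenet_calibration` (or a0..a4 vector).
#' @param isotonic Replace the curve by its isotonic regression on the
#'   observed scores (default `FALSE`).
#' @return The network with a `probability` column; the number of clamped
#'   pairs is attached as attribute `"n_clamped"`.
#' @export
calibrate_network <- function(net, calibration, isotonic = FALSE) {
  net <- as_scored_network(net)
  p_raw <- eval_calibration(net$score, calibration)
  # net is sorted by score descending; monotone curve means p non-increasing
  viol <- sum(diff(p_raw) > 1e-12)
  if (viol > 0L && !isotonic) {
    warning("fitted calibration curve is non-monotone on the observed ",
            "score range (", viol, " rank inversions); consider ",
            "isotonic = TRUE")
  }
  if (isotonic) {
    # isoreg fits non-decreasing; scores are descending, so reverse
    p_raw <- rev(stats::isoreg(rev(net$score), rev(p_raw))$yf)
  }
  p <- pmin(pmax(p_raw, 0), 1)
  out <- net
  out$probability <- p
  attr(out, "n_clamped") <- sum(p != p_raw)
  out
}
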