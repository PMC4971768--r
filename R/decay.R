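# Distance-decay model: equal-occupancy binning + monotone log-log spline.

#' Split contacts into equal-occupancy distance bins
#'
#' Contacts are sorted by distance and partitioned so that each bin carries an
#' (approximately) equal number of reads. All reads at one distance always
#' fall in the same bin: when a bin boundary would split a distance value it
#' moves to the next distinct distance, so occupancies are equal only up to
#' that constraint (exact to within one contact when all distances are
#' distinct and counts are 1).
#'
#' @param contacts Contacts data.frame (`k`, `D`).
#' @param n_bins Number of bins (default 50).
#' @return data.frame with one row per bin: `bin`, `a`/`b` (lowest/highest
#'   distance in bin, bp), `n_reads`, `C` (per-bp contact intensity,
#'   `n_reads / (b - a + 1)`) and `D` (read-weighted mean distance).
#' @export
equal_occupancy_bins <- function(contacts, n_bins = 50) {
  .assert_df_cols(contacts, c("k", "D"), "contacts")
  if (sum(contacts$k) < n_bins) stop("fewer reads than bins")
  tab <- rowsum(as.numeric(contacts$k), contacts$D)
  d <- as.numeric(rownames(tab))
  n <- as.numeric(tab[, 1L])
  ord <- order(d)
  d <- d[ord]; n <- n[ord]
  if (length(d) < n_bins) {
    stop("only ", length(d), " distinct distances; choose n_bins <= that")
  }
  total <- sum(n)
  bin_id <- integer(length(d))
  bin <- 1L
  acc <- 0
  used <- 0
  for (i in seq_along(d)) {
    bin_id[i] <- bin
    acc <- acc + n[i]
    remaining_bins <- n_bins - bin + 1L
    target <- (total - used) / remaining_bins
    # close the bin on reaching its target, or when the remaining distinct
    # distances are only just enough to give each later bin one value
    must_close <- (length(d) - i) <= (n_bins - bin)
    if ((acc >= target || must_close) && bin < n_bins && i < length(d)) {
      used <- used + acc
      acc <- 0
      bin <- bin + 1L
    }
  }
  res <- lapply(seq_len(n_bins), function(b) {
    sel <- bin_id == b
    st <- bin_statistics(d[sel], n[sel])
    data.frame(bin = b, a = st$a, b = st$b, n_reads = st$n_reads,
               C = st$C, D = st$D)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Per-bin decay statistics
#'
#' Intensity is the total read count divided by the bin's distance span in bp,
#' `C = N / (b - a + 1)`; the representative distance is the read-weighted
#' mean of the distances in the bin.
#'
#' @param distances Distinct distances (bp) falling in the bin.
#' @param counts Read counts at each distance.
#' @return list with `a`, `b`, `n_reads`, `C`, `D`.
#' @export
bin_statistics <- function(distances, counts) {
  if (!length(distances)) stop("empty bin")
  a <- min(distances); b <- max(distances)
  n <- sum(counts)
  list(a = a, b = b, n_reads = n,
       C = n / (b - a + 1),
       D = sum(counts * distances) / n)
}

#' Fit the monotone distance-decay model
#'
#' Fits a cubic smoothing spline to the (log D, log C) bin points, projects
#' the fitted values onto the nearest non-increasing sequence (antitonic
#' regression in log space), and interpolates linearly in log-log space
#' between the bin knots. Evaluation outside the fitted domain clamps to the
#' boundary value, so the model is positive and non-increasing everywhere.
#'
#' @param bins Bin table from [equal_occupancy_bins()].
#' @param df Target effective degrees of freedom of the spline (default 8;
#'   ignored when `spar` is given).
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()].
#' @return An object of class `decay_model`.
#' @seealso [evaluate_decay()], [decay_slope()]
#' @export
fit_decay <- function(bins, df = 8, spar = NULL) {
  .assert_df_cols(bins, c("C", "D"), "bins")
  bins <- bins[order(bins$D), , drop = FALSE]
  if (any(bins$C <= 0)) stop("non-positive bin intensity; cannot take logs")
  x <- log(bins$D); y <- log(bins$C)
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need at least 4 distinct bins to fit the decay model")
  fit <- if (is.null(spar)) {
    stats::smooth.spline(x, y, df = min(df, length(x) - 1L))
  } else {
    stats::smooth.spline(x, y, spar = spar)
  }
  yhat <- stats::predict(fit, x)$y
  # antitonic (non-increasing) projection
  ymono <- -stats::isoreg(x, -yhat)$yf
  structure(
    list(log_d = x, log_c = ymono, domain = range(exp(x)),
         df = fit$df, spar = fit$spar, n_bins = length(x)),
    class = "decay_model"
  )
}

#' Evaluate the decay model at given distances
#'
#' @param model A `decay_model` from [fit_decay()].
#' @param D Distances in bp (must be positive).
#' @return Expected per-bp contact intensity f(D); positive and
#'   non-increasing in D, clamped to the boundary values outside the fitted
#'   domain.
#' @export
evaluate_decay <- function(model, D) {
  stopifnot(inherits(model, "decay_model"))
  if (any(D <= 0)) stop("distances must be positive")
  exp(stats::approx(model$log_d, model$log_c, xout = log(D), rule = 2)$y)
}

#' @export
predict.decay_model <- function(object, D, ...) evaluate_decay(object, D)

#' @export
print.decay_model <- function(x, ...) {
  cat("Monotone distance-decay model\n")
  cat(sprintf("  knots: %d bins over %.0f - %.0f bp\n",
              x$n_bins, x$domain[1], x$domain[2]))
  cat(sprintf("  spline effective df: %.2f (spar %.3f)\n", x$df, x$spar))
  cat(sprintf("  log-log slope (least squares over knots): %.3f\n",
              decay_slope(x)))
  invisible(x)
}

#' @export
plot.decay_model <- function(x, ...) {
  graphics::plot(exp(x$log_d), exp(x$log_c), log = "xy",
                 xlab = "distance (bp)", ylab = "contact intensity (per bp)",
                 type = "b", pch = 16, ...)
  invisible(x)
}

#' Log-log slope of a fitted decay model
#'
#' Least-squares slope of log f(D) on log D over an evenly log-spaced grid in
#' the fitted domain; for a power-law decay C ~ D^alpha this recovers alpha.
#'
#' @param model A `decay_model`.
#' @param n_grid Grid size (default 200).
#' @return The slope (dimensionless).
#' @export
decay_slope <- function(model, n_grid = 200) {
  ld <- seq(log(model$domain[1]), log(model$domain[2]), length.out = n_grid)
  lc <- log(evaluate_decay(model, exp(ld)))
  unname(stats::coef(stats::lm(lc ~ ld))[2L])
}
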