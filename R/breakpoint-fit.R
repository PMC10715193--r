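#' @keywords internal
#' Residual sum of squares of the continuous two-segment model at a fixed
#' breakpoint. The model y = b0 + b1*x + b2*(x - psi)_+ is linear in its
#' coefficients once psi is fixed.
#' @noRd
seg_rss_at <- function(x, y, psi) {
  Z <- cbind(1, x, pmax(x - psi, 0))
  fit <- stats::lm.fit(Z, y)
  rss <- sum(fit$residuals^2)
  list(rss = rss, coef = fit$coefficients)
}

seg_result <- function(x, y, psi, coef, rss, converged, break_se = NA_real_,
                       label = NULL, min_segment = NULL) {
  b0 <- unname(coef[1L]); b1 <- unname(coef[2L]); b2 <- unname(coef[3L])
  if (is.na(b2)) b2 <- 0
  left <- x <= psi
  n1 <- sum(left); n2 <- sum(!left)
  side_fit <- function(sel) {
    if (sum(sel) >= 3L && (max(x[sel]) - min(x[sel])) > 0) {
      ols_fit(list(x = x[sel], y = y[sel], n_dropped_zero = 0L, label = label))
    } else NULL
  }
  f1 <- side_fit(left); f2 <- side_fit(!left)
  structure(list(
    break_x = psi,
    slope1 = b1, slope2 = b1 + b2,
    intercept1 = b0,
    rss = rss,
    n1 = n1, n2 = n2,
    slope1_ci95 = if (!is.null(f1)) f1$slope_ci95 else NA_real_,
    slope2_ci95 = if (!is.null(f2)) f2$slope_ci95 else NA_real_,
    break_ci95 = if (is.finite(break_se)) stats::qt(0.975, length(x) - 4L) * break_se
                 else NA_real_,
    segment_fits = list(below = f1, above = f2),
    break_percentile = 100 * mean(x < psi),
    converged = converged,
    label = label),
    class = "segmented_fit")
}

#' Admissible breakpoint interval given a minimum segment size
#' @noRd
psi_bounds <- function(x, min_segment) {
  xs <- sort(x)
  n <- length(xs)
  # keep >= min_segment points on each side: left side counts x <= psi,
  # right side x > psi, so psi must stay strictly below xs[n - min_segment + 1]
  lo <- xs[min_segment]
  hi <- xs[n - min_segment + 1L] - 1e-8 * max(1, xs[n] - xs[1L])
  c(lo, hi)
}

default_min_segment <- function(n) max(10L, ceiling(0.05 * n))

#' Continuous two-segment fit in log-log space
#'
#' Fits the continuous piecewise-linear model
#' `y = b0 + b1*x + b2*(x - psi)_+` by least squares over both the
#' coefficients and the breakpoint position `psi`, using iterative
#' linearization (Muggeo-style updates) started from a grid of initial
#' breakpoints. Both segments are required to hold at least `min_segment`
#' points. If no start converges, the exhaustive grid optimum
#' ([grid_oracle()]) is returned with a warning.
#'
#' After locating the breakpoint, each side is also refit independently with
#' [ols_fit()]; those per-segment fits supply the reported slope confidence
#' intervals (`slope1_ci95`, `slope2_ci95`) and are kept in `segment_fits`.
#' The slopes `slope1`/`slope2` themselves come from the joint continuous fit
#' that determines `rss`. The breakpoint half-width `break_ci95` uses the
#' delta-method standard error of the linearized update and is approximate.
#'
#' @param input A `fit_input` with x = log10 totals, y = log10 counts.
#' @param min_segment Minimum points per segment; default
#'   `max(10, ceiling(0.05 * n))`.
#' @param n_starts Number of initial breakpoints (quantiles of x) for the
#'   iterative search.
#' @param n_breakpoints Number of breakpoints; only 1 is implemented.
#' @param max_iter,tol Iteration controls.
#' @return An object of class `segmented_fit`; see Details for fields.
#' @export
segmented_fit <- function(input, min_segment = NULL, n_starts = 10L,
                          n_breakpoints = 1L, max_iter = 50L, tol = 1e-8) {
  if (n_breakpoints != 1L) {
    stop("only a single breakpoint is implemented")
  }
  x <- input$x; y <- input$y
  n <- length(x)
  if (is.null(min_segment)) min_segment <- default_min_segment(n)
  min_segment <- max(2L, as.integer(min_segment))
  if (n < 2L * min_segment) {
    stop("insufficient data: ", n, " points for two segments of at least ",
         min_segment)
  }
  if (length(unique(x)) < 2L * min_segment) {
    stop("insufficient distinct x values for two segments of ", min_segment)
  }
  bounds <- psi_bounds(x, min_segment)
  if (bounds[2L] <= bounds[1L]) {
    stop("no admissible breakpoint interval at min_segment = ", min_segment)
  }
  # coarse rss profile over the admissible interval; the best points seed the
  # iterative search (the profile can be multimodal under noise, so starts
  # chosen by rss are much more reliable than quantiles of x)
  n_coarse <- max(n_starts * 3L, 30L)
  coarse <- seq(bounds[1L], bounds[2L], length.out = n_coarse)
  coarse_rss <- vapply(coarse, function(p) seg_rss_at(x, y, p)$rss, numeric(1))
  starts <- coarse[order(coarse_rss)][seq_len(min(n_starts, n_coarse))]

  best <- NULL
  for (psi0 in starts) {
    psi <- psi0
    visited <- numeric(0)
    converged <- FALSE
    break_se <- NA_real_
    start_best <- NULL  # best psi visited from this start (rss can oscillate)
    for (it in seq_len(max_iter)) {
      U <- pmax(x - psi, 0)
      V <- -(x > psi)
      fit <- stats::lm(y ~ x + U + V)
      cf <- stats::coef(fit)
      rss_now <- seg_rss_at(x, y, psi)$rss
      if (is.null(start_best) || rss_now < start_best$rss) {
        start_best <- list(psi = psi, rss = rss_now)
      }
      b2 <- unname(cf["U"]); gam <- unname(cf["V"])
      if (is.na(b2) || is.na(gam) || abs(b2) < 1e-12) {
        # no detectable slope change at this psi: treat as converged here
        converged <- TRUE
        break
      }
      step <- gam / b2
      psi_new <- min(max(psi + step, bounds[1L]), bounds[2L])
      # converged when the update stalls or revisits any earlier breakpoint
      # (on discrete data the linearized update settles into cycles around
      # an optimum); the best rss visited is then the solution
      if (abs(psi_new - psi) < tol ||
          any(abs(psi_new - visited) < tol)) {
        converged <- TRUE
        sm <- suppressWarnings(summary(fit))$coefficients
        if ("V" %in% rownames(sm)) {
          break_se <- sm["V", "Std. Error"] / abs(b2)
        }
        rss_new <- seg_rss_at(x, y, psi_new)$rss
        if (rss_new < start_best$rss) {
          start_best <- list(psi = psi_new, rss = rss_new)
        }
        break
      }
      visited <- c(visited, psi)
      psi <- psi_new
    }
    if (converged && !is.null(start_best)) {
      cand <- list(psi = start_best$psi, rss = start_best$rss,
                   break_se = break_se)
      if (is.null(best) || cand$rss < best$rss ||
          (cand$rss == best$rss && cand$psi < best$psi)) {
        best <- cand
      }
      # polish each converged candidate within one coarse-grid spacing: the
      # linearized update can stall one data gap away from the optimum
      w <- (bounds[2L] - bounds[1L]) / n_coarse
      opt <- stats::optimize(function(p) seg_rss_at(x, y, p)$rss,
                             lower = max(bounds[1L], cand$psi - w),
                             upper = min(bounds[2L], cand$psi + w),
                             tol = 1e-10)
      if (opt$objective < best$rss) {
        best <- list(psi = opt$minimum, rss = opt$objective,
                     break_se = break_se)
      }
    }
  }
  if (is.null(best)) {
    warning("breakpoint iteration did not converge from any start; ",
            "falling back to exhaustive grid search")
    return(grid_oracle(input, min_segment = min_segment))
  }
  at <- seg_rss_at(x, y, best$psi)
  seg_result(x, y, best$psi, at$coef, at$rss, converged = TRUE,
             break_se = best$break_se, label = input$label,
             min_segment = min_segment)
}

#' Exhaustive breakpoint search (test oracle)
#'
#' Brute-force counterpart of [segmented_fit()]: evaluates the continuous
#' two-segment least-squares fit at every candidate breakpoint placed at the
#' midpoint between consecutive sorted distinct x values (restricted so both
#' segments keep `min_segment` points) and returns the RSS-minimal fit.
#' Ties are broken toward the smallest breakpoint.
#'
#' @inheritParams segmented_fit
#' @return A `segmented_fit` object (with `break_ci95 = NA`).
#' @export
grid_oracle <- function(input, min_segment = NULL) {
  x <- input$x; y <- input$y
  n <- length(x)
  if (is.null(min_segment)) min_segment <- default_min_segment(n)
  min_segment <- max(2L, as.integer(min_segment))
  if (n < 2L * min_segment) {
    stop("insufficient data: ", n, " points for two segments of at least ",
         min_segment)
  }
  xs <- sort(unique(x))
  mids <- (xs[-1L] + xs[-length(xs)]) / 2
  bounds <- psi_bounds(x, min_segment)
  mids <- mids[mids >= bounds[1L] & mids <= bounds[2L]]
  if (length(mids) == 0L) {
    stop("no admissible candidate breakpoints at min_segment = ", min_segment)
  }
  best <- NULL
  for (psi in mids) {  # mids ascending: strict < keeps the smallest rss tie
    at <- seg_rss_at(x, y, psi)
    if (is.null(best) || at$rss < best$rss - 1e-12) {
      best <- list(psi = psi, rss = at$rss, coef = at$coef)
    }
  }
  seg_result(x, y, best$psi, best$coef, best$rss, converged = TRUE,
             label = input$label, min_segment = min_segment)
}

#' @export
print.segmented_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Segmented power-law fit: breakpoint at log10(x) = %.*f (%.0f%% of organisms below)\n",
              digits, x$break_x, x$break_percentile))
  cat(sprintf("  slope below: %.*f   slope above: %.*f   RSS: %.*g   (n = %d + %d)\n",
              digits, x$slope1, digits, x$slope2, digits, x$rss, x$n1, x$n2))
  invisible(x)
}

#' Choose between a single power law and a breakpoint model
#'
#' Fits both the single-line model ([ols_fit()]) and the continuous
#' two-segment model ([segmented_fit()]) and selects the breakpoint model
#' when it yields a sufficient improvement in goodness of fit: the ratio of
#' the segmented RSS to the single-line RSS must drop by at least
#' `threshold` (default 5%), i.e. `rss_ratio <= 1 - threshold`. A perfect
#' single-line fit (RSS 0) never selects a breakpoint. If the segmented fit
#' is infeasible (too few points), the single model is kept with
#' `rss_ratio = NA`.
#'
#' @param input A `fit_input`.
#' @param threshold Required relative RSS decrease in (0, 1); default 0.05.
#' @param min_segment Passed to [segmented_fit()].
#' @return An object of class `scaling_model`: list with `kind`
#'   (`"single"`/`"segmented"`), `single` (`power_law_fit`), `segmented`
#'   (`segmented_fit` or `NULL`), `rss_ratio`, `threshold`.
#' @export
select_model <- function(input, threshold = 0.05, min_segment = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  single <- ols_fit(input)
  if (single$rss <= 1e-12) {
    return(structure(list(kind = "single", single = single, segmented = NULL,
                          rss_ratio = 1, threshold = threshold),
                     class = "scaling_model"))
  }
  seg <- tryCatch(segmented_fit(input, min_segment = min_segment),
                  error = function(e) NULL)
  if (is.null(seg)) {
    return(structure(list(kind = "single", single = single, segmented = NULL,
                          rss_ratio = NA_real_, threshold = threshold),
                     class = "scaling_model"))
  }
  ratio <- seg$rss / single$rss
  kind <- if (ratio <= 1 - threshold) "segmented" else "single"
  structure(list(kind = kind, single = single, segmented = seg,
                 rss_ratio = ratio, threshold = threshold),
            class = "scaling_model")
}

#' @export
print.scaling_model <- function(x, digits = 3, ...) {
  cat(sprintf("Scaling model: %s (RSS ratio %.3f, threshold %.0f%%)\n",
              x$kind, x$rss_ratio, 100 * x$threshold))
  print(x$single, digits = digits)
  if (!is.null(x$segmented)) print(x$segmented, digits = digits)
  invisible(x)
}
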