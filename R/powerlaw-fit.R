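#' Assemble log-log fit input for one category
#'
#' Extracts, for one COG category and an optional subset of organisms, the
#' vectors x = log10(total annotations) and y = log10(category count) that all
#' scaling fits operate on. Organisms with a zero count in the category are
#' either dropped (and tallied) or kept via a +1 pseudocount.
#'
#' @param matrix A `cog_matrix`.
#' @param category Single category letter.
#' @param selector Optional logical or character vector selecting organisms
#'   (logical over rows, or organism ids).
#' @param zero_policy `"drop"` (default) removes zero-count organisms and
#'   reports how many were removed; `"pseudocount"` uses `log10(count + 1)`.
#' @param min_n Minimum number of usable points (default 3); fewer raises an
#'   insufficient-data error (this is how NA cells in per-group fit tables
#'   arise).
#' @param x_source `"total"` (default) uses the realized per-organism row-sum
#'   total as x; `"target"` uses the generative target total recorded by
#'   [simulate_matrix()] (only available on simulated matrices) — useful for
#'   parameter-recovery experiments where the category of interest dominates
#'   its own row sum.
#' @param group Group tag recorded in the fit label.
#'
#' @return A list of class `fit_input` with elements `x`, `y`,
#'   `n_dropped_zero`, `label` (category/group tag), `organism`.
#' @export
make_fit_input <- function(matrix, category, selector = NULL,
                           zero_policy = c("drop", "pseudocount"),
                           min_n = 3L, group = "all",
                           x_source = c("total", "target")) {
  stopifnot(inherits(matrix, "cog_matrix"))
  zero_policy <- match.arg(zero_policy)
  x_source <- match.arg(x_source)
  if (x_source == "target" && is.null(matrix$total_target)) {
    stop("matrix carries no generative target totals (not simulated)")
  }
  if (!category %in% colnames(matrix$counts)) {
    stop("category ", category, " not present in matrix")
  }
  keep <- rep(TRUE, nrow(matrix$counts))
  if (!is.null(selector)) {
    if (is.logical(selector)) {
      stopifnot(length(selector) == nrow(matrix$counts))
      keep <- selector
    } else {
      keep <- rownames(matrix$counts) %in% selector
    }
  }
  cnt <- matrix$counts[keep, category]
  tot <- if (x_source == "target") matrix$total_target[keep]
         else matrix$total[keep]
  org <- rownames(matrix$counts)[keep]
  usable <- tot > 0L
  cnt <- cnt[usable]; tot <- tot[usable]; org <- org[usable]
  n_dropped <- 0L
  if (zero_policy == "drop") {
    nz <- cnt > 0L
    n_dropped <- sum(!nz)
    cnt <- cnt[nz]; tot <- tot[nz]; org <- org[nz]
    y <- log10(cnt)
  } else {
    y <- log10(cnt + 1)
  }
  if (length(y) < min_n) {
    stop("insufficient data for category ", category, " in group ", group,
         ": ", length(y), " usable points (minimum ", min_n, ")")
  }
  structure(list(x = log10(tot), y = y,
                 n_dropped_zero = as.integer(n_dropped),
                 label = c(category = category, group = group),
                 organism = org),
            class = "fit_input")
}

#' Internal constructor for fit_input from bare vectors
#' @noRd
fit_input <- function(x, y, n_dropped_zero = 0L,
                      label = c(category = "?", group = "all")) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 n_dropped_zero = as.integer(n_dropped_zero), label = label,
                 organism = NULL),
            class = "fit_input")
}

#' Fit a power law by OLS on log-transformed data
#'
#' Ordinary least-squares regression of log10 category count on log10 total
#' annotations. The slope is the scaling exponent; the intercept is the log10
#' normalization constant (the prefactor c in y = c * x^beta). 95% confidence
#' half-widths use the t distribution with n - 2 degrees of freedom times the
#' standard error of each estimate; both the half-widths and the raw standard
#' errors are reported.
#'
#' @param input A `fit_input` (see [make_fit_input()]), or any list with
#'   numeric `x` and `y`.
#' @return An object of class `power_law_fit` with elements `slope`,
#'   `intercept`, `slope_ci95`, `intercept_ci95`, `slope_se`, `intercept_se`,
#'   `n`, `rss`, `r` (Pearson correlation of x and y), `n_dropped_zero`,
#'   `label`.
#' @examples
#' f <- ols_fit(list(x = log10(c(1e3, 1e4, 1e5)), y = c(1, 2, 3)))
#' f$slope  # 1
#' @export
ols_fit <- function(input) {
  x <- input$x; y <- input$y
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L, all(is.finite(x)), all(is.finite(y)))
  if (max(x) - min(x) <= 0) {
    stop("degenerate design: x is constant, slope not identifiable")
  }
  fit <- stats::lm(y ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients
  tq <- stats::qt(0.975, df = n - 2L)
  res <- structure(list(
    slope = unname(cf["x", "Estimate"]),
    intercept = unname(cf["(Intercept)", "Estimate"]),
    slope_se = unname(cf["x", "Std. Error"]),
    intercept_se = unname(cf["(Intercept)", "Std. Error"]),
    slope_ci95 = unname(tq * cf["x", "Std. Error"]),
    intercept_ci95 = unname(tq * cf["(Intercept)", "Std. Error"]),
    n = n,
    rss = sum(stats::residuals(fit)^2),
    r = stats::cor(x, y),
    n_dropped_zero = input$n_dropped_zero %||% 0L,
    label = input$label %||% c(category = "?", group = "all")),
    class = "power_law_fit")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.power_law_fit <- function(x, digits = 3, ...) {
  lab <- x$label
  cat(sprintf("Power-law fit [%s | %s]: exponent %.*f +/- %.*f (95%% CI), ",
              lab[["category"]], lab[["group"]],
              digits, x$slope, digits, x$slope_ci95))
  cat(sprintf("log10 c = %.*f +/- %.*f, n = %d, RSS = %.*g\n",
              digits, x$intercept, digits, x$intercept_ci95, x$n,
              digits, x$rss))
  invisible(x)
}

#' Bin fit input along the log10 x axis
#'
#' OLS fits can be dominated by the x range holding the most genomes; binning
#' counteracts this unequal sampling. The x axis is cut into `n_bins`
#' equal-width bins in log10 units; each non-empty bin contributes a single
#' point at (mean x in bin, mean y in bin), so points already on an exact
#' line stay exactly on it. Empty bins are dropped. The result is a
#' `fit_input` that feeds [ols_fit()].
#'
#' @param input A `fit_input`.
#' @param n_bins Number of equal-width bins (default 20).
#' @return A binned `fit_input`; fewer than 3 non-empty bins is an error.
#' @export
bin_points <- function(input, n_bins = 20L) {
  x <- input$x; y <- input$y
  stopifnot(n_bins >= 3L)
  if (max(x) - min(x) <= 0) stop("x span is zero; cannot bin")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  fbin <- factor(bin, levels = seq_len(n_bins))
  # the bin's x is the mean of x inside it (not the geometric bin center),
  # so that means of collinear points stay exactly collinear
  xmean <- tapply(x, fbin, mean)
  ymean <- tapply(y, fbin, mean)
  nonempty <- !is.na(ymean)
  if (sum(nonempty) < 3L) {
    stop("insufficient data: only ", sum(nonempty), " non-empty bins")
  }
  structure(list(x = unname(xmean[nonempty]), y = unname(ymean[nonempty]),
                 n_dropped_zero = input$n_dropped_zero,
                 label = input$label, organism = NULL),
            class = "fit_input")
}
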