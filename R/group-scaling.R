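#' Fit every (group, category) power law at domain or phylum level
#'
#' Splits the organisms by taxon at the requested level and fits one power
#' law per group and category via [make_fit_input()] + [ols_fit()]. Cells
#' with too few usable points are reported as NA rows with a reason rather
#' than dropped, mirroring how unfit-able categories appear as NA in summary
#' tables.
#'
#' @param matrix A `cog_matrix`.
#' @param level `"domain"` or `"phylum"`.
#' @param zero_policy,min_n Passed to [make_fit_input()].
#' @param binned If `TRUE`, points are binned with [bin_points()] before
#'   fitting.
#' @param n_bins Bins for `binned = TRUE`.
#' @return A data frame with one row per (group, category): `group`,
#'   `domain` (the domain the group's organisms belong to), `category`, `n`,
#'   `n_dropped_zero`, `slope`, `slope_ci95`, `slope_se`, `intercept`,
#'   `intercept_ci95`, `rss`, `r`, `binned`, `note` (NA reason or "").
#'   The per-cell `power_law_fit` objects are attached as attribute `fits`
#'   (a named list keyed `group|category`).
#' @export
fit_groups <- function(matrix, level = c("domain", "phylum"),
                       zero_policy = "drop", min_n = 3L,
                       binned = FALSE, n_bins = 20L) {
  stopifnot(inherits(matrix, "cog_matrix"))
  level <- match.arg(level)
  labels <- matrix$taxon[[level]]
  if (all(is.na(labels))) stop("no ", level, " labels present in matrix")
  groups <- sort(unique(labels[!is.na(labels)]))
  cats <- colnames(matrix$counts)
  rows <- list(); fits <- list()
  for (g in groups) {
    sel <- !is.na(labels) & labels == g
    dom <- if (level == "domain") g else {
      doms <- unique(matrix$taxon$domain[sel])
      doms[1L]
    }
    for (cc in cats) {
      fit <- tryCatch({
        inp <- make_fit_input(matrix, cc, selector = sel,
                              zero_policy = zero_policy, min_n = min_n,
                              group = g)
        if (binned) inp <- bin_points(inp, n_bins = n_bins)
        ols_fit(inp)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, domain = dom, category = cc, n = NA_integer_,
          n_dropped_zero = NA_integer_, slope = NA_real_,
          slope_ci95 = NA_real_, slope_se = NA_real_, intercept = NA_real_,
          intercept_ci95 = NA_real_, rss = NA_real_, r = NA_real_,
          binned = binned, note = conditionMessage(fit),
          stringsAsFactors = FALSE)
      } else {
        fits[[paste(g, cc, sep = "|")]] <- fit
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, domain = dom, category = cc, n = fit$n,
          n_dropped_zero = fit$n_dropped_zero, slope = fit$slope,
          slope_ci95 = fit$slope_ci95, slope_se = fit$slope_se,
          intercept = fit$intercept, intercept_ci95 = fit$intercept_ci95,
          rss = fit$rss, r = fit$r, binned = binned, note = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Z-statistic score for a phylum exponent against its domain exponent
#'
#' Quantifies how far a phylum's scaling exponent deviates from the
#' domain-level exponent, scaled by the slope error bars:
#' \deqn{Z = (\beta_{phylum} - \beta_{domain}) / \sqrt{e_p^2 - e_d^2}}
#' in `"as_printed"` mode (difference of squared errors under the root,
#' undefined when the phylum error does not exceed the domain error), or
#' with `e_p^2 + e_d^2` under the root in `"sum_of_squares"` mode, which is
#' always defined when either error is positive. The error bars are the 95%
#' CI half-widths of the slopes. Equal slopes give Z = 0 in both modes.
#'
#' @param group,domain `power_law_fit` objects (or lists with `slope` and
#'   `slope_ci95`).
#' @param mode `"as_printed"` (default) or `"sum_of_squares"`.
#' @return The Z score, or `NA` with attribute `reason` when undefined
#'   (negative radicand in `as_printed` mode, or both errors zero).
#' @export
z_statistic <- function(group, domain,
                        mode = c("as_printed", "sum_of_squares")) {
  mode <- match.arg(mode)
  gs <- group$slope; ge <- group$slope_ci95
  ds <- domain$slope; de <- domain$slope_ci95
  stopifnot(is.finite(gs), is.finite(ds), is.finite(ge), is.finite(de))
  num <- gs - ds
  if (num == 0) return(0)
  if (ge == 0 && de == 0) {
    return(structure(NA_real_, reason = "both slope errors are zero"))
  }
  rad <- if (mode == "as_printed") ge^2 - de^2 else ge^2 + de^2
  if (rad <= 0) {
    return(structure(NA_real_,
                     reason = "phylum error does not exceed domain error"))
  }
  num / sqrt(rad)
}

#' Z-score table across phyla and categories, ordered by Z range
#'
#' Computes the Z score of every (phylum, category) cell against the matching
#' domain-level fit and orders categories by the spread (max minus min) of
#' their defined Z scores, descending — the ordering used to rank categories
#' from most to least variable across phyla. Cells whose phylum or domain
#' fit is NA, or whose Z is undefined, are kept as NA rows with a reason.
#'
#' @param group_fits Output of `fit_groups(matrix, "phylum")`.
#' @param domain_fits Output of `fit_groups(matrix, "domain")`.
#' @param mode Passed to [z_statistic()].
#' @return Data frame with columns `category`, `group`, `domain`,
#'   `group_slope`, `group_err`, `domain_slope`, `domain_err`, `z`, `mode`,
#'   `reason`, ordered by per-category Z range (descending); the ranges are
#'   attached as attribute `z_range` (named numeric).
#' @export
z_table <- function(group_fits, domain_fits,
                    mode = c("as_printed", "sum_of_squares")) {
  mode <- match.arg(mode)
  rows <- list()
  for (i in seq_len(nrow(group_fits))) {
    gr <- group_fits[i, ]
    dr <- domain_fits[domain_fits$group == gr$domain &
                      domain_fits$category == gr$category, ]
    z <- NA_real_; reason <- ""
    if (is.na(gr$slope)) {
      reason <- "phylum fit NA"
    } else if (nrow(dr) == 0L || is.na(dr$slope[1L])) {
      reason <- "domain fit NA"
    } else {
      zz <- z_statistic(list(slope = gr$slope, slope_ci95 = gr$slope_ci95),
                        list(slope = dr$slope[1L],
                             slope_ci95 = dr$slope_ci95[1L]),
                        mode = mode)
      if (is.na(zz)) reason <- attr(zz, "reason") else z <- zz
    }
    rows[[i]] <- data.frame(
      category = gr$category, group = gr$group, domain = gr$domain,
      group_slope = gr$slope, group_err = gr$slope_ci95,
      domain_slope = if (nrow(dr)) dr$slope[1L] else NA_real_,
      domain_err = if (nrow(dr)) dr$slope_ci95[1L] else NA_real_,
      z = z, mode = mode, reason = reason, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  zr <- tapply(out$z, out$category, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else max(v) - min(v)
  })
  ord_cats <- names(sort(zr, decreasing = TRUE, na.last = TRUE))
  out <- out[order(match(out$category, ord_cats), out$group), ]
  rownames(out) <- NULL
  attr(out, "z_range") <- zr
  out
}

#' Overlay phylum annotation spans on domain breakpoint locations
#'
#' For every category whose domain-level model selected a breakpoint, lists
#' each phylum of that domain with the log10 range of total annotations its
#' organisms cover and whether that range straddles the breakpoint — i.e.
#' whether the phylum traverses the scaling-exponent shift. Phyla are
#' ordered from the most to the least spanning (count of straddled
#' categories).
#'
#' @param matrix A `cog_matrix`.
#' @param domain_models A list of entries `list(group =, category =,
#'   model = scaling_model)` as produced by [fit_scaling_models()].
#' @return Data frame with `phylum`, `domain`, `category`, `group_min_x`,
#'   `group_max_x` (log10 totals), `break_x` (log10), `spans_break`; empty
#'   (with a message) when no model is segmented.
#' @export
breakpoint_spans <- function(matrix, domain_models) {
  stopifnot(inherits(matrix, "cog_matrix"))
  seg <- Filter(function(e) e$model$kind == "segmented", domain_models)
  empty <- data.frame(phylum = character(), domain = character(),
                      category = character(), group_min_x = numeric(),
                      group_max_x = numeric(), break_x = numeric(),
                      spans_break = logical(), stringsAsFactors = FALSE)
  if (length(seg) == 0L) {
    message("no segmented domain models; breakpoint-span table is empty")
    return(empty)
  }
  tx <- matrix$taxon
  rows <- list()
  for (e in seg) {
    dom <- e$group
    bx <- e$model$segmented$break_x
    sel_dom <- !is.na(tx$domain) & tx$domain == dom
    phyla <- sort(unique(tx$phylum[sel_dom & !is.na(tx$phylum)]))
    for (ph in phyla) {
      sel <- sel_dom & !is.na(tx$phylum) & tx$phylum == ph
      lt <- log10(matrix$total[sel])
      mn <- min(lt); mx <- max(lt)
      rows[[length(rows) + 1L]] <- data.frame(
        phylum = ph, domain = dom, category = e$category,
        group_min_x = mn, group_max_x = mx, break_x = bx,
        spans_break = (mn < bx && bx < mx), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  nspan <- tapply(out$spans_break, out$phylum, sum)
  out <- out[order(-nspan[out$phylum], out$phylum, out$category), ]
  rownames(out) <- NULL
  out
}

#' Model selection for every (group, category) cell
#'
#' Runs [select_model()] per group (at the given taxon level) and category,
#' skipping cells with insufficient data.
#'
#' @inheritParams fit_groups
#' @param threshold,min_segment Passed to [select_model()].
#' @return A list of entries `list(group =, category =, model =
#'   scaling_model)`; a summary data frame is attached as attribute
#'   `summary` with columns `group`, `category`, `kind`, `rss_single`,
#'   `rss_segmented`, `rss_ratio`, `break_x_log10`, `break_percentile`,
#'   `slope1`, `slope1_ci95`, `slope2`, `slope2_ci95`, `slope`, `slope_ci95`.
#' @export
fit_scaling_models <- function(matrix, level = c("domain", "phylum"),
                               threshold = 0.05, min_segment = NULL,
                               zero_policy = "drop", min_n = 3L) {
  level <- match.arg(level)
  labels <- matrix$taxon[[level]]
  groups <- sort(unique(labels[!is.na(labels)]))
  cats <- colnames(matrix$counts)
  out <- list(); srows <- list()
  for (g in groups) {
    sel <- !is.na(labels) & labels == g
    for (cc in cats) {
      model <- tryCatch({
        inp <- make_fit_input(matrix, cc, selector = sel,
                              zero_policy = zero_policy, min_n = min_n,
                              group = g)
        select_model(inp, threshold = threshold, min_segment = min_segment)
      }, error = function(e) NULL)
      if (is.null(model)) next
      out[[length(out) + 1L]] <- list(group = g, category = cc, model = model)
      sg <- model$segmented
      srows[[length(srows) + 1L]] <- data.frame(
        group = g, category = cc, kind = model$kind,
        rss_single = model$single$rss,
        rss_segmented = if (!is.null(sg)) sg$rss else NA_real_,
        rss_ratio = model$rss_ratio,
        break_x_log10 = if (!is.null(sg)) sg$break_x else NA_real_,
        break_percentile = if (!is.null(sg)) sg$break_percentile else NA_real_,
        slope1 = if (!is.null(sg)) sg$slope1 else NA_real_,
        slope1_ci95 = if (!is.null(sg)) sg$slope1_ci95 else NA_real_,
        slope2 = if (!is.null(sg)) sg$slope2 else NA_real_,
        slope2_ci95 = if (!is.null(sg)) sg$slope2_ci95 else NA_real_,
        slope = model$single$slope, slope_ci95 = model$single$slope_ci95,
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "summary") <- if (length(srows)) do.call(rbind, srows) else NULL
  out
}
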