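#' Shuffle COG category labels across annotations
#'
#' The permutation null: the multiset of split category letters over all
#' records is permuted uniformly at random and re-dealt to the same
#' (organism, protein) slots with each record keeping its original number of
#' letters. Consequently every organism's total annotation count and the
#' global count of every category letter are conserved exactly, while
#' per-organism per-category abundances change — destroying any
#' category-specific scaling. `level = "record"` instead permutes whole
#' category strings between records (conserving global letter totals but not
#' per-organism totals when records differ in letter count).
#'
#' @param records A `cog_annotations` data frame.
#' @param seed Integer seed; a fixed seed reproduces the shuffle exactly.
#' @param level `"letter"` (default) or `"record"`.
#' @return A `cog_annotations` data frame of the same shape with shuffled
#'   category assignments.
#' @export
shuffle_categories <- function(records, seed, level = c("letter", "record")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  set.seed(seed)
  out <- records
  if (level == "record") {
    out$categories <- sample(records$categories)
  } else {
    per_rec <- strsplit(records$categories, "", fixed = TRUE)
    nlet <- lengths(per_rec)
    pool <- unlist(per_rec, use.names = FALSE)
    pool <- sample(pool)
    ends <- cumsum(nlet)
    starts <- ends - nlet + 1L
    out$categories <- vapply(seq_along(nlet), function(i)
      paste(pool[starts[i]:ends[i]], collapse = ""), character(1))
  }
  class(out) <- class(records)
  attr(out, "n_skipped") <- attr(records, "n_skipped")
  out
}

#' Null distribution of a category's scaling exponent under label shuffling
#'
#' Repeatedly shuffles the category labels ([shuffle_categories()]), rebuilds
#' the count matrix, and refits the given category's power-law slope; the
#' observed slope is fit on the unshuffled records. Per-permutation seeds are
#' derived deterministically from the master seed. Permutations in which the
#' category cannot be fit are recorded as NA, not dropped.
#'
#' @param records A `cog_annotations` data frame.
#' @param category Single category letter.
#' @param taxon_map Organism-to-taxon data frame (see
#'   [build_count_matrix()]).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Master seed.
#' @param zero_policy,min_n Fit options, see [make_fit_input()].
#' @param level Shuffle level, see [shuffle_categories()].
#' @return An object of class `null_result`: list with `category`,
#'   `observed_slope`, `null_slopes` (length `n_perm`, may contain NA),
#'   `n_perm`, `seed`.
#' @export
null_distribution <- function(records, category, taxon_map, n_perm, seed,
                              zero_policy = "drop", min_n = 3L,
                              level = "letter") {
  stopifnot(n_perm >= 1L)
  fit_slope <- function(recs) {
    tryCatch({
      m <- build_count_matrix(recs, taxon_map, permissive = TRUE)
      inp <- make_fit_input(m, category, zero_policy = zero_policy,
                            min_n = min_n)
      ols_fit(inp)$slope
    }, error = function(e) NA_real_)
  }
  observed <- fit_slope(records)
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  null_slopes <- vapply(perm_seeds, function(s)
    fit_slope(shuffle_categories(records, seed = s, level = level)),
    numeric(1))
  structure(list(category = category, observed_slope = observed,
                 null_slopes = null_slopes, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "null_result")
}

#' Summarize shuffle-null results across categories
#'
#' @param results A list of `null_result` objects (one per category).
#' @return Data frame with `category`, `observed_slope`, `null_mean`,
#'   `null_sd`, `n_perm`, `n_na` (unfittable permutations), and
#'   `quantile_two_sided`: the empirical two-sided tail position of the
#'   observed slope in the null distribution,
#'   `min(P(null <= obs), P(null >= obs))` over defined null slopes.
#' @export
null_summary <- function(results) {
  if (inherits(results, "null_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    ns <- r$null_slopes
    ok <- ns[!is.na(ns)]
    q <- if (length(ok)) min(mean(ok <= r$observed_slope),
                             mean(ok >= r$observed_slope)) else NA_real_
    data.frame(category = r$category, observed_slope = r$observed_slope,
               null_mean = if (length(ok)) mean(ok) else NA_real_,
               null_sd = if (length(ok) > 1L) stats::sd(ok) else NA_real_,
               n_perm = r$n_perm, n_na = sum(is.na(ns)),
               quantile_two_sided = q, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
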