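# A two-phylum matrix where J scales differently per phylum. The dominant
# category S (exponent 1) makes the realized total track the generative total,
# and J's normalization keeps it a minor component of the total everywhere.
two_phylum_matrix <- function(seed = 1, n = 400, j_offset_B = 0.3) {
  spec <- simulation_spec(
    n, c(1000, 1e5),
    list(S = scaling_law(1, -0.05, 0.1),
         J = scaling_law(0.7, -1.5, 0.1)),
    phyla = list(A = list(name = "A", fraction = 0.5, offsets = numeric()),
                 B = list(name = "B", fraction = 0.5,
                          offsets = c(J = j_offset_B))),
    domain = "Bacteria", seed = seed)
  simulate_matrix(spec)
}

test_that("group fits recover per-phylum exponents and mark unfittable cells NA", {
  sim <- two_phylum_matrix()
  fits <- fit_groups(sim$matrix, "phylum")
  expect_setequal(unique(fits$group), c("A", "B"))
  jA <- fits[fits$group == "A" & fits$category == "J", ]
  jB <- fits[fits$group == "B" & fits$category == "J", ]
  # realized totals (row sums) are a noisy proxy for the generative totals,
  # so allow a small attenuation on top of the CI
  expect_lt(abs(jA$slope - 0.7), 0.1)
  expect_lt(abs(jB$slope - 1.0), 0.1)
  expect_equal(fits$note[!is.na(fits$slope)], rep("", sum(!is.na(fits$slope))))

  # domain level on a single-domain matrix equals whole-matrix fits
  dfits <- fit_groups(sim$matrix, "domain")
  whole <- ols_fit(make_fit_input(sim$matrix, "J"))
  expect_equal(dfits$slope[dfits$category == "J"], whole$slope)
})

test_that("tiny groups yield NA rows with an insufficient-data reason", {
  sim <- two_phylum_matrix(seed = 3, n = 40)
  m <- sim$matrix
  # shrink phylum B to 2 organisms
  bidx <- which(m$taxon$phylum == "B")
  drop <- bidx[-(1:2)]
  keep <- setdiff(seq_len(nrow(m$counts)), drop)
  m$counts <- m$counts[keep, , drop = FALSE]
  m$total <- m$total[keep]
  m$taxon <- m$taxon[keep, ]
  m$total_target <- m$total_target[keep]
  fits <- fit_groups(m, "phylum")
  bj <- fits[fits$group == "B" & fits$category == "J", ]
  expect_true(is.na(bj$slope))
  expect_match(bj$note, "insufficient")
})

test_that("z statistic matches hand evaluation, its guards, and antisymmetry", {
  g <- list(slope = 1.5, slope_ci95 = 0.1)
  d <- list(slope = 1.2, slope_ci95 = 0.05)
  expect_equal(z_statistic(g, d, "as_printed"), 0.3 / sqrt(0.0075),
               tolerance = 1e-12)
  expect_equal(z_statistic(g, d, "sum_of_squares"), 0.3 / sqrt(0.0125),
               tolerance = 1e-12)

  # equal slopes -> exactly zero in both modes
  e <- list(slope = 1.2, slope_ci95 = 0.2)
  expect_identical(z_statistic(e, d, "as_printed"), 0)
  expect_identical(z_statistic(e, d, "sum_of_squares"), 0)

  # negative radicand guard in the printed form
  gsmall <- list(slope = 1.5, slope_ci95 = 0.02)
  zna <- z_statistic(gsmall, d, "as_printed")
  expect_true(is.na(zna))
  expect_match(attr(zna, "reason"), "does not exceed")
  # sum mode remains defined
  expect_false(is.na(z_statistic(gsmall, d, "sum_of_squares")))

  # both errors zero -> degenerate
  expect_true(is.na(z_statistic(list(slope = 2, slope_ci95 = 0),
                                list(slope = 1, slope_ci95 = 0))))

  # antisymmetry in the slope difference
  zp <- z_statistic(g, d, "sum_of_squares")
  zm <- z_statistic(list(slope = 0.9, slope_ci95 = 0.1), d, "sum_of_squares")
  expect_equal(zm, -zp, tolerance = 1e-12)
})

test_that("z table ranks categories by z-range and keeps NA rows visible", {
  sim <- two_phylum_matrix(seed = 7)
  pf <- fit_groups(sim$matrix, "phylum")
  df <- fit_groups(sim$matrix, "domain")
  zt <- z_table(pf, df, mode = "sum_of_squares")
  # no category gained or lost
  expect_setequal(unique(zt$category), unique(pf$category))
  zr <- attr(zt, "z_range")
  # J carries a large phylum offset, S none: J must have the wider z range
  expect_gt(zr[["J"]], zr[["S"]])
  # ordering of rows follows the range ordering
  expect_equal(unique(zt$category),
               names(sort(zr, decreasing = TRUE, na.last = TRUE)))
  # the two phyla deviate from the pooled domain slope in opposite directions
  zj <- zt[zt$category == "J" & !is.na(zt$z), ]
  expect_lt(zj$z[zj$group == "A"], 0)
  expect_gt(zj$z[zj$group == "B"], 0)
})

test_that("breakpoint spans flag phyla straddling the domain break", {
  # domain data with a real breakpoint in J; phylum ranges controlled directly
  spec <- simulation_spec(
    600, c(100, 1e5),
    list(S = scaling_law(1, -0.02, 0.05),
         J = breakpoint_law(scaling_law(1.5, -1.5, 0.1), 0.6, 10^3.5)),
    domain = "Bacteria", seed = 19)
  sim <- simulate_matrix(spec)
  m <- sim$matrix
  # assign phyla by position relative to the break: Low below, Wide across
  lt <- log10(m$total)
  m$taxon$phylum <- ifelse(lt < 3.4, "Low", "Wide")
  midx <- sample(which(lt >= 3.4))  # Wide also gets some low-end organisms
  m$taxon$phylum[midx[seq_len(30)]] <- "Wide"
  low_extra <- which(lt < 3.0)
  models <- fit_scaling_models(m, "domain")
  kinds <- vapply(models, function(e) e$model$kind, character(1))
  cats <- vapply(models, function(e) e$category, character(1))
  expect_equal(kinds[cats == "J"], "segmented")
  spans <- breakpoint_spans(m, models)
  sj <- spans[spans$category == "J", ]
  expect_false(sj$spans_break[sj$phylum == "Low"])
  expect_true(sj$spans_break[sj$phylum == "Wide"])
  # most-spanning phylum listed first
  expect_equal(spans$phylum[1], "Wide")
  # no segmented models -> empty table with a message
  single_only <- Filter(function(e) e$model$kind == "single", models)
  expect_message(empty <- breakpoint_spans(m, single_only), "empty")
  expect_equal(nrow(empty), 0L)
})
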