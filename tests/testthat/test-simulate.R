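test_that("law evaluation follows the power law and the continuous breakpoint form", {
  l <- scaling_law(0.5, log10_norm = 0)
  expect_equal(law_mean_log10(l, 10000), 2)  # 10000^0.5 = 100
  bl <- breakpoint_law(scaling_law(1.5, log10_norm = 1), slope_large = 0.9,
                       break_x = 10^3.5)
  # continuity at the break
  eps <- 1e-9
  expect_equal(law_mean_log10(bl, 10^(3.5 - eps)),
               law_mean_log10(bl, 10^(3.5 + eps)), tolerance = 1e-6)
  # slopes on either side
  expect_equal(law_mean_log10(bl, 10^3) - law_mean_log10(bl, 10^2), 1.5)
  expect_equal(law_mean_log10(bl, 10^5) - law_mean_log10(bl, 10^4), 0.9)
})

test_that("simulated matrices satisfy the row-sum invariant and are seed-reproducible", {
  spec <- simulation_spec(100, c(100, 1e5),
                          list(J = scaling_law(0.3, 1, 0.1),
                               Q = scaling_law(1.7, -3, 0.1)),
                          seed = 5)
  s1 <- simulate_matrix(spec)
  s2 <- simulate_matrix(spec)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(unname(s1$matrix$total),
                   as.integer(unname(rowSums(s1$matrix$counts))))
  expect_true(all(s1$matrix$counts >= 0L))
  expect_true(is.integer(s1$matrix$counts))
  # generative targets are recorded alongside realized totals
  expect_length(s1$matrix$total_target, nrow(s1$matrix$counts))
})

test_that("identity law reproduces the target total exactly when noise-free", {
  spec <- simulation_spec(50, c(100, 1e4), list(K = scaling_law(1, 0, 0)),
                          seed = 3)
  sim <- simulate_matrix(spec)
  expect_equal(unname(sim$matrix$counts[, "K"]),
               as.integer(round(sim$matrix$total_target)))
})

test_that("OLS recovers generating exponents from simulated data", {
  spec <- simulation_spec(500, c(100, 1e5),
                          list(J = scaling_law(1.5, -1, 0.1)), seed = 42)
  sim <- simulate_matrix(spec)
  f <- ols_fit(make_fit_input(sim$matrix, "J", x_source = "target"))
  expect_lt(abs(f$slope - 1.5), 0.05)
})

test_that("phylum fractions and exponent offsets propagate into the truth", {
  spec <- simulation_spec(
    400, c(100, 1e5), list(J = scaling_law(1, 0, 0.1)),
    phyla = list(A = list(name = "A", fraction = 0.5, offsets = c(J = 0.4)),
                 B = list(name = "B", fraction = 0.5, offsets = numeric())),
    seed = 8)
  sim <- simulate_matrix(spec)
  expect_equal(sim$truth$A$J$exponent, 1.4)
  expect_equal(sim$truth$B$J$exponent, 1)
  expect_setequal(unique(sim$matrix$taxon$phylum), c("A", "B"))
  # each phylum's fit recovers its own exponent
  for (ph in c("A", "B")) {
    sel <- sim$matrix$taxon$phylum == ph
    f <- ols_fit(make_fit_input(sim$matrix, "J", selector = sel,
                                x_source = "target", group = ph))
    expect_lt(abs(f$slope - sim$truth[[ph]]$J$exponent), 3 * f$slope_ci95)
  }
  expect_error(simulation_spec(10, c(10, 100), list(J = scaling_law(1)),
                               phyla = list(A = list(name = "A",
                                                     fraction = 0.7))),
               "sum to 1")
})

test_that("simulated trees couple offsets to patristic distance only when asked", {
  expect_error(simulate_tree(c("A", "B"), 1), "at least 3")

  st <- simulate_tree(paste0("P", 1:20), coupling = 1, seed = 11)
  expect_s3_class(st$tree, "phylo")
  d <- cophenetic(st$tree)
  labs <- names(st$offsets)
  pairs <- t(combn(labs, 2))
  dd <- d[cbind(pairs[, 1], pairs[, 2])]
  dv <- abs(st$offsets[pairs[, 1]] - st$offsets[pairs[, 2]])
  expect_gt(cor(dd, dv, method = "spearman"), 0.5)

  # decoupled: correlation near zero on average across seeds
  cors <- vapply(1:30, function(s) {
    st0 <- simulate_tree(paste0("P", 1:20), coupling = 0, seed = s)
    d0 <- cophenetic(st0$tree)
    dv0 <- abs(st0$offsets[pairs[, 1]] - st0$offsets[pairs[, 2]])
    cor(d0[cbind(pairs[, 1], pairs[, 2])], dv0)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})
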