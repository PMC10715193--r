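test_that("phylum patristic matrix averages tip-pair path lengths", {
  # two phyla, one tip each: the matrix entry is the tip-to-tip path length
  tr <- ape::read.tree(text = "(a:1.5,b:2.5);")
  mp <- data.frame(organism = c("a", "b"), phylum = c("P1", "P2"),
                   stringsAsFactors = FALSE)
  d <- patristic_phylum_matrix(tr, mp)
  expect_equal(d["P1", "P2"], 4)
  expect_equal(diag(d), c(P1 = 0, P2 = 0))

  # star tree with unit branches: every between-phylum distance is 2
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  mp4 <- data.frame(organism = letters[1:4], phylum = paste0("P", 1:4))
  d4 <- patristic_phylum_matrix(star, mp4)
  expect_true(all(d4[upper.tri(d4)] == 2))

  # averaging over multiple tips per phylum
  tr2 <- ape::read.tree(text = "((a:1,b:2):1,(c:1,d:3):2);")
  mp2 <- data.frame(organism = letters[1:4],
                    phylum = c("X", "X", "Y", "Y"))
  d2 <- patristic_phylum_matrix(tr2, mp2)
  manual <- mean(c(patristic_oracle(tr2, "a", "c"),
                   patristic_oracle(tr2, "a", "d"),
                   patristic_oracle(tr2, "b", "c"),
                   patristic_oracle(tr2, "b", "d")))
  expect_equal(d2["X", "Y"], manual, tolerance = 1e-12)
})

test_that("patristic matrix matches the brute-force path-walking oracle on random trees", {
  set.seed(77)
  for (rep in 1:3) {
    tr <- ape::rtree(12)
    mp <- data.frame(organism = tr$tip.label,
                     phylum = paste0("P", rep(1:4, each = 3)))
    d <- patristic_phylum_matrix(tr, mp)
    for (pair in list(c("P1", "P2"), c("P2", "P4"), c("P3", "P1"))) {
      tips_a <- mp$organism[mp$phylum == pair[1]]
      tips_b <- mp$organism[mp$phylum == pair[2]]
      manual <- mean(outer(tips_a, tips_b,
                           Vectorize(function(u, v) patristic_oracle(tr, u, v))))
      expect_equal(d[pair[1], pair[2]], manual, tolerance = 1e-9)
    }
    expect_equal(d, t(d))
    expect_true(all(d[upper.tri(d)] > 0))
  }
})

test_that("unmapped tips are ignored and degenerate inputs rejected", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  mp <- data.frame(organism = c("a", "c"), phylum = c("P1", "P2"))
  expect_message(d <- patristic_phylum_matrix(tr, mp), "ignored")
  expect_equal(dim(d), c(2L, 2L))

  tr_nb <- ape::read.tree(text = "((a,b),(c,d));")
  expect_error(patristic_phylum_matrix(tr_nb, mp), "branch lengths")
  mp1 <- data.frame(organism = letters[1:4], phylum = "only")
  expect_error(patristic_phylum_matrix(tr, mp1), "fewer than 2")
})

test_that("exponent divergence computes differences and sign-guarded quotients", {
  sl <- c(P1 = 1.5, P2 = 1.2)
  ad <- exponent_divergence(sl, "abs_diff")
  expect_equal(ad["P1", "P2"], 0.3)
  expect_equal(diag(ad), c(P1 = 0, P2 = 0))
  qt <- exponent_divergence(sl, "quotient")
  expect_equal(qt["P1", "P2"], 1.25)
  expect_equal(diag(qt), c(P1 = 1, P2 = 1))

  mixed <- exponent_divergence(c(A = 0.5, B = -0.1, C = 0.25), "quotient")
  expect_true(is.na(mixed["A", "B"]))
  expect_equal(mixed["A", "C"], 2)

  same <- exponent_divergence(c(A = 0.9, B = 0.9), "quotient")
  expect_equal(same["A", "B"], 1)
  expect_error(exponent_divergence(c(A = 1), "abs_diff"), "insufficient")
})

test_that("association statistic is invariant to phylum relabeling and guards small inputs", {
  st <- simulate_tree(paste0("P", 1:12), coupling = 1, seed = 5)
  mp <- data.frame(organism = names(st$offsets), phylum = names(st$offsets))
  dm <- patristic_phylum_matrix(st$tree, mp)
  vm <- exponent_divergence(1 + st$offsets, "abs_diff")
  a1 <- distance_divergence_association(dm, vm, "spearman")
  expect_gt(a1$statistic, 0.5)
  expect_equal(a1$n_pairs, choose(12, 2))

  perm <- sample(rownames(dm))
  a2 <- distance_divergence_association(dm[perm, perm], vm, "spearman")
  expect_equal(a2$statistic, a1$statistic, tolerance = 1e-12)

  expect_error(distance_divergence_association(dm[1:2, 1:2], vm),
               "insufficient")
  # mantel permutation p-value is available and small for coupled data
  am <- distance_divergence_association(dm, vm, "pearson",
                                        mantel_perm = 99, seed = 2)
  expect_lt(am$mantel_p, 0.1)
})
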