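# Shared fixtures and independent oracles used across the suite.

# Write a small annotation TSV and return its path.
write_annotation_fixture <- function(rows, dir = tempdir()) {
  path <- tempfile("annot", tmpdir = dir, fileext = ".tsv")
  writeLines(c("# organism\tprotein\tcategories", rows), path)
  path
}

simple_taxon_map <- function(organisms, domain = "Bacteria",
                             phylum = "Proteobacteria") {
  data.frame(organism = organisms,
             domain = rep_len(domain, length(organisms)),
             phylum = rep_len(phylum, length(organisms)),
             stringsAsFactors = FALSE)
}

# Closed-form normal-equation OLS: the independent oracle for ols_fit.
ols_oracle <- function(x, y) {
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  s2 <- rss / (n - 2)
  list(slope = slope, intercept = intercept, rss = rss,
       slope_se = sqrt(s2 / sxx),
       intercept_se = sqrt(s2 * (1 / n + xbar^2 / sxx)))
}

# Brute-force patristic distance between two tips: walk the node path and
# sum edge lengths. Independent of stats::cophenetic.
patristic_oracle <- function(tree, tip_a, tip_b) {
  ia <- match(tip_a, tree$tip.label)
  ib <- match(tip_b, tree$tip.label)
  path <- ape::nodepath(tree, ia, ib)
  d <- 0
  for (k in seq_len(length(path) - 1L)) {
    e <- which((tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1]) |
               (tree$edge[, 2] == path[k] & tree$edge[, 1] == path[k + 1]))
    d <- d + tree$edge.length[e]
  }
  d
}

# Fit input straight from vectors (bypasses matrix bookkeeping).
raw_input <- function(x, y) {
  list(x = x, y = y, n_dropped_zero = 0L,
       label = c(category = "?", group = "test"))
}

# Two-regime log-log data with a continuous break, Gaussian log-scale noise.
two_regime_data <- function(n, s1, s2, break_log10, noise_sd, seed,
                            xlim = c(2, 5), intercept = 1) {
  set.seed(seed)
  x <- stats::runif(n, xlim[1], xlim[2])
  y <- ifelse(x <= break_log10,
              intercept + s1 * x,
              intercept + s1 * break_log10 + s2 * (x - break_log10))
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
  raw_input(x, y)
}
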