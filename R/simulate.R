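#' Scaling-law and breakpoint-law constructors
#'
#' A `scaling_law` describes a single power law y = c * x^beta for one
#' category: `exponent` is beta (the slope in log-log space), `log10_norm` is
#' log10(c) (the normalization constant), and `noise_sd` the standard
#' deviation of Gaussian noise added to log10(y) (i.e. log-normal scatter on
#' counts). A `breakpoint_law` joins two power laws continuously at
#' `break_x` on the total-annotations axis: below the break the law is
#' `law_small`; above it the slope changes to `slope_large` with the
#' intercept derived from continuity.
#'
#' @param exponent Scaling exponent beta.
#' @param log10_norm log10 of the normalization constant c.
#' @param noise_sd Standard deviation of the log10-scale noise (>= 0).
#' @return An object of class `scaling_law` or `breakpoint_law`.
#' @export
scaling_law <- function(exponent, log10_norm = 0, noise_sd = 0) {
  stopifnot(is.finite(exponent), is.finite(log10_norm), noise_sd >= 0)
  structure(list(exponent = exponent, log10_norm = log10_norm,
                 noise_sd = noise_sd),
            class = "scaling_law")
}

#' @rdname scaling_law
#' @param law_small `scaling_law` governing the regime below `break_x`.
#' @param slope_large Exponent above the breakpoint.
#' @param break_x Breakpoint position on the raw total-annotations axis (> 0).
#' @export
breakpoint_law <- function(law_small, slope_large, break_x) {
  stopifnot(inherits(law_small, "scaling_law"), is.finite(slope_large),
            break_x > 0)
  structure(list(law_small = law_small, slope_large = slope_large,
                 break_x = break_x),
            class = "breakpoint_law")
}

#' Mean log10 count of a scaling or breakpoint law at given totals
#'
#' Evaluates the noise-free log10 expected category count of a
#' [scaling_law()] or [breakpoint_law()] at the given total-annotation
#' values (the deterministic backbone the generator adds noise to).
#'
#' @param law A `scaling_law` or `breakpoint_law`.
#' @param total Numeric vector of totals (> 0).
#' @return Numeric vector of log10 expected counts.
#' @export
law_mean_log10 <- function(law, total) {
  lx <- log10(total)
  if (inherits(law, "scaling_law")) {
    law$log10_norm + law$exponent * lx
  } else if (inherits(law, "breakpoint_law")) {
    lb <- log10(law$break_x)
    below <- law$law_small$log10_norm + law$law_small$exponent * lx
    at_break <- law$law_small$log10_norm + law$law_small$exponent * lb
    above <- at_break + law$slope_large * (lx - lb)
    ifelse(lx <= lb, below, above)
  } else {
    stop("unknown law class")
  }
}

law_noise_sd <- function(law) {
  if (inherits(law, "scaling_law")) law$noise_sd else law$law_small$noise_sd
}

#' Shift a law's exponent(s) by a phylum offset, preserving continuity
#' @noRd
law_offset <- function(law, offset) {
  if (offset == 0) return(law)
  if (inherits(law, "scaling_law")) {
    scaling_law(law$exponent + offset, law$log10_norm, law$noise_sd)
  } else {
    breakpoint_law(law_offset(law$law_small, offset),
                   law$slope_large + offset, law$break_x)
  }
}

#' Specification for a synthetic organism x category count matrix
#'
#' Defines the study conditions for the generator: how many organisms, the
#' (log-uniformly sampled) range of total annotations, the per-category
#' scaling or breakpoint laws, and optional phylum structure given as a list
#' of `list(name =, fraction =, offsets =)` entries where `offsets` is a
#' named numeric vector of per-category exponent offsets (missing categories
#' default to 0).
#'
#' @param n_organisms Number of organisms.
#' @param total_range Length-2 numeric `(min, max)` of total annotations;
#'   totals are drawn log-uniformly in this range. `min >= 1`.
#' @param laws Named list mapping single category letters to `scaling_law` /
#'   `breakpoint_law` objects.
#' @param phyla Optional list of phylum entries (see Description); fractions
#'   must sum to 1.
#' @param domain Domain label given to every simulated organism.
#' @param seed Integer seed; the generated matrix is bit-reproducible.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_organisms, total_range, laws, phyla = NULL,
                            domain = "SimDomain", seed = 1L) {
  stopifnot(n_organisms >= 1, length(total_range) == 2L,
            total_range[1L] >= 1, total_range[2L] >= total_range[1L],
            length(laws) >= 1L, !is.null(names(laws)),
            all(grepl("^[A-Z]$", names(laws))))
  ok <- vapply(laws, function(l)
    inherits(l, "scaling_law") || inherits(l, "breakpoint_law"), logical(1))
  if (!all(ok)) stop("every law must be a scaling_law or breakpoint_law")
  if (!is.null(phyla)) {
    fr <- vapply(phyla, function(p) p$fraction, numeric(1))
    if (abs(sum(fr) - 1) > 1e-8) stop("phylum fractions must sum to 1")
    if (is.null(names(phyla))) {
      names(phyla) <- vapply(phyla, function(p) p$name, character(1))
    }
  }
  structure(list(n_organisms = as.integer(n_organisms),
                 total_range = as.numeric(total_range),
                 laws = laws, phyla = phyla, domain = domain,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate an organism x category count matrix with known scaling truth
#'
#' For each organism a generative total T is drawn log-uniformly over
#' `total_range`; for each category the mean log10 count at x = T follows the
#' category's (phylum-adjusted) law; Gaussian noise of the law's `noise_sd`
#' is added on the log10 scale; counts are the exponentiated values rounded
#' to the nearest non-negative integer (rounded-to-zero entries stay 0). The
#' matrix `total` is then the realized row sum, so the count-matrix invariant
#' holds exactly; the drawn T is recorded separately as `total_target`.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `matrix` (a `cog_matrix` carrying an extra
#'   `total_target` element) and `truth` (per-phylum named list of
#'   per-category laws after phylum offsets).
#' @export
simulate_matrix <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_organisms
  orgs <- sprintf("org%04d", seq_len(n))
  lt <- stats::runif(n, log10(spec$total_range[1L]), log10(spec$total_range[2L]))
  target <- 10^lt
  if (is.null(spec$phyla)) {
    phylum <- rep("P1", n)
    phyla_names <- "P1"
    offsets <- list(P1 = numeric())
  } else {
    phyla_names <- names(spec$phyla)
    fr <- vapply(spec$phyla, function(p) p$fraction, numeric(1))
    phylum <- sample(phyla_names, n, replace = TRUE, prob = fr)
    offsets <- lapply(spec$phyla, function(p) {
      o <- p$offsets %||% numeric()
      o
    })
  }
  cats <- names(spec$laws)
  counts <- matrix(0L, n, length(cats), dimnames = list(orgs, cats))
  truth <- lapply(phyla_names, function(ph) {
    lapply(spec$laws, function(l) l)
  })
  names(truth) <- phyla_names
  for (ph in phyla_names) {
    rows <- which(phylum == ph)
    for (ci in seq_along(cats)) {
      cat_letter <- cats[ci]
      off <- 0
      o <- offsets[[ph]]
      if (!is.null(o) && cat_letter %in% names(o)) off <- o[[cat_letter]]
      law <- law_offset(spec$laws[[cat_letter]], off)
      truth[[ph]][[cat_letter]] <- law
      if (length(rows) == 0L) next
      mu <- law_mean_log10(law, target[rows])
      sdv <- law_noise_sd(law)
      ly <- mu + if (sdv > 0) stats::rnorm(length(rows), 0, sdv) else 0
      counts[rows, ci] <- as.integer(pmin(pmax(round(10^ly), 0),
                                          .Machine$integer.max - 1))
    }
  }
  total <- rowSums(counts)
  storage.mode(total) <- "integer"
  keep <- total > 0L
  m <- structure(list(counts = counts[keep, , drop = FALSE],
                      total = total[keep],
                      taxon = data.frame(organism = orgs[keep],
                                         domain = spec$domain,
                                         phylum = phylum[keep],
                                         stringsAsFactors = FALSE),
                      total_target = target[keep]),
                 class = "cog_matrix")
  list(matrix = m, truth = truth)
}

# Place the tips of an ultrametric tree on the number line so that the
# absolute position difference of any two tips is rank-monotone in their
# patristic distance. Merges (taken in height order via the hclust form of
# the tree) position the right cluster after the left one with a gap larger
# than every within-cluster span built so far; therefore all tip pairs
# joined at a lower node sit closer together than any pair joined at a
# higher node. Positions grow geometrically but are standardized by callers.
monotone_embedding <- function(tree) {
  hc <- stats::as.hclust(tree)
  n <- length(hc$labels)
  pos <- numeric(n)
  clusters <- vector("list", nrow(hc$merge))
  members <- function(k) if (k < 0L) -k else clusters[[k]]
  span_max <- 1
  for (k in seq_len(nrow(hc$merge))) {
    a <- members(hc$merge[k, 1L])
    b <- members(hc$merge[k, 2L])
    gap <- span_max + 1
    pos[b] <- pos[b] + (max(pos[a]) + gap - min(pos[b]))
    clusters[[k]] <- c(a, b)
    span_max <- max(span_max, max(pos[clusters[[k]]]) - min(pos[clusters[[k]]]))
  }
  stats::setNames(pos, hc$labels)
}

#' Simulate an ultrametric phylum tree with tunable exponent-offset coupling
#'
#' Generates a random coalescent (ultrametric) tree over the given phyla and
#' a per-phylum scaling-exponent offset whose relation to the tree is set by
#' `coupling`: at `coupling = 1` offsets come from a monotone line embedding
#' of the tree — clusters are placed on the number line in order of merge
#' height with gaps exceeding every existing within-cluster span — so the
#' absolute offset difference between two phyla is rank-monotone in their
#' patristic distance (phyla far apart on the tree get very different
#' offsets); at `coupling = 0` offsets are independent Gaussian draws
#' unrelated to the tree; intermediate values blend the two components (each
#' standardized) with weights `coupling` and `1 - coupling`.
#'
#' @param phyla Character vector of at least 3 phylum names.
#' @param coupling Real in `[0, 1]`.
#' @param seed Integer seed.
#' @param offset_sd Standard deviation of the returned offsets (default 0.25
#'   exponent units).
#' @return A list with `tree` (an `ape::phylo` with tip labels = phyla) and
#'   `offsets` (named numeric vector of exponent offsets).
#' @export
simulate_tree <- function(phyla, coupling, seed = 1L, offset_sd = 0.25) {
  if (length(phyla) < 3L) {
    stop("at least 3 phyla are required to simulate a tree")
  }
  stopifnot(coupling >= 0, coupling <= 1, offset_sd > 0)
  set.seed(seed)
  tree <- ape::rcoal(length(phyla), tip.label = phyla)
  axis1 <- monotone_embedding(tree)[phyla]
  standardize <- function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else v * 0
  }
  tree_part <- standardize(axis1)
  indep_part <- standardize(stats::rnorm(length(phyla)))
  raw <- coupling * tree_part + (1 - coupling) * indep_part
  offsets <- offset_sd * standardize(raw)
  names(offsets) <- phyla
  list(tree = tree, offsets = offsets)
}
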