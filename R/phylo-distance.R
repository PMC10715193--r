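#' Average patristic distances between phyla
#'
#' Computes the patristic (path-length) distance between every pair of tips
#' of a tree and averages, for each pair of phyla, over all tip pairs with
#' one tip in each phylum — giving a phylum-level distance matrix. Tips
#' absent from the mapping are ignored (their number is attached as
#' attribute `n_unmapped`). The diagonal is zero by construction.
#'
#' @param tree An `ape::phylo` tree with branch lengths whose tips are
#'   organisms (or phyla directly, with an identity mapping).
#' @param mapping Data frame with columns `organism` and `phylum`; tip
#'   labels are matched against `organism`.
#' @return A symmetric numeric matrix (phyla x phyla, zero diagonal) of
#'   class `matrix`, with attribute `n_unmapped`.
#' @export
patristic_phylum_matrix <- function(tree, mapping) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; patristic distances are undefined")
  }
  stopifnot(is.data.frame(mapping),
            all(c("organism", "phylum") %in% names(mapping)))
  tips <- tree$tip.label
  ph <- mapping$phylum[match(tips, mapping$organism)]
  n_unmapped <- sum(is.na(ph))
  keep <- !is.na(ph)
  if (n_unmapped > 0L) {
    message(n_unmapped, " tip(s) absent from the organism-phylum mapping; ignored")
  }
  phyla <- sort(unique(ph[keep]))
  if (length(phyla) < 2L) {
    stop("insufficient data: fewer than 2 phyla have mapped tips")
  }
  d_tip <- stats::cophenetic(tree)[tips, tips]
  d <- matrix(0, length(phyla), length(phyla),
              dimnames = list(phyla, phyla))
  for (i in seq_along(phyla)) {
    for (j in seq_len(i - 1L)) {
      ti <- which(keep & ph == phyla[i])
      tj <- which(keep & ph == phyla[j])
      d[i, j] <- d[j, i] <- mean(d_tip[ti, tj])
    }
  }
  attr(d, "n_unmapped") <- n_unmapped
  d
}

#' Pairwise scaling-exponent divergence between phyla
#'
#' For one category's per-phylum exponents, builds the symmetric matrix of
#' either absolute exponent differences (`abs_diff`, diagonal 0) or exponent
#' quotients (`quotient`: max/min >= 1, diagonal 1, defined only for pairs
#' of same-sign exponents, NA otherwise).
#'
#' @param slopes Named numeric vector of per-phylum exponents (NA entries
#'   are dropped).
#' @param mode `"abs_diff"` or `"quotient"`.
#' @return Symmetric matrix with phylum names as dimnames and attribute
#'   `mode`.
#' @export
exponent_divergence <- function(slopes, mode = c("abs_diff", "quotient")) {
  mode <- match.arg(mode)
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) < 2L) {
    stop("insufficient data: need exponents for at least 2 phyla")
  }
  if (is.null(names(slopes))) stop("`slopes` must be named by phylum")
  n <- length(slopes)
  v <- matrix(if (mode == "quotient") 1 else 0, n, n,
              dimnames = list(names(slopes), names(slopes)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      a <- slopes[i]; b <- slopes[j]
      val <- if (mode == "abs_diff") abs(a - b)
             else if (sign(a) == sign(b) && a != 0 && b != 0)
               max(abs(a), abs(b)) / min(abs(a), abs(b))
             else NA_real_
      v[i, j] <- v[j, i] <- val
    }
  }
  attr(v, "mode") <- mode
  v
}

#' Correlation between phylogenetic distance and exponent divergence
#'
#' Correlates the upper-triangle entries of a phylum patristic-distance
#' matrix with the matching entries of an exponent-divergence matrix, over
#' phyla present in both (pairs with undefined divergence are excluded).
#' Phylum pairs share phyla and are therefore not independent observations;
#' the plain correlation is reported as-is with that caveat carried in the
#' result, and an optional Mantel permutation test is available.
#'
#' @param dm Patristic distance matrix ([patristic_phylum_matrix()]).
#' @param vm Divergence matrix ([exponent_divergence()]).
#' @param method `"pearson"` or `"spearman"`.
#' @param mantel_perm If > 0, additionally runs a Mantel permutation test
#'   with this many label permutations (requires common labels only).
#' @param seed Seed for the Mantel permutations.
#' @return List with `statistic`, `n_pairs`, `method`, `n_phyla`,
#'   `independent_pairs = FALSE`, and (when requested) `mantel_p`.
#' @export
distance_divergence_association <- function(dm, vm,
                                            method = c("pearson", "spearman"),
                                            mantel_perm = 0L, seed = 1L) {
  method <- match.arg(method)
  common <- intersect(rownames(dm), rownames(vm))
  if (length(common) < 3L) {
    stop("insufficient data: need at least 3 phyla shared by both matrices")
  }
  dmat <- dm[common, common]
  vmat <- vm[common, common]
  ut <- upper.tri(dmat)
  dv <- dmat[ut]; vv <- vmat[ut]
  ok <- !is.na(dv) & !is.na(vv)
  if (sum(ok) < 3L) {
    stop("insufficient data: fewer than 3 defined phylum pairs")
  }
  stat <- stats::cor(dv[ok], vv[ok], method = method)
  out <- list(statistic = stat, n_pairs = sum(ok), method = method,
              n_phyla = length(common), independent_pairs = FALSE)
  if (mantel_perm > 0L) {
    set.seed(seed)
    perm_stats <- replicate(mantel_perm, {
      p <- sample(length(common))
      vp <- vmat[p, p][ut]
      okp <- !is.na(dv) & !is.na(vp)
      if (sum(okp) < 3L) NA_real_
      else stats::cor(dv[okp], vp[okp], method = method)
    })
    out$mantel_p <- mean(abs(perm_stats) >= abs(stat), na.rm = TRUE)
  }
  out
}
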