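#' Parse a per-protein functional-annotation table
#'
#' Reads a tab-separated table of per-protein COG annotations in the style of
#' eggNOG-mapper output: one row per protein, carrying the organism identifier,
#' the protein identifier, and a string of one or more single-letter COG
#' category codes (e.g. `"KT"` for a protein annotated with both transcription
#' and signal transduction). Lines starting with `#` are treated as comments.
#' Rows whose category field is empty or `"-"` (unannotated proteins) are
#' skipped and counted.
#'
#' @param path Path to a tab-separated annotation table.
#' @param columns Named integer vector mapping the logical columns
#'   `organism`, `protein` and `categories` to column indices of the file, so
#'   that both pre-digested 3-column tables and wider eggNOG-mapper exports can
#'   be read. Default `c(organism = 1, protein = 2, categories = 3)`.
#' @param sep Field separator, default tab.
#'
#' @return A data frame of class `cog_annotations` with character columns
#'   `organism`, `protein`, `categories`, and an attribute `n_skipped` giving
#'   the number of unannotated rows that were dropped.
#' @seealso [split_categories()], [build_count_matrix()]
#' @export
parse_annotation_table <- function(path,
                                   columns = c(organism = 1L, protein = 2L,
                                               categories = 3L),
                                   sep = "\t") {
  if (!file.exists(path)) {
    stop("annotation table not found: ", path)
  }
  needed <- c("organism", "protein", "categories")
  if (!all(needed %in% names(columns))) {
    stop("`columns` must name organism, protein and categories indices")
  }
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      comment.char = "#", quote = "",
                      colClasses = "character", fill = FALSE,
                      blank.lines.skip = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame()
      } else {
        stop(e)
      }
    })
  if (nrow(raw) == 0L) {
    out <- data.frame(organism = character(), protein = character(),
                      categories = character(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    class(out) <- c("cog_annotations", class(out))
    return(out)
  }
  maxcol <- max(columns[needed])
  if (ncol(raw) < maxcol) {
    stop("annotation table has ", ncol(raw), " columns but column map ",
         "requires at least ", maxcol, " (first data line: ",
         paste(raw[1, ], collapse = " | "), ")")
  }
  out <- data.frame(organism   = raw[[columns[["organism"]]]],
                    protein    = raw[[columns[["protein"]]]],
                    categories = raw[[columns[["categories"]]]],
                    stringsAsFactors = FALSE)
  empty <- out$categories == "" | out$categories == "-"
  n_skipped <- sum(empty)
  out <- out[!empty, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- as.integer(n_skipped)
  class(out) <- c("cog_annotations", class(out))
  out
}

#' Split a multi-category annotation into single category letters
#'
#' A protein annotated with several COG categories (e.g. `"KT"`) is counted
#' once in each category, so the annotation string is split into its
#' individual letters. Duplicate letters are kept: each occurrence counts.
#'
#' @param categories A character vector of category strings (each one or more
#'   uppercase letters `A`-`Z`).
#' @return For a single string, a character vector of single letters in input
#'   order; for a vector of strings, a list of such vectors.
#' @examples
#' split_categories("KT")   # "K" "T"
#' split_categories("CCE")  # "C" "C" "E"
#' @export
split_categories <- function(categories) {
  if (length(categories) == 0L) return(character())
  bad <- !grepl("^[A-Z]+$", categories)
  if (any(bad)) {
    stop("invalid category string(s): ",
         paste(utils::head(categories[bad], 5L), collapse = ", "))
  }
  parts <- strsplit(categories, "", fixed = TRUE)
  if (length(categories) == 1L) parts[[1]] else parts
}

#' Build an organism-by-category count matrix
#'
#' Splits every annotation record into single category letters and tallies
#' them per organism, giving the count of annotations in each COG category and
#' the per-organism total (the sum over categories, the x-axis of every
#' scaling fit). Organisms with no annotations contribute no row.
#'
#' @param records A `cog_annotations` data frame (see
#'   [parse_annotation_table()]) or any data frame with columns `organism` and
#'   `categories`.
#' @param taxon_map A data frame with columns `organism`, `domain` and
#'   (optionally) `phylum` mapping organisms to taxa.
#' @param include Optional character vector of category letters to restrict
#'   counting to (a whitelist); totals are row sums after restriction.
#' @param permissive If `TRUE`, organisms absent from `taxon_map` are kept
#'   with `NA` taxon labels instead of raising an error.
#'
#' @return An object of class `cog_matrix`: a list with elements
#'   \describe{
#'     \item{counts}{integer matrix, organisms x category letters}
#'     \item{total}{named integer vector of per-organism totals (row sums)}
#'     \item{taxon}{data frame with `organism`, `domain`, `phylum`}
#'   }
#' @export
build_count_matrix <- function(records, taxon_map, include = NULL,
                               permissive = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("organism", "categories") %in% names(records)))
  if (!is.data.frame(taxon_map) ||
      !all(c("organism", "domain") %in% names(taxon_map))) {
    stop("`taxon_map` must be a data frame with organism and domain columns")
  }
  if (anyDuplicated(taxon_map$organism)) {
    stop("duplicate organisms in taxon map: ",
         paste(unique(taxon_map$organism[duplicated(taxon_map$organism)]),
               collapse = ", "))
  }
  if (nrow(records) == 0L) {
    m <- matrix(integer(), 0L, 0L)
    out <- structure(list(counts = m, total = integer(0),
                          taxon = data.frame(organism = character(),
                                             domain = character(),
                                             phylum = character())),
                     class = "cog_matrix")
    return(out)
  }
  missing_orgs <- setdiff(unique(records$organism), taxon_map$organism)
  if (length(missing_orgs) > 0L && !permissive) {
    stop("organisms missing from taxon map: ",
         paste(utils::head(missing_orgs, 10L), collapse = ", "))
  }
  letters_per_rec <- strsplit(records$categories, "", fixed = TRUE)
  nlet <- lengths(letters_per_rec)
  org <- rep(records$organism, nlet)
  lett <- unlist(letters_per_rec, use.names = FALSE)
  if (!all(grepl("^[A-Z]$", unique(lett)))) {
    stop("category strings contain non-letter characters")
  }
  if (!is.null(include)) {
    keep <- lett %in% include
    org <- org[keep]
    lett <- lett[keep]
  }
  if (length(org) == 0L) {
    m <- matrix(integer(), 0L, 0L)
    return(structure(list(counts = m, total = integer(0),
                          taxon = data.frame(organism = character(),
                                             domain = character(),
                                             phylum = character())),
                     class = "cog_matrix"))
  }
  orgs <- unique(org)
  cats <- sort(unique(lett))
  counts <- table(factor(org, levels = orgs), factor(lett, levels = cats))
  counts <- matrix(as.integer(counts), nrow = length(orgs),
                   dimnames = list(orgs, cats))
  total <- rowSums(counts)
  storage.mode(total) <- "integer"
  idx <- match(orgs, taxon_map$organism)
  taxon <- data.frame(
    organism = orgs,
    domain = if (length(idx)) as.character(taxon_map$domain[idx]) else character(),
    phylum = if ("phylum" %in% names(taxon_map))
      as.character(taxon_map$phylum[idx]) else NA_character_,
    stringsAsFactors = FALSE)
  structure(list(counts = counts, total = total, taxon = taxon),
            class = "cog_matrix")
}

#' @export
print.cog_matrix <- function(x, ...) {
  cat("Organism x COG category count matrix\n")
  cat("  organisms:  ", nrow(x$counts), "\n", sep = "")
  cat("  categories: ", ncol(x$counts),
      if (ncol(x$counts) > 0)
        paste0(" (", paste(colnames(x$counts), collapse = ""), ")"),
      "\n", sep = "")
  doms <- unique(x$taxon$domain)
  cat("  domains:    ", paste(doms, collapse = ", "), "\n", sep = "")
  if (length(x$total)) {
    cat("  totals:     ", min(x$total), "-", max(x$total),
        " annotations per organism\n", sep = "")
  }
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' The on-disk form is one row per organism with the category letters as
#' columns plus `total`, `domain` and `phylum`.
#'
#' @param x A `cog_matrix`.
#' @param path Output (input) file path.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns a `cog_matrix`.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "cog_matrix"))
  df <- data.frame(organism = rownames(x$counts),
                   x$counts,
                   total = x$total,
                   domain = x$taxon$domain,
                   phylum = x$taxon$phylum,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  catcols <- setdiff(names(df), c("organism", "total", "domain", "phylum"))
  counts <- as.matrix(df[, catcols, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$organism
  total <- df$total
  storage.mode(total) <- "integer"
  names(total) <- df$organism
  structure(list(counts = counts, total = total,
                 taxon = data.frame(organism = df$organism,
                                    domain = df$domain,
                                    phylum = df$phylum,
                                    stringsAsFactors = FALSE)),
            class = "cog_matrix")
}

#' Expand a count matrix back into single-letter annotation records
#'
#' The inverse of [build_count_matrix()] up to protein identity: each unit of
#' `counts[i, c]` becomes one record for organism `i` with the single category
#' letter `c`. Useful for running record-level procedures (such as the shuffle
#' null) on simulated matrices.
#'
#' With `compact = TRUE` the `counts[i, c]` units are emitted as a single
#' record whose category string repeats the letter `c` `counts[i, c]` times.
#' The multiset of split letters per organism — all that the letter-level
#' shuffle null and [build_count_matrix()] consume — is identical to the
#' expanded form, but the record count stays at the number of nonzero cells,
#' which matters for large simulated matrices.
#'
#' @param x A `cog_matrix`.
#' @param compact Emit one multi-letter record per nonzero cell instead of
#'   one single-letter record per count unit (default `FALSE`).
#' @return A `cog_annotations` data frame with synthetic protein ids.
#' @export
matrix_to_records <- function(x, compact = FALSE) {
  stopifnot(inherits(x, "cog_matrix"))
  idx <- which(x$counts > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    out <- data.frame(organism = character(), protein = character(),
                      categories = character(), stringsAsFactors = FALSE)
    class(out) <- c("cog_annotations", class(out))
    return(out)
  }
  reps <- x$counts[idx]
  if (isTRUE(compact)) {
    org <- rownames(x$counts)[idx[, 1L]]
    lett <- strrep(colnames(x$counts)[idx[, 2L]], reps)
    ord <- order(org, lett)
    out <- data.frame(organism = org[ord],
                      protein = paste0(org[ord], "_c", seq_along(ord)),
                      categories = lett[ord],
                      stringsAsFactors = FALSE)
    class(out) <- c("cog_annotations", class(out))
    return(out)
  }
  org <- rep(rownames(x$counts)[idx[, 1L]], reps)
  lett <- rep(colnames(x$counts)[idx[, 2L]], reps)
  ord <- order(org, lett)
  org <- org[ord]; lett <- lett[ord]
  out <- data.frame(organism = org,
                    protein = paste0(org, "_p", stats::ave(seq_along(org), org,
                                                           FUN = seq_along)),
                    categories = lett,
                    stringsAsFactors = FALSE)
  class(out) <- c("cog_annotations", class(out))
  out
}
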