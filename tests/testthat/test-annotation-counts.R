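test_that("annotation tables parse, skip unannotated rows, and honor column maps", {
  path <- write_annotation_fixture(c(
    "org1\tp1\tKT",
    "org1\tp2\t-",
    "org2\tp3\tJ",
    "org2\tp4\t"
  ))
  rec <- parse_annotation_table(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$categories, c("KT", "J"))
  expect_equal(attr(rec, "n_skipped"), 2L)

  # wider eggNOG-mapper-like export with the category string in column 5
  wide <- tempfile(fileext = ".tsv")
  writeLines(c("orgA\tp1\tx\tx\tKT", "orgA\tp2\tx\tx\tC"), wide)
  rec2 <- parse_annotation_table(wide, columns = c(organism = 1, protein = 2,
                                                   categories = 5))
  expect_equal(rec2$categories, c("KT", "C"))

  expect_error(parse_annotation_table(tempfile()), "not found")
  expect_error(parse_annotation_table(wide, columns = c(organism = 1,
                                                        protein = 2,
                                                        categories = 9)),
               "columns")
})

test_that("empty annotation file yields an empty record set with zero skips", {
  path <- tempfile(fileext = ".tsv")
  writeLines("# header only", path)
  rec <- parse_annotation_table(path)
  expect_equal(nrow(rec), 0L)
  expect_equal(attr(rec, "n_skipped"), 0L)
})

test_that("multi-category strings split per character with duplicates kept", {
  expect_equal(split_categories("KT"), c("K", "T"))
  expect_equal(split_categories("J"), "J")
  expect_equal(split_categories("CCE"), c("C", "C", "E"))
  expect_error(split_categories("K1"), "invalid")
  expect_error(split_categories("kt"), "invalid")
})

test_that("count matrix uses the per-letter counting rule and keeps row sums exact", {
  rec <- data.frame(organism = c("org1", "org1"), protein = c("p1", "p2"),
                    categories = c("KT", "K"), stringsAsFactors = FALSE)
  tm <- simple_taxon_map("org1")
  m <- build_count_matrix(rec, tm)
  expect_equal(m$counts["org1", "K"], 2L)
  expect_equal(m$counts["org1", "T"], 1L)
  expect_equal(unname(m$total["org1"]), 3L)

  # whitelist restriction recomputes the total after restriction
  mw <- build_count_matrix(rec, tm, include = "K")
  expect_equal(unname(mw$total["org1"]), 2L)
  expect_equal(colnames(mw$counts), "K")

  # duplicate letters inside one record each count
  rec2 <- data.frame(organism = "o", protein = "p", categories = "CC",
                     stringsAsFactors = FALSE)
  m2 <- build_count_matrix(rec2, simple_taxon_map("o"))
  expect_equal(m2$counts["o", "C"], 2L)
})

test_that("matrix invariants hold on random record sets", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:80, 1)
    orgs <- paste0("g", sample(1:8, n, replace = TRUE))
    cats <- replicate(n, paste(sample(LETTERS[1:6], sample(1:3, 1),
                                      replace = TRUE), collapse = ""))
    rec <- data.frame(organism = orgs, protein = paste0("p", 1:n),
                      categories = cats, stringsAsFactors = FALSE)
    tm <- simple_taxon_map(unique(orgs))
    m <- build_count_matrix(rec, tm)
    # row-sum conservation, exact
    expect_identical(unname(m$total), as.integer(unname(rowSums(m$counts))))
    # splitting conservation: all letters land somewhere
    expect_equal(sum(m$counts), sum(nchar(cats)))
    # permutation of input rows changes nothing (up to row order)
    perm <- sample(n)
    m2 <- build_count_matrix(rec[perm, ], tm)
    expect_equal(m2$counts[rownames(m$counts), colnames(m$counts)], m$counts)
  }
})

test_that("unknown organisms error unless permissive, and absent organisms drop out", {
  rec <- data.frame(organism = c("known", "mystery"), protein = c("p1", "p2"),
                    categories = c("K", "T"), stringsAsFactors = FALSE)
  tm <- simple_taxon_map("known")
  expect_error(build_count_matrix(rec, tm), "mystery")
  m <- build_count_matrix(rec, tm, permissive = TRUE)
  expect_true(is.na(m$taxon$domain[m$taxon$organism == "mystery"]))
  # an organism listed in the map but with no records is simply absent
  tm2 <- simple_taxon_map(c("known", "silent"))
  m2 <- build_count_matrix(rec[1, ], tm2)
  expect_false("silent" %in% rownames(m2$counts))
})

test_that("count matrices round-trip through TSV and expand back to records", {
  rec <- data.frame(organism = c("a", "a", "b"), protein = paste0("p", 1:3),
                    categories = c("KT", "J", "JJ"), stringsAsFactors = FALSE)
  m <- build_count_matrix(rec, simple_taxon_map(c("a", "b")))
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  m2 <- read_count_matrix(path)
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$total, m$total)
  expect_equal(m2$taxon$phylum, m$taxon$phylum)

  back <- matrix_to_records(m)
  m3 <- build_count_matrix(back, simple_taxon_map(c("a", "b")))
  expect_equal(m3$counts[rownames(m$counts), colnames(m$counts)], m$counts)

  # the compact form carries the same letters in fewer records
  comp <- matrix_to_records(m, compact = TRUE)
  expect_equal(nrow(comp), sum(m$counts > 0L))
  m4 <- build_count_matrix(comp, simple_taxon_map(c("a", "b")))
  expect_equal(m4$counts[rownames(m$counts), colnames(m$counts)], m$counts)
})
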