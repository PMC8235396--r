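gct_text <- function(rows, ncol_declared = NULL, nrow_declared = NULL,
                     cells = c("A_LUNG", "B_SKIN")) {
  nr <- if (is.null(nrow_declared)) length(rows) else nrow_declared
  nc <- if (is.null(ncol_declared)) length(cells) else ncol_declared
  c(
    "#1.2", paste(nr, nc, sep = "\t"),
    paste(c("Name", "Description", cells), collapse = "\t"),
    rows
  )
}

write_tmp <- function(lines, ext = ".gct") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("GCT parsing returns the declared matrix, transposed to cells x alterations", {
  path <- write_tmp(gct_text(c(
    "BRAF_MUT\tna\t1\t0",
    "TP53_DEL\tna\t0\t0",
    "MYC_AMP\tna\t1\t1"
  )))
  x <- read_alteration_gct(path)
  expect_identical(dim(x), c(2L, 3L))
  expect_identical(rownames(x), c("A_LUNG", "B_SKIN"))
  expect_identical(colnames(x), c("BRAF_MUT", "TP53_DEL", "MYC_AMP"))
  expect_identical(unname(x["A_LUNG", ]), c(1L, 0L, 1L))
  # parsing never alters values: entry sum equals the file's token sum
  expect_identical(sum(x), 3L)
})

test_that("GCT parser rejects malformed input", {
  expect_error(
    read_alteration_gct(write_tmp(gct_text("BRAF_MUT\tna\t2\t0", nrow_declared = 1))),
    "non-binary"
  )
  expect_error(
    read_alteration_gct(write_tmp(gct_text(
      c("BRAF_MUT\tna\t1\t0", "BRAF_MUT\tna\t0\t0")
    ))),
    "duplicate alteration label"
  )
  expect_error(
    read_alteration_gct(write_tmp(gct_text("BRAF_MUT\tna\t1\t0", nrow_declared = 5))),
    "dimension mismatch"
  )
  expect_error(
    read_alteration_gct(write_tmp(c(
      "not-gct", "1\t2",
      "Name\tDescription\tA\tB", "BRAF_MUT\tna\t1\t0"
    ))),
    "version line"
  )
  expect_error(read_alteration_gct(write_tmp(c("#1.2", "1\t2"))), "truncated")
})

test_that("GCT write/read round-trips exactly", {
  set.seed(11)
  x <- random_alterations(7, 5)
  path <- tempfile(fileext = ".gct")
  write_alteration_gct(x, path)
  expect_identical(read_alteration_gct(path), x)
})

test_that("response tables map blanks to missing and reject bad values", {
  path <- write_tmp(c(
    "compound,A,B,C",
    "drugX,0.5,,1",
    "drugY,0.25,0.75,0.1"
  ), ext = ".csv")
  x <- read_response_table(path)
  expect_identical(dim(x), c(2L, 3L))
  expect_identical(sum(is.na(x)), 1L)
  expect_true(is.na(x["drugX", "B"]))

  full <- read_response_table(write_tmp(
    c("compound,A,B", "drugX,0,1"),
    ext = ".csv"
  ))
  expect_identical(sum(is.na(full)), 0L)

  expect_error(
    read_response_table(write_tmp(c("compound,A", "drugX,1.2"), ext = ".csv")),
    "out of range"
  )
  expect_error(
    read_response_table(write_tmp(
      c("compound,A", "drugX,0.5", "drugX,0.6"),
      ext = ".csv"
    )),
    "duplicate compound"
  )
})

test_that("response CSV writer round-trips through the reader", {
  set.seed(4)
  x <- matrix(round(runif(6), 3), 2, 3,
    dimnames = list(c("d1", "d2"), c("A", "B", "C"))
  )
  x[1, 2] <- NA
  path <- tempfile(fileext = ".csv")
  write_response_table(x, path)
  expect_equal(read_response_table(path), x)
})

test_that("driver-gene lists are deduplicated, header-tolerant, never empty", {
  expect_identical(
    read_driver_genes(write_tmp(c("BRAF", "TP53", "BRAF"), ext = ".txt")),
    c("BRAF", "TP53")
  )
  expect_identical(
    read_driver_genes(write_tmp(c("gene", " BRAF ", "TP53"), ext = ".txt")),
    c("BRAF", "TP53")
  )
  expect_error(read_driver_genes(write_tmp(character(), ext = ".txt")), "empty")
})

test_that("cell-line normalization strips known tissue suffixes only", {
  expect_identical(
    normalize_cell_line_names(
      c("a375_SKIN", "KMS_11_HAEMATOPOIETIC_AND_LYMPHOID_TISSUE", "NO_SUFFIX_HERE"),
      strip_tissue_suffix = TRUE
    ),
    c("A375", "KMS_11", "NO_SUFFIX_HERE")
  )
  expect_identical(normalize_cell_line_names("a375_SKIN"), "A375_SKIN")
})

test_that("cell-line matching intersects normalized names in alteration order", {
  alt <- toy_alterations(matrix(c(1L, 0L, 1L, 1L), 2, 2))
  rownames(alt) <- c("A_LUNG", "B_SKIN")
  resp <- matrix(c(0.5, 0.25), 1, 2, dimnames = list("drugX", c("A", "C")))
  m <- match_cell_lines(alt, resp)
  expect_s3_class(m, "matched_study")
  expect_identical(m$cell_lines, "A")
  expect_identical(dim(m$alterations), c(1L, 2L))
  expect_identical(dim(m$responses), c(1L, 1L))

  disjoint <- matrix(0.5, 1, 1, dimnames = list("drugX", "ZZ"))
  expect_error(match_cell_lines(alt, disjoint), "no shared cell lines")
})

test_that("matching identical name sets preserves order and is idempotent", {
  set.seed(2)
  alt <- random_alterations(5, 3)
  rownames(alt) <- c("E", "D", "C", "B", "A")
  resp <- matrix(runif(10), 2, 5,
    dimnames = list(c("d1", "d2"), c("A", "B", "C", "D", "E"))
  )
  m <- match_cell_lines(alt, resp, strip_tissue_suffix = FALSE)
  expect_identical(m$cell_lines, c("E", "D", "C", "B", "A"))
  expect_identical(colnames(m$responses), rownames(m$alterations))
  m2 <- match_cell_lines(m$alterations, m$responses, strip_tissue_suffix = FALSE)
  expect_identical(m2$alterations, m$alterations)
  expect_identical(m2$responses, m$responses)
})
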