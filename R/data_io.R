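# Input parsing and cell-line matching.
#
# Internal orientation convention: cell lines are rows and alterations are
# columns of the alteration matrix (samples x features), regardless of the
# file orientation; the response matrix keeps the screen's native
# compounds x cell-lines layout.

#' CCLE-style tissue vocabulary
#'
#' Organ/tissue tokens that may be appended to a cell-line name with an
#' underscore (e.g. `A375_SKIN`). Used by [normalize_cell_line_names()] to
#' decide where the sample token ends.
#'
#' @return Character vector of uppercase tissue suffixes.
#' @export
ccle_tissue_vocabulary <- function() {
  c(
    "LUNG", "HAEMATOPOIETIC_AND_LYMPHOID_TISSUE", "BREAST", "LARGE_INTESTINE",
    "CENTRAL_NERVOUS_SYSTEM", "SKIN", "OVARY", "PANCREAS", "OESOPHAGUS",
    "STOMACH", "LIVER", "URINARY_TRACT", "UPPER_AERODIGESTIVE_TRACT",
    "SOFT_TISSUE", "KIDNEY", "AUTONOMIC_GANGLIA", "BONE", "ENDOMETRIUM",
    "THYROID", "PLEURA", "PROSTATE", "BILIARY_TRACT", "SMALL_INTESTINE"
  )
}

#' Normalize cell-line names
#'
#' Uppercases names and, optionally, strips a trailing `_TISSUE` suffix: the
#' name is cut at the first underscore whose remainder matches the tissue
#' vocabulary. Alteration-matrix columns carry such suffixes while response
#' tables usually do not, so matching needs a common normal form.
#'
#' @param x Character vector of cell-line names.
#' @param strip_tissue_suffix Strip a recognized tissue suffix?
#' @param tissue_vocabulary Uppercase tissue tokens recognized as suffixes.
#' @return Character vector of normalized names.
#' @export
normalize_cell_line_names <- function(x, strip_tissue_suffix = FALSE,
                                      tissue_vocabulary = ccle_tissue_vocabulary()) {
  out <- toupper(trimws(x))
  if (!strip_tissue_suffix) {
    return(out)
  }
  vapply(out, function(nm) {
    cuts <- gregexpr("_", nm, fixed = TRUE)[[1]]
    if (cuts[1] == -1L) {
      return(nm)
    }
    for (pos in cuts) {
      if (substring(nm, pos + 1L) %in% tissue_vocabulary) {
        return(substring(nm, 1L, pos - 1L))
      }
    }
    nm
  }, character(1), USE.NAMES = FALSE)
}

assert_alteration_matrix <- function(x) {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x))) {
    stop("alteration matrix must be a matrix with cell-line rownames and alteration colnames")
  }
  if (anyNA(x)) stop("alteration matrix contains missing entries")
  if (!all(x %in% c(0, 1))) stop("non-binary entry in alteration matrix")
  if (anyDuplicated(colnames(x))) stop("duplicate alteration label")
  if (anyDuplicated(rownames(x))) stop("duplicate cell-line label")
  invisible(x)
}

assert_response_matrix <- function(x) {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x))) {
    stop("response matrix must be a matrix with compound rownames and cell-line colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate compound label")
  v <- x[!is.na(x)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) stop("AUC out of range [0, 1]")
  invisible(x)
}

#' Read a binary alteration matrix in GCT dialect
#'
#' Expects the classic GCT layout: a `#1.2` version line, a
#' `<nrows>\t<ncols>` dimension line, a header row starting with
#' `Name`/`Description`, then one row per alteration. Rows are gene
#' alterations labelled `GENE_MUT` / `GENE_DEL` / `GENE_AMP`, columns are
#' cell lines, entries are presence indicators in \{0, 1\}.
#'
#' @param path Path to a GCT file.
#' @return Integer matrix, cell lines in rows and alterations in columns
#'   (the file is transposed into the package's samples-by-features
#'   convention).
#' @export
read_alteration_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("truncated GCT file: ", path)
  if (!grepl("^#1\\.", lines[1])) {
    stop("not a GCT file (missing '#1.x' version line): ", path)
  }
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]]))
  if (length(dims) < 2L || anyNA(dims[1:2])) stop("malformed GCT dimension line")
  tab <- read.delim(
    text = paste(lines[-(1:2)], collapse = "\n"),
    header = TRUE, check.names = FALSE, stringsAsFactors = FALSE
  )
  if (ncol(tab) < 3L) stop("GCT body must have Name, Description and data columns")
  if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2]) {
    stop(sprintf(
      "GCT dimension mismatch: declared %d x %d, found %d x %d",
      dims[1], dims[2], nrow(tab), ncol(tab) - 2L
    ))
  }
  alteration_labels <- as.character(tab[[1]])
  if (anyDuplicated(alteration_labels)) {
    stop(
      "duplicate alteration label: ",
      paste(unique(alteration_labels[duplicated(alteration_labels)]), collapse = ", ")
    )
  }
  values <- as.matrix(tab[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(values) <- "numeric")
  if (anyNA(values)) stop("missing or non-numeric entry in GCT body")
  if (!all(values %in% c(0, 1))) stop("non-binary entry in GCT body")
  out <- t(values)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(colnames(tab)[-(1:2)], alteration_labels)
  assert_alteration_matrix(out)
  out
}

#' Write an alteration matrix in GCT dialect
#'
#' Inverse of [read_alteration_gct()]; round-trips exactly.
#'
#' @param x Alteration matrix (cell lines x alterations).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alteration_gct <- function(x, path) {
  assert_alteration_matrix(x)
  body <- t(x) # back to alterations x cell lines
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(body), ncol(body), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", rownames(x)), collapse = "\t"), con)
  writeLines(paste(rownames(body), "na",
    apply(body, 1L, paste, collapse = "\t"),
    sep = "\t"
  ), con)
  invisible(path)
}

#' Read a compound-by-cell-line AUC table
#'
#' First column: compound identifiers; remaining columns: cell lines;
#' entries: dose-response AUCs in \[0, 1\] (0 = highest cytotoxicity,
#' 1 = lowest). Blank, `NA` and `NaN` cells all map to missing. `.csv`,
#' `.tsv`/`.txt` and `.xlsx` (via readxl) inputs are supported.
#'
#' @param path Path to the response table.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"xlsx"`.
#' @return Numeric matrix, compounds in rows, cell lines in columns, with
#'   `NA` for unscreened combinations.
#' @export
read_response_table <- function(path, format = c("auto", "csv", "tsv", "xlsx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", xlsx = "xlsx", "tsv"
    )
  }
  na_tokens <- c("", "NA", "NaN", "na", "nan")
  if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx response tables requires the 'readxl' package")
    }
    tab <- as.data.frame(readxl::read_excel(path, na = na_tokens),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  } else {
    tab <- read.delim(path,
      sep = if (format == "csv") "," else "\t",
      header = TRUE, check.names = FALSE, stringsAsFactors = FALSE,
      na.strings = na_tokens
    )
  }
  if (ncol(tab) < 2L) stop("response table needs a compound column and at least one cell line")
  compounds <- as.character(tab[[1]])
  if (anyDuplicated(compounds)) {
    stop(
      "duplicate compound label: ",
      paste(unique(compounds[duplicated(compounds)]), collapse = ", ")
    )
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(values) <- "numeric")
  rownames(values) <- compounds
  assert_response_matrix(values)
  values
}

#' Write a response matrix as CSV
#'
#' @param x Response matrix (compounds x cell lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(x, path) {
  assert_response_matrix(x)
  df <- data.frame(compound = rownames(x), x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a driver-gene list
#'
#' One gene symbol per line; an optional header line (`gene`, `symbol`, ...)
#' is dropped; whitespace is stripped and duplicates removed.
#'
#' @param path Path to the gene list.
#' @return Character vector of unique gene symbols.
#' @export
read_driver_genes <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) &&
    grepl("^(gene|genes|symbol|symbols|gene_symbol|hugo_symbol)$",
      lines[1],
      ignore.case = TRUE
    )) {
    lines <- lines[-1L]
  }
  genes <- unique(lines)
  if (!length(genes)) stop("empty driver-gene list: ", path)
  genes
}

#' Match cell lines between the alteration and response datasets
#'
#' Cell-line names on the alteration side are normalized (uppercased, tissue
#' suffix optionally stripped); response names are uppercased. Both matrices
#' are restricted to the intersection, in the alteration matrix's original
#' order, with identical ordering in the two components.
#'
#' @param alterations Alteration matrix (cell lines x alterations).
#' @param responses Response matrix (compounds x cell lines).
#' @param strip_tissue_suffix Strip tissue suffixes from alteration-side
#'   names (the CCLE convention)?
#' @param tissue_vocabulary Passed to [normalize_cell_line_names()].
#' @return A `matched_study`: list with elements `alterations`
#'   (cells x alterations), `responses` (compounds x cells, columns
#'   co-ordered with the alteration rows) and `cell_lines`.
#' @export
match_cell_lines <- function(alterations, responses, strip_tissue_suffix = TRUE,
                             tissue_vocabulary = ccle_tissue_vocabulary()) {
  assert_alteration_matrix(alterations)
  assert_response_matrix(responses)
  alt_names <- normalize_cell_line_names(rownames(alterations),
    strip_tissue_suffix = strip_tissue_suffix,
    tissue_vocabulary = tissue_vocabulary
  )
  resp_names <- normalize_cell_line_names(colnames(responses))
  if (anyDuplicated(alt_names)) stop("cell-line names collide after normalization")
  keep <- which(alt_names %in% resp_names)
  if (!length(keep)) stop("no shared cell lines between the two datasets")
  shared <- alt_names[keep]
  alt <- alterations[keep, , drop = FALSE]
  rownames(alt) <- shared
  resp <- responses[, match(shared, resp_names), drop = FALSE]
  colnames(resp) <- shared
  structure(
    list(alterations = alt, responses = resp, cell_lines = shared),
    class = "matched_study"
  )
}

#' @export
print.matched_study <- function(x, ...) {
  cat(
    "Matched pharmacogenomic study:",
    length(x$cell_lines), "cell lines,",
    ncol(x$alterations), "alterations,",
    nrow(x$responses), "compounds\n"
  )
  cat(
    "missing AUCs:",
    sprintf("%.1f%%", 100 * mean(is.na(x$responses))), "\n"
  )
  invisible(x)
}
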