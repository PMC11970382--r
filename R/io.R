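## Readers/writers for the external formats the pipeline touches. All tables
## are plain data.frames; reals are serialized with 12 significant digits so
## write -> read round-trips to that precision.

#' Read spot positions
#'
#' Reads spot coordinates in either of two dialects:
#'
#' * `"visium_list"`: the headerless Visium `tissue_positions_list.csv`
#'   layout `barcode,in_tissue,array_row,array_col,pxl_row,pxl_col`. Pixel
#'   columns are mapped to Cartesian coordinates as `x = pxl_col`,
#'   `y = pxl_row`. Spots with `in_tissue = 0` are retained but flagged.
#' * `"generic_xy"`: a headered CSV with columns `spot_id,x,y`.
#'
#' Coordinate units (pixels or micrometres) are not interpreted; downstream
#' analyses treat them as consistent Euclidean units within one file.
#'
#' @param path CSV file path.
#' @param dialect `"visium_list"` or `"generic_xy"`.
#' @return A data.frame with columns `spot_id` (character), `in_tissue`
#'   (logical), `array_row`, `array_col` (integer; `NA` for `generic_xy`),
#'   `x`, `y` (numeric).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("AAAC-1,1,0,0,102.5,311.0", "AAAG-1,0,0,2,102.5,425.5"), f)
#' read_spot_positions(f, "visium_list")
#' @export
read_spot_positions <- function(path, dialect = c("visium_list", "generic_xy")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "visium_list") {
    raw <- tryCatch(
      read.csv(path, header = FALSE, colClasses = c(
        "character", "integer", "integer", "integer", "numeric", "numeric"
      )),
      error = function(e) stop("malformed visium_list file '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    if (nrow(raw) == 0L) stop("no data rows in ", path)
    if (ncol(raw) != 6L) {
      stop("visium_list file must have 6 columns, found ", ncol(raw))
    }
    spots <- data.frame(
      spot_id = raw[[1L]],
      in_tissue = raw[[2L]] != 0L,
      array_row = raw[[3L]],
      array_col = raw[[4L]],
      x = raw[[6L]],   # pxl_col -> x
      y = raw[[5L]],   # pxl_row -> y
      stringsAsFactors = FALSE
    )
  } else {
    raw <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("spot_id", "x", "y")
    miss <- setdiff(need, names(raw))
    if (length(miss)) {
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    }
    if (nrow(raw) == 0L) stop("no data rows in ", path)
    for (cc in c("x", "y")) {
      v <- suppressWarnings(as.numeric(raw[[cc]]))
      bad <- which(is.na(v) & !is.na(raw[[cc]]))
      if (length(bad)) {
        stop("non-numeric value in column '", cc, "' at data row ", bad[1L])
      }
      raw[[cc]] <- v
    }
    spots <- data.frame(
      spot_id = as.character(raw$spot_id),
      in_tissue = if ("in_tissue" %in% names(raw)) raw$in_tissue != 0 else TRUE,
      array_row = NA_integer_, array_col = NA_integer_,
      x = raw$x, y = raw$y, stringsAsFactors = FALSE
    )
  }
  validate_spot_table(spots)
  spots
}

validate_spot_table <- function(spots) {
  stopifnot(is.data.frame(spots),
            all(c("spot_id", "x", "y") %in% names(spots)))
  if (nrow(spots) < 1L) stop("spot table must have at least 1 row")
  dup <- spots$spot_id[duplicated(spots$spot_id)]
  if (length(dup)) {
    stop("duplicate spot_id: ", paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(spots$x)) || any(!is.finite(spots$y))) {
    stop("spot coordinates must be finite")
  }
  invisible(spots)
}

#' Write spot positions
#'
#' Inverse of [read_spot_positions()], in either dialect.
#'
#' @param spots Spot table as returned by [read_spot_positions()].
#' @param path Output CSV path.
#' @param dialect Output dialect; `visium_list` requires integer array
#'   indices and writes `x`/`y` back to `pxl_col`/`pxl_row`.
#' @return `path`, invisibly.
#' @export
write_spot_positions <- function(spots, path,
                                 dialect = c("visium_list", "generic_xy")) {
  dialect <- match.arg(dialect)
  validate_spot_table(spots)
  if (dialect == "visium_list") {
    out <- data.frame(
      barcode = spots$spot_id,
      in_tissue = as.integer(spots$in_tissue),
      array_row = spots$array_row,
      array_col = spots$array_col,
      pxl_row = fmt_real(spots$y),
      pxl_col = fmt_real(spots$x)
    )
    write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                col.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  } else {
    out <- data.frame(spot_id = spots$spot_id,
                      x = fmt_real(spots$x), y = fmt_real(spots$y))
    write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  }
  invisible(path)
}

fmt_real <- function(x) formatC(x, digits = 12, format = "g")

#' Read a sparse count matrix (MatrixMarket triplet + feature/barcode TSVs)
#'
#' Reads the conventional CellRanger-style trio: a MatrixMarket coordinate
#' file of non-negative integer counts with features (genes) as rows and
#' barcodes (spots) as columns, plus one-feature-per-line and
#' one-barcode-per-line TSVs. Duplicate (gene, barcode) triplets are
#' collapsed by summation on load, so the returned matrix has at most one
#' value per cell.
#'
#' @param mtx Path to the `.mtx` file.
#' @param features Path to the features TSV (first column = gene id; an
#'   optional second column holds gene names).
#' @param barcodes Path to the barcodes TSV (one barcode per line).
#' @return A `dgCMatrix` (genes x spots) with dimnames set from the TSVs.
#' @export
read_counts_mtx <- function(mtx, features, barcodes) {
  for (p in c(mtx, features, barcodes)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MatrixMarket file '",
                                         mtx, "': ", conditionMessage(e),
                                         call. = FALSE))
  feat <- read.delim(features, header = FALSE, stringsAsFactors = FALSE)
  bc <- read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feat) != nrow(m)) {
    stop("dimension mismatch: mtx declares ", nrow(m), " features but '",
         features, "' has ", nrow(feat), " lines")
  }
  if (nrow(bc) != ncol(m)) {
    stop("dimension mismatch: mtx declares ", ncol(m), " barcodes but '",
         barcodes, "' has ", nrow(bc), " lines")
  }
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(vals)) {
    if (any(vals < 0)) stop("negative counts in ", mtx)
    if (any(vals != floor(vals))) stop("non-integer counts in ", mtx)
  }
  out <- methods::as(m, "CsparseMatrix")
  dimnames(out) <- list(feat[[1L]], bc[[1L]])
  out
}

#' Write a sparse count matrix as MatrixMarket triplet + TSVs
#'
#' @param counts genes x spots matrix (coercible to sparse).
#' @param mtx,features,barcodes Output paths.
#' @return `mtx`, invisibly.
#' @export
write_counts_mtx <- function(counts, mtx, features, barcodes) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, mtx)
  writeLines(rownames(counts), features)
  writeLines(colnames(counts), barcodes)
  invisible(mtx)
}

#' Read a headered CSV/TSV against a column schema
#'
#' Generic validated table reader used for abundance matrices, point
#' patterns, and cohort tables. `schema` names the required columns and
#' their semantic types; extra columns are preserved.
#'
#' @param path File path (.csv or .tsv by extension; comma default).
#' @param schema Named character vector: `c(column = type, ...)` with types
#'   `"character"`, `"numeric"`, `"integer"`, or `"logical"`.
#' @return The validated data.frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(cell_id = "c1", phenotype = "HEV",
#'                      x_um = 1, y_um = 2), f, row.names = FALSE)
#' read_table(f, schema = c(cell_id = "character", phenotype = "character",
#'                          x_um = "numeric", y_um = "numeric"))
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is.character(schema), !is.null(names(schema)))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
  miss <- setdiff(names(schema), names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  for (col in names(schema)) {
    raw[[col]] <- coerce_column(raw[[col]], schema[[col]], col)
  }
  raw
}

coerce_column <- function(v, type, col) {
  switch(type,
    character = as.character(v),
    logical = {
      out <- as.logical(v)
      if (is.numeric(v)) out <- v != 0
      out
    },
    numeric = ,
    integer = {
      out <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(out) & !is.na(v) & v != "")
      if (length(bad)) {
        stop("non-", type, " value '", v[bad[1L]], "' in column '", col,
             "' at data row ", bad[1L])
      }
      if (type == "integer") out <- as.integer(out)
      out
    },
    stop("unknown schema type: ", type)
  )
}

#' Built-in table schemas
#'
#' Column schemas for the three generic tables the pipeline consumes, for
#' use with [read_table()]: mIHC-style point patterns
#' (`cell_id, phenotype, x_um, y_um`), cohort design
#' (`patient, arm, timepoint, response`), and per-cell annotation tables
#' (`sample_id, cell_type`).
#'
#' @format Named character vectors.
#' @name schemas
NULL

#' @rdname schemas
#' @export
schema_point_pattern <- c(cell_id = "character", phenotype = "character",
                          x_um = "numeric", y_um = "numeric")

#' @rdname schemas
#' @export
schema_cohort <- c(patient = "character", arm = "character",
                   timepoint = "character", response = "character")

#' @rdname schemas
#' @export
schema_cell_annotation <- c(sample_id = "character", cell_type = "character")

#' Read a spots x cell-types abundance matrix from CSV
#'
#' Expects a headered CSV whose first column is `spot_id` and whose
#' remaining columns are numeric per-type abundances (deconvolution
#' output).
#'
#' @param path CSV path.
#' @return Numeric matrix (spots x cell types) with `spot_id` rownames.
#' @export
read_abundance_csv <- function(path) {
  tab <- read_table(path, schema = c(spot_id = "character"))
  if (ncol(tab) < 2L) stop("abundance table needs at least one type column")
  types <- setdiff(names(tab), "spot_id")
  for (col in types) tab[[col]] <- coerce_column(tab[[col]], "numeric", col)
  m <- as.matrix(tab[types])
  rownames(m) <- tab$spot_id
  if (anyDuplicated(rownames(m))) stop("duplicate spot_id in ", path)
  m
}

#' Write a data.frame (or abundance matrix) as a CSV
#'
#' Numeric columns are serialized with 12 significant digits, UTF-8, LF
#' line endings, so round-trips through [read_table()] /
#' [read_abundance_csv()] agree to that precision.
#'
#' @param x data.frame, or a numeric matrix with rownames (written with a
#'   leading `spot_id` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(spot_id = rownames(x), as.data.frame(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- x
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- fmt_real(out[[col]])
    }
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
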