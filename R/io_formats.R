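# Readers/writers for the three tabular interchange formats (sample metadata,
# feature table, distance matrix) and the Jaccard presence/absence helper.

ID_HEADERS <- c("#sampleid", "sample-id", "sampleid", "id")

#' Construct a sample-metadata object
#'
#' A `sample_metadata` is a per-sample table keyed by unique sample IDs, with
#' a designated numeric state (time) column and a categorical subject
#' (individual) column used by all longitudinal operations.
#'
#' @param data data.frame of metadata columns; row names are the sample IDs
#'   (or pass a `sample_id` column which is promoted to row names).
#' @param state_column name of the numeric time column.
#' @param subject_column name of the subject (individual) identifier column.
#' @param column_types optional named character vector (`"numeric"` or
#'   `"categorical"`) overriding type inference per column.
#' @return An object of class `sample_metadata`: a data.frame with attributes
#'   `state_column`, `subject_column` and `column_types`.
#' @export
sample_metadata <- function(data, state_column, subject_column = NULL,
                            column_types = NULL) {
  stopifnot(is.data.frame(data))
  if ("sample_id" %in% names(data) && is.null(rownames(data))) {
    rownames(data) <- data[["sample_id"]]
    data[["sample_id"]] <- NULL
  }
  ids <- rownames(data)
  if (is.null(ids) || any(ids == "" | is.na(ids))) {
    stop("sample metadata requires non-empty sample IDs as row names")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sample IDs in metadata: ", paste(dup, collapse = ", "))
  }
  if (!state_column %in% names(data)) {
    stop("state column '", state_column, "' not found in metadata")
  }
  types <- infer_column_types(data, column_types)
  types[[state_column]] <- "numeric"  # the state column must parse as numeric
  # coerce declared-numeric columns, validating the state column strictly;
  # columns that are already numeric are kept bit-for-bit as given
  for (col in names(data)) {
    if (identical(types[[col]], "numeric")) {
      if (is.numeric(data[[col]])) next
      raw <- as.character(data[[col]])
      raw[raw %in% c("", "NA")] <- NA_character_
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & is.na(num))
      if (length(bad)) {
        if (identical(col, state_column)) {
          stop("non-numeric value in state column '", col, "': row '",
               ids[bad[1L]], "' has value '", raw[bad[1L]], "'")
        }
        types[[col]] <- "categorical"
        val <- raw
        data[[col]] <- val
      } else {
        data[[col]] <- num
      }
    } else {
      if (is.numeric(data[[col]])) {
        data[[col]] <- as.character(data[[col]])
        next
      }
      val <- as.character(data[[col]])
      val[val %in% c("", "NA")] <- NA_character_
      data[[col]] <- val
    }
  }
  if (!is.numeric(data[[state_column]])) {
    stop("state column '", state_column, "' must be numeric")
  }
  if (!all(is.finite(data[[state_column]]) | is.na(data[[state_column]]))) {
    stop("state column '", state_column, "' contains non-finite values")
  }
  if (!is.null(subject_column) && !subject_column %in% names(data)) {
    stop("subject column '", subject_column, "' not found in metadata")
  }
  structure(data,
            state_column = state_column,
            subject_column = subject_column,
            column_types = types,
            class = c("sample_metadata", "data.frame"))
}

infer_column_types <- function(data, declared = NULL) {
  types <- vapply(names(data), function(col) {
    raw <- as.character(data[[col]])
    raw <- raw[!(raw %in% c("", "NA") | is.na(raw))]
    if (length(raw) && !anyNA(suppressWarnings(as.numeric(raw)))) "numeric"
    else "categorical"
  }, character(1))
  if (!is.null(declared)) {
    unknown <- setdiff(names(declared), names(data))
    if (length(unknown)) {
      stop("declared types for unknown columns: ", paste(unknown, collapse = ", "))
    }
    types[names(declared)] <- declared
  }
  types
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("sample_metadata: %d samples x %d columns (state: %s, subject: %s)\n",
              nrow(x), ncol(x), attr(x, "state_column"),
              if (is.null(attr(x, "subject_column"))) "<none>" else attr(x, "subject_column")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read sample metadata from TSV
#'
#' Reads a tab-separated metadata file whose first column holds sample IDs
#' under one of the accepted headers (`#SampleID`, `sample-id`, `sampleid`,
#' `id`; case-insensitive). An optional second header line beginning
#' `#q2:types` declares per-column types (`categorical`/`numeric`) and takes
#' precedence over inference; otherwise a column is numeric when every
#' non-missing value parses as a number. Empty cells and `NA` are missing.
#'
#' @inheritParams sample_metadata
#' @param path path to the TSV file.
#' @return A [sample_metadata] object.
#' @export
read_metadata <- function(path, state_column, subject_column = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty metadata file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!tolower(header[[1L]]) %in% ID_HEADERS) {
    stop("metadata ID header must be one of #SampleID/sample-id/sampleid/id; got '",
         header[[1L]], "'")
  }
  declared <- NULL
  body_start <- 2L
  if (length(lines) >= 2L && startsWith(lines[[2L]], "#q2:types")) {
    decl <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    decl <- decl[-1L]
    length(decl) <- length(header) - 1L
    decl <- tolower(trimws(decl))
    keep <- decl %in% c("numeric", "categorical")
    declared <- stats::setNames(decl[keep], header[-1L][keep])
    body_start <- 3L
  }
  body <- lines[seq.int(body_start, length.out = max(0L, length(lines) - body_start + 1L))]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  df <- as.data.frame(do.call(rbind, lapply(cells, function(r) {
    length(r) <- length(header)
    r[is.na(r)] <- ""
    r
  })), stringsAsFactors = FALSE)
  names(df) <- header
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sample IDs in metadata: ", paste(dup, collapse = ", "))
  }
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- ids
  sample_metadata(df, state_column = state_column,
                  subject_column = subject_column, column_types = declared)
}

#' Write sample metadata to TSV
#'
#' Emits a `sample-id` header, a `#q2:types` type-declaration line and one
#' row per sample; numeric values carry 10 significant digits, LF line
#' terminators.
#'
#' @param x a [sample_metadata] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path) {
  stopifnot(inherits(x, "sample_metadata"))
  types <- attr(x, "column_types")[names(x)]
  rows <- vapply(seq_len(nrow(x)), function(i) {
    vals <- vapply(names(x), function(col) {
      v <- x[[col]][i]
      if (is.na(v)) "" else if (is.numeric(v)) format_number(v) else as.character(v)
    }, character(1))
    paste(c(rownames(x)[i], vals), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("sample-id", names(x)), collapse = "\t"),
               paste(c("#q2:types", unname(types)), collapse = "\t"),
               rows), path, sep = "\n")
  invisible(path)
}

format_number <- function(x) {
  out <- formatC(x, digits = 10L, format = "g", mode = "double")
  trimws(out)
}

#' Construct a feature table
#'
#' Samples x features abundance matrix (counts or relative frequencies).
#' Entries must be nonnegative and IDs unique on both axes; when declared
#' relative, every non-empty sample row must sum to 1 within 1e-6.
#'
#' @param values numeric matrix, samples as rows, with dimnames.
#' @param relative logical; declare the table as relative frequencies.
#' @return An object of class `feature_table` (a validated numeric matrix).
#' @export
feature_table <- function(values, relative = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("feature table requires sample (row) and feature (column) names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample IDs in feature table")
  if (anyDuplicated(colnames(values))) stop("duplicate feature IDs in feature table")
  if (anyNA(values)) stop("feature table contains missing values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative entry in feature table at sample '",
         rownames(values)[bad[1L]], "', feature '", colnames(values)[bad[2L]], "'")
  }
  if (relative) {
    rs <- rowSums(values)
    off <- which(rs > 0 & abs(rs - 1) > 1e-6)
    if (length(off)) {
      stop("relative feature table rows must sum to 1 (or 0): sample '",
           rownames(values)[off[1L]], "' sums to ", rs[off[1L]])
    }
  }
  structure(values, relative = relative,
            class = c("feature_table", class(values)))
}

#' Read a feature table from TSV or BIOM
#'
#' Dense TSV input has row and column headers; `orientation` says whether
#' rows are samples (default) or features, and the result is always oriented
#' samples x features. Files ending in `.biom` are read with the biomformat
#' package and auto-oriented from its axis labels (observations are
#' features).
#'
#' @param path input path.
#' @param orientation `"samples-as-rows"` (default) or `"features-as-rows"`;
#'   ignored for BIOM input.
#' @param relative declare the table as relative frequencies (validated).
#' @return A [feature_table].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples-as-rows", "features-as-rows"),
                               relative = FALSE) {
  orientation <- match.arg(orientation)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM input requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
    values <- t(m)
  } else {
    values <- read_tsv_matrix(path)
    if (orientation == "features-as-rows") values <- t(values)
  }
  feature_table(values, relative = relative)
}

read_tsv_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file needs a header and at least one row: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1L]])
  ragged <- which(lengths(cells) != width)
  if (length(ragged)) {
    stop("ragged rows in ", path, ": line ", ragged[1L], " has ",
         lengths(cells)[ragged[1L]], " fields, expected ", width)
  }
  col_ids <- cells[[1L]][-1L]
  row_ids <- vapply(cells[-1L], `[[`, character(1), 1L)
  num <- vapply(cells[-1L], function(r) {
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(v)) stop("non-numeric matrix entry in ", path)
    v
  }, numeric(width - 1L))
  values <- if (is.matrix(num)) t(num) else matrix(num, nrow = length(row_ids))
  dimnames(values) <- list(row_ids, col_ids)
  values
}

#' Write a feature table to TSV
#'
#' Samples as rows; 10 significant digits; LF terminators.
#' @param x a [feature_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  write_tsv_matrix(unclass(x), path, corner = "sample-id")
  invisible(path)
}

write_tsv_matrix <- function(m, path, corner = "id") {
  header <- paste(c(corner, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], vapply(m[i, ], format_number, character(1))),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path, sep = "\n")
}

#' Construct a distance matrix
#'
#' Square, symmetric (within 1e-8), hollow (zero diagonal) nonnegative matrix
#' over unique sample IDs.
#'
#' @param values square numeric matrix with identical row/column names.
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  ids <- rownames(values)
  if (is.null(ids) || !identical(ids, colnames(values))) {
    stop("distance matrix requires identical row and column IDs")
  }
  if (anyDuplicated(ids)) stop("duplicate IDs in distance matrix")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8) {
    stop("distance matrix asymmetric: max |d(a,b) - d(b,a)| = ", format(asym))
  }
  if (any(abs(diag(values)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (any(values < 0)) stop("distance matrix entries must be nonnegative")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(values, class = c("distance_matrix", class(values)))
}

#' Read a distance matrix from square TSV
#'
#' Expects an ID header row, a leading ID column, and identical row/column
#' ID orderings. Asymmetry beyond 1e-8 or a nonzero diagonal is an error.
#'
#' @param path input path.
#' @return A [distance_matrix].
#' @export
read_distance_matrix <- function(path) {
  values <- read_tsv_matrix(path)
  if (!identical(rownames(values), colnames(values))) {
    stop("distance matrix row and column ID orderings differ in ", path)
  }
  distance_matrix(values)
}

#' Write a distance matrix to square TSV
#' @param x a [distance_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(x, path) {
  stopifnot(inherits(x, "distance_matrix"))
  write_tsv_matrix(unclass(x), path, corner = "id")
  invisible(path)
}

#' Pairwise Jaccard distances between samples
#'
#' The Jaccard distance between two samples is the proportion of observed
#' features that are not shared: `1 - |Pa intersect Pb| / |Pa union Pb|`,
#' where `Ps` is the set of features detected (abundance strictly above
#' `detection_threshold`, default 0) in sample `s`. Two empty samples are at
#' distance 0. Depends only on presence/absence, so any positive rescaling
#' of a sample leaves it unchanged.
#'
#' @param table a [feature_table] with at least two samples.
#' @param detection_threshold abundance strictly above this counts as present.
#' @return A [distance_matrix] over the table's samples.
#' @export
jaccard_distances <- function(table, detection_threshold = 0) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table) < 2L) stop("jaccard_distances requires at least two samples")
  pres <- matrix(as.numeric(unclass(table) > detection_threshold), nrow = nrow(table),
                 dimnames = dimnames(table))
  inter <- pres %*% t(pres)
  sizes <- rowSums(pres)
  union <- outer(sizes, sizes, `+`) - inter
  d <- 1 - inter / union
  d[union == 0] <- 0  # both samples empty
  diag(d) <- 0
  distance_matrix(d)
}
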