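#' Read a contact matrix from a text file
#'
#' Three dialects are supported:
#'
#' * `"square_tsv"` — tab-separated 20x20 table with a residue header row
#'   and a residue label as the first field of each row. The table must
#'   be symmetric to within 1e-9.
#' * `"lower_triangle"` — a line with the residue labels (whitespace- or
#'   tab-separated) followed by the n(n+1)/2 values of the lower triangle
#'   including the diagonal, row-major (row k carries k values; line
#'   breaks are not significant).
#' * `"aaindex"` — an AAindex-style matrix entry (read-only). The line
#'   starting `M ` declares the row/column alphabets
#'   (`M rows = ARND..., cols = ARND...`); the body is the
#'   lower-triangular matrix (or a full square), terminated by `//` or
#'   end of input. `-` or `NA` cells are rejected.
#'
#' The label order declared by the source is preserved on the returned
#' object.
#'
#' @param source Path to a file, or a character vector of lines.
#' @param dialect One of `"square_tsv"`, `"lower_triangle"`, `"aaindex"`.
#' @param name Provenance tag; defaults to the file name.
#' @return A [contact_matrix].
#' @seealso [write_contact_matrix()]
#' @export
read_contact_matrix <- function(source,
                                dialect = c("square_tsv", "lower_triangle",
                                            "aaindex"),
                                name = NULL) {
  dialect <- match.arg(dialect)
  lines <- read_source_lines(source)
  if (is.null(name)) {
    name <- if (length(source) == 1L && file.exists(source)) {
      basename(source)
    } else {
      dialect
    }
  }
  switch(dialect,
    square_tsv = parse_square_tsv(lines, name),
    lower_triangle = parse_lower_triangle(lines, name),
    aaindex = parse_aaindex_matrix(lines, name)
  )
}

read_source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  }
}

check_matrix_labels <- function(labels) {
  if (anyDuplicated(labels)) {
    stop("duplicate residue labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  missing <- setdiff(residue_alphabet(), labels)
  if (length(labels) == 20L && length(missing)) {
    stop("missing residues: ", paste(missing, collapse = ", "))
  }
  labels
}

parse_square_tsv <- function(lines, name) {
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "[\t ]+")[[1]]
  labels <- check_matrix_labels(header)
  n <- length(labels)
  if (length(lines) < n + 1L) stop("square table truncated: expected ",
                                   n, " data rows")
  vals <- matrix(NA_real_, n, n)
  row_labels <- character(n)
  for (k in seq_len(n)) {
    fields <- strsplit(trimws(lines[k + 1L]), "[\t ]+")[[1]]
    if (length(fields) != n + 1L) {
      stop("row ", k, " has ", length(fields) - 1L, " cells, expected ", n)
    }
    row_labels[k] <- fields[1]
    x <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1]
      stop(sprintf("non-numeric cell at row %s, column %s: '%s'",
                   fields[1], labels[bad], fields[bad + 1L]))
    }
    vals[k, ] <- x
  }
  if (!identical(row_labels, labels)) {
    stop("row labels do not match header order")
  }
  contact_matrix(vals, labels, name = name, tol = 1e-9)
}

parse_lower_triangle <- function(lines, name) {
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^#", lines)]
  labels <- strsplit(trimws(lines[1]), "[\t ]+")[[1]]
  labels <- check_matrix_labels(labels)
  n <- length(labels)
  fields <- unlist(strsplit(trimws(lines[-1]), "[\t ]+"))
  fields <- fields[nzchar(fields)]
  need <- n * (n + 1L) / 2L
  if (length(fields) != need) {
    stop("lower-triangle body has ", length(fields),
         " values, expected ", need)
  }
  x <- suppressWarnings(as.numeric(fields))
  if (anyNA(x)) {
    stop("non-numeric cell in lower-triangle body: '",
         fields[which(is.na(x))[1]], "'")
  }
  vals <- matrix(0, n, n)
  vals[upper.tri(vals, diag = TRUE)] <- x
  vals <- vals + t(vals) - diag(diag(vals))
  contact_matrix(vals, labels, name = name)
}

parse_aaindex_matrix <- function(lines, name) {
  mline <- grep("^M ", lines)
  if (!length(mline)) stop("no 'M rows = ..., cols = ...' line found")
  decl <- lines[mline[1]]
  rows <- sub(".*rows\\s*=\\s*([A-Za-z]+).*", "\\1", decl)
  cols <- sub(".*cols\\s*=\\s*([A-Za-z]+).*", "\\1", decl)
  if (!nzchar(rows) || rows == decl) stop("could not parse alphabets in: ",
                                          decl)
  if (rows != cols) stop("row and column alphabets differ")
  labels <- check_matrix_labels(strsplit(rows, "")[[1]])
  n <- length(labels)
  body <- lines[-seq_len(mline[1])]
  end <- grep("^//", body)
  if (length(end)) body <- body[seq_len(end[1] - 1L)]
  body <- body[nzchar(trimws(body))]
  tokens <- lapply(body, function(l) strsplit(trimws(l), "[\t ]+")[[1]])
  if (any(unlist(tokens) %in% c("-", "NA"))) {
    stop("AAindex entry has missing cells ('-' or NA)")
  }
  counts <- lengths(tokens)
  vals <- matrix(NA_real_, n, n)
  if (length(tokens) == n && all(counts == seq_len(n))) {
    for (i in seq_len(n)) {
      x <- as.numeric(tokens[[i]])
      vals[i, seq_len(i)] <- x
      vals[seq_len(i), i] <- x
    }
  } else if (length(tokens) == n && all(counts == n)) {
    vals <- matrix(as.numeric(unlist(tokens)), n, n, byrow = TRUE)
  } else {
    stop("AAindex body is neither lower-triangular nor square (rows: ",
         paste(counts, collapse = ","), ")")
  }
  if (anyNA(vals)) stop("non-numeric cell in AAindex body")
  contact_matrix(vals, labels, name = name, tol = 1e-6)
}

#' Write a contact matrix to text
#'
#' Serializes a [contact_matrix] in the `"square_tsv"` or
#' `"lower_triangle"` dialect of [read_contact_matrix()]. Values are
#' written with 15 significant digits (`%.15g`), so a write/read round
#' trip reproduces the matrix to well below 1e-12.
#'
#' @param matrix A [contact_matrix].
#' @param path Output file path, or `NULL` to return the lines.
#' @param dialect `"square_tsv"` or `"lower_triangle"`.
#' @return The lines, invisibly when written to `path`.
#' @export
write_contact_matrix <- function(matrix, path = NULL,
                                 dialect = c("square_tsv",
                                             "lower_triangle")) {
  stopifnot(inherits(matrix, "contact_matrix"))
  dialect <- match.arg(dialect)
  fmt <- function(x) sprintf("%.15g", x)
  labels <- matrix$labels
  n <- length(labels)
  if (dialect == "square_tsv") {
    lines <- c(
      paste(c("", labels), collapse = "\t"),
      vapply(seq_len(n), function(i) {
        paste(c(labels[i], fmt(matrix$values[i, ])), collapse = "\t")
      }, character(1))
    )
  } else {
    lines <- c(
      paste(labels, collapse = "\t"),
      vapply(seq_len(n), function(i) {
        paste(fmt(matrix$values[i, seq_len(i)]), collapse = "\t")
      }, character(1))
    )
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Per-residue free-energy scale
#'
#' A 20-element (or fewer, for partial scales) vector of per-residue free
#' energies on the RT scale: fitted one-body terms, q-values, or
#' converted secondary-structure propensities.
#'
#' @param values Named numeric vector, or unnamed with `labels` given.
#' @param labels Residue labels.
#' @param name Provenance tag.
#' @return Object of class `one_body_scale`: list with `labels`,
#'   `values` (named numeric) and `name`.
#' @export
one_body_scale <- function(values, labels = names(values), name = "") {
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  values <- as.numeric(values)
  if (length(values) != length(labels)) stop("one value per residue required")
  if (anyDuplicated(labels)) stop("duplicate residue labels")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("scale values must be finite")
  }
  names(values) <- labels
  structure(list(labels = labels, values = values, name = name),
            class = "one_body_scale")
}

#' @export
print.one_body_scale <- function(x, ...) {
  cat("One-body scale", if (nzchar(x$name)) paste0("\"", x$name, "\""),
      sprintf("(%d residues)\n", length(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' Read a one-body scale from two-column TSV
#'
#' Expects lines of `residue<TAB>value`; a header line is detected and
#' skipped when its second field is non-numeric.
#'
#' @param source Path or character lines.
#' @param name Provenance tag.
#' @return A [one_body_scale].
#' @export
read_onebody_scale <- function(source, name = NULL) {
  lines <- read_source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(name)) {
    name <- if (length(source) == 1L && file.exists(source)) {
      basename(source)
    } else {
      "scale"
    }
  }
  fields <- strsplit(trimws(lines), "[\t ]+")
  second <- vapply(fields, `[`, character(1), 2)
  if (is.na(suppressWarnings(as.numeric(second[1])))) {
    fields <- fields[-1]
    second <- second[-1]
  }
  vals <- suppressWarnings(as.numeric(second))
  if (anyNA(vals)) stop("non-numeric value in scale file")
  one_body_scale(vals, vapply(fields, `[`, character(1), 1), name = name)
}

#' Write a one-body scale as two-column TSV
#' @param scale A [one_body_scale].
#' @param path Output path, or `NULL` to return lines.
#' @return The lines, invisibly when written.
#' @export
write_onebody_scale <- function(scale, path = NULL) {
  stopifnot(inherits(scale, "one_body_scale"))
  lines <- c("residue\tvalue",
             sprintf("%s\t%.15g", scale$labels, scale$values))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Bundled one-body reference scales
#'
#' Loads the package's bundled table of six per-residue free-energy
#' scales (RT units): the one-body terms fitted to the MJ, parallel and
#' antiparallel strand-pairing matrices, the q-value scale of the MJ
#' one-body decomposition literature, and parallel/antiparallel
#' beta-sheet formation free energies converted from published propensity
#' scales.
#'
#' @return Named list of six [one_body_scale] objects:
#'   `q_mj`, `q_parallel`, `q_antiparallel`, `qvalues_li`,
#'   `dg_beta_parallel`, `dg_beta_antiparallel`.
#' @export
table2_scales <- function() {
  path <- system.file("extdata", "table2_scales.tsv", package = "potdecomp",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE)
  out <- lapply(names(tab)[-1], function(col) {
    one_body_scale(tab[[col]], tab$residue, name = col)
  })
  names(out) <- names(tab)[-1]
  out
}

#' Load an externally supplied contact matrix with checksum validation
#'
#' The published contact potentials this package analyses (MJ, parallel /
#' antiparallel strand pairing, SJKG) are other publications' data and
#' are not bundled; users who have transcribed them can drop the files
#' under `inst/extdata/external/` (or pass explicit paths) and optionally
#' pin an MD5 checksum so that analyses are reproducible against a known
#' transcription.
#'
#' @param path File path.
#' @param dialect Matrix dialect, as in [read_contact_matrix()].
#' @param md5 Optional expected MD5 checksum of the file.
#' @param name Provenance tag.
#' @return A [contact_matrix].
#' @export
load_external_matrix <- function(path, dialect = "square_tsv",
                                 md5 = NULL, name = NULL) {
  if (!file.exists(path)) stop("external matrix file not found: ", path)
  if (!is.null(md5)) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, md5)) {
      stop(sprintf("checksum mismatch for %s: expected %s, got %s",
                   path, md5, got))
    }
  }
  read_contact_matrix(path, dialect = dialect, name = name)
}

#' Locate an externally supplied fixture, if present
#'
#' @param filename File name under the package's `extdata/external`
#'   directory.
#' @return The path, or `NA_character_` when the fixture has not been
#'   supplied.
#' @export
external_fixture_path <- function(filename) {
  p <- system.file("extdata", "external", filename, package = "potdecomp")
  if (nzchar(p) && file.exists(p)) p else NA_character_
}
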