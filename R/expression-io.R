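# Expression matrix / phenotype label input-output and train/test splitting.
#
# The canonical in-memory representation is a plain numeric matrix with
# probes as rows and samples as columns (the GEO series-matrix convention),
# with unique rownames (probe IDs) and colnames (sample IDs).  Samples are
# always addressed by ID, never by position.  Values are assumed to be
# already log2-transformed and normalized; no normalization is performed
# here.

#' Class coding used throughout the package
#'
#' Cases (disease samples) are coded `-1` and controls `+1`, matching the
#' sign convention of the SVM decision function: a negative decision score
#' predicts the case class.
#'
#' @format A named integer vector with entries `case = -1`, `control = +1`.
#' @export
CLASS_CODES <- c(case = -1L, control = +1L)

#' Construct and validate an expression matrix
#'
#' @param values Numeric matrix, probes as rows, samples as columns,
#'   log2-scale intensities.
#' @param probe_ids,sample_ids Optional character vectors overriding the
#'   dimnames of `values`.
#' @return The validated numeric matrix with dimnames set.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  rownames(values) <- probe_ids
  colnames(values) <- sample_ids
  validate_expression_matrix(values)
}

#' @rdname expression_matrix
#' @param x Object to validate.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must have probe rownames and sample colnames",
         call. = FALSE)
  }
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup)) {
    stop("duplicated probe ID(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup)) {
    stop("duplicated sample ID(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at probe '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]), call. = FALSE)
  }
  x
}

#' Read a tab-separated expression matrix
#'
#' The file must have a header row of sample IDs and a first column of probe
#' IDs (a leading header cell such as `ID_REF` is tolerated).  Matrices
#' stored samples-as-rows are transposed into the canonical probes-as-rows
#' orientation.
#'
#' @param path Path to a tab-separated text file.
#' @param orientation `"probes_as_rows"` (default) or `"samples_as_rows"`,
#'   describing the file layout.
#' @return A numeric matrix, probes as rows (see [expression_matrix()]).
#' @export
read_expression <- function(path,
                            orientation = c("probes_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file needs a header and at least one data row",
                               call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  body <- cells[-1L]
  widths <- lengths(body)
  ncol_body <- widths[1L]
  if (any(widths != ncol_body)) {
    bad <- which(widths != ncol_body)[1L]
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 bad + 1L, ncol_body, widths[bad]), call. = FALSE)
  }
  # header may or may not carry a cell above the ID column
  col_ids <- if (length(header) == ncol_body) header[-1L]
             else if (length(header) == ncol_body - 1L) header
             else stop(sprintf("header has %d fields but data rows have %d",
                               length(header), ncol_body), call. = FALSE)
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = ncol_body - 1L)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite value '%s' at data row %d, column %d",
                   body[[i]][bad[1L] + 1L], i, bad[1L] + 1L), call. = FALSE)
    }
    vals[i, ] <- v
  }
  rownames(vals) <- row_ids
  colnames(vals) <- col_ids
  if (orientation == "samples_as_rows") vals <- t(vals)
  validate_expression_matrix(vals)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are serialized at full double precision so that a write/read round
#' trip reproduces them bit-exactly.
#'
#' @param x Expression matrix (probes as rows).
#' @param path Output path.
#' @param id_header Header cell written above the probe-ID column.
#' @export
write_expression <- function(x, path, id_header = "ID_REF") {
  x <- validate_expression_matrix(x)
  header <- paste(c(id_header, colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a two-column sample-label table
#'
#' Each row pairs a sample ID with a class string.  Case samples are coded
#' `-1` and controls `+1` (see [CLASS_CODES]).
#'
#' @param path Path to a tab-separated two-column file (no header by
#'   default).
#' @param case_label,control_label Class strings denoting cases and
#'   controls.
#' @param header Whether the file carries a header row to skip.
#' @return A named integer vector of `-1`/`+1` labels, names = sample IDs.
#' @export
read_labels <- function(path, case_label = "psoriasis",
                        control_label = "control", header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (header) lines <- lines[-1L]
  if (!length(lines)) stop("label file is empty", call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 2L)) {
    bad <- which(lengths(cells) != 2L)[1L]
    stop(sprintf("label row %d does not have exactly 2 fields", bad),
         call. = FALSE)
  }
  ids <- vapply(cells, `[[`, character(1L), 1L)
  cls <- vapply(cells, `[[`, character(1L), 2L)
  phenotype_labels(ids, cls, case_label, control_label)
}

#' Build phenotype labels from sample IDs and class strings
#'
#' @param sample_ids Character vector of sample IDs (unique).
#' @param class Character vector of class strings, same length.
#' @param case_label,control_label The two admissible class strings.
#' @return Named integer vector, case -> -1, control -> +1.
#' @export
phenotype_labels <- function(sample_ids, class, case_label = "psoriasis",
                             control_label = "control") {
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    stop("duplicated sample ID(s) in labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(class), c(case_label, control_label))
  if (length(unknown)) {
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         "; expected '", case_label, "' or '", control_label, "'",
         call. = FALSE)
  }
  y <- ifelse(class == case_label, CLASS_CODES[["case"]],
              CLASS_CODES[["control"]])
  names(y) <- sample_ids
  y
}

#' Write labels as a two-column TSV
#'
#' @param labels Named `-1`/`+1` vector.
#' @param path Output path.
#' @param case_label,control_label Class strings to write.
#' @export
write_labels <- function(labels, path, case_label = "psoriasis",
                         control_label = "control") {
  cls <- ifelse(labels == CLASS_CODES[["case"]], case_label, control_label)
  writeLines(paste(names(labels), cls, sep = "\t"), path)
  invisible(path)
}

# check labels cover the matrix and both classes are present
check_labels <- function(x, labels) {
  missing <- setdiff(colnames(x), names(labels))
  if (length(missing)) {
    stop("sample(s) without a label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- labels[colnames(x)]
  if (!all(y %in% c(-1L, 1L))) stop("labels must be coded -1/+1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  y
}

#' Stratified train/test split of an expression dataset
#'
#' Samples are partitioned into a training and a test set.  With
#' `stratified = TRUE` (default) the per-class training counts are the
#' largest-remainder apportionment of `n_train`, so the training class
#' proportions differ from the overall proportions by less than one sample.
#' The split is deterministic for a fixed seed.
#'
#' @param x Expression matrix (probes x samples).
#' @param labels Named `-1`/`+1` vector covering all samples of `x`.
#' @param n_train Number of training samples (the remainder is the test
#'   set).
#' @param seed Integer seed controlling the random assignment.
#' @param stratified Stratify by class (default `TRUE`).
#' @return A list with elements `train` and `test`, each a list holding the
#'   column-subset matrix `x` and label vector `y`.
#' @export
split_train_test <- function(x, labels, n_train, seed, stratified = TRUE) {
  x <- validate_expression_matrix(x)
  y <- check_labels(x, labels)
  n <- ncol(x)
  n_train <- assert_count(n_train, "n_train", min = 1L)
  if (n_train >= n) stop("'n_train' must be smaller than the sample count",
                         call. = FALSE)
  train_ids <- with_seed(seed, {
    if (stratified) {
      classes <- sort(unique(y))
      quota <- n_train * tabulate(match(y, classes)) / n
      take <- floor(quota)
      rem <- n_train - sum(take)
      if (rem > 0) {
        extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
        take[extra] <- take[extra] + 1L
      }
      unlist(lapply(seq_along(classes), function(i) {
        ids <- names(y)[y == classes[i]]
        sample(ids, take[i])
      }), use.names = FALSE)
    } else {
      sample(names(y), n_train)
    }
  })
  test_ids <- setdiff(names(y), train_ids)
  for (part in list(train_ids, test_ids)) {
    counts <- table(factor(y[part], levels = c(-1L, 1L)))
    if (any(counts < 2L)) {
      stop("split leaves fewer than 2 samples of a class on one side; ",
           "choose a different n_train", call. = FALSE)
    }
  }
  list(
    train = list(x = x[, train_ids, drop = FALSE], y = y[train_ids]),
    test  = list(x = x[, test_ids,  drop = FALSE], y = y[test_ids])
  )
}
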