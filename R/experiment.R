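#' Construct a profile experiment
#'
#' A `ProfileExperiment` holds a proteins-by-fractions matrix of relative
#' quantitation values ("occupancy profiles"), per-protein feature metadata,
#' and the name of the metadata column carrying sub-cellular marker labels.
#' Missing quantitation values are stored as `NA` and are never silently
#' imputed: the distance engine handles them explicitly (see
#' [profile_distance()]) and visualisation paths use [zero_imputed_view()].
#'
#' @param values numeric matrix, proteins in rows (unique, non-empty
#'   rownames), fractions in columns (>= 2, named). Entries must be finite
#'   or `NA`.
#' @param fdata optional `data.frame` of per-protein metadata, with rownames
#'   matching `values`. Defaults to an empty frame.
#' @param marker_column name of the `fdata` column holding marker labels,
#'   or `NULL` if the experiment carries no annotation.
#' @param unknown_label label reserved for unannotated proteins
#'   (default `"unknown"`).
#'
#' @return an object of class `ProfileExperiment` with elements `values`,
#'   `fdata`, `marker_column`, `unknown_label`.
#' @examples
#' m <- matrix(runif(12), 3, 4,
#'             dimnames = list(c("P1", "P2", "P3"), paste0("F", 1:4)))
#' exp <- profile_experiment(m)
#' dim(exp)
#' @export
profile_experiment <- function(values, fdata = NULL, marker_column = NULL,
                               unknown_label = "unknown") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L) stop("need at least one protein")
  if (ncol(values) < 2L) stop("need at least two fractions")
  ids <- rownames(values)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("'values' must have non-empty rownames (protein identifiers)")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate protein identifiers: ", paste(dup, collapse = ", "))
  }
  if (is.null(colnames(values)))
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  bad <- is.infinite(values) | is.nan(values)
  if (any(bad, na.rm = TRUE))
    stop("non-finite (infinite/NaN) quantitation values are not allowed")
  if (is.null(fdata)) {
    fdata <- data.frame(row.names = ids)
  } else {
    if (!is.data.frame(fdata)) stop("'fdata' must be a data.frame")
    if (!setequal(rownames(fdata), ids))
      stop("'fdata' rownames must match protein identifiers")
    fdata <- fdata[ids, , drop = FALSE]
  }
  if (!is.null(marker_column) && !marker_column %in% names(fdata))
    stop("marker column '", marker_column, "' not found in feature metadata")
  structure(list(values = values, fdata = fdata,
                 marker_column = marker_column,
                 unknown_label = unknown_label),
            class = "ProfileExperiment")
}

#' @export
dim.ProfileExperiment <- function(x) dim(x$values)

#' @export
dimnames.ProfileExperiment <- function(x) dimnames(x$values)

#' Protein and fraction identifiers
#'
#' @param exp a `ProfileExperiment`.
#' @return character vector of identifiers.
#' @export
protein_ids <- function(exp) rownames(exp$values)

#' @rdname protein_ids
#' @export
fraction_ids <- function(exp) colnames(exp$values)

#' @export
print.ProfileExperiment <- function(x, ...) {
  cat(sprintf("ProfileExperiment: %d proteins x %d fractions\n",
              nrow(x$values), ncol(x$values)))
  mf <- missing_fraction(x)
  if (mf > 0)
    cat(sprintf("  missing values: %.1f%%\n", 100 * mf))
  if (!is.null(x$marker_column)) {
    mk <- markers(x)
    tab <- marker_table(mk)
    cat(sprintf("  markers ('%s'): %d clusters, %d marker proteins\n",
                x$marker_column, length(tab), sum(tab)))
  }
  invisible(x)
}

#' Subset a profile experiment by protein and/or fraction
#'
#' @param x a `ProfileExperiment`.
#' @param i protein index (ids, logical or integer).
#' @param j fraction index.
#' @param ... ignored.
#' @param drop ignored; the result is always a `ProfileExperiment`.
#' @export
`[.ProfileExperiment` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  profile_experiment(x$values[i, j, drop = FALSE],
                     fdata = x$fdata[i, , drop = FALSE],
                     marker_column = x$marker_column,
                     unknown_label = x$unknown_label)
}

#' Extract the marker annotation of an experiment
#'
#' Returns the per-protein sub-cellular labels as a `MarkerAnnotation`:
#' a named character vector (names are protein identifiers) whose
#' `unknown_label` attribute names the sentinel used for unannotated
#' proteins. Empty and `NA` labels are mapped to the unknown label.
#'
#' @param exp a `ProfileExperiment` with a marker column.
#' @param marker_column override the experiment's marker column.
#' @return a `MarkerAnnotation`.
#' @export
markers <- function(exp, marker_column = NULL) {
  col <- if (is.null(marker_column)) exp$marker_column else marker_column
  if (is.null(col))
    stop("experiment carries no marker column")
  if (!col %in% names(exp$fdata))
    stop("marker column '", col, "' not found in feature metadata")
  lab <- as.character(exp$fdata[[col]])
  names(lab) <- protein_ids(exp)
  marker_annotation(lab, unknown_label = exp$unknown_label)
}

#' Construct a marker annotation
#'
#' @param assignments named character vector mapping protein identifiers to
#'   cluster labels; `NA` or empty labels become `unknown_label`.
#' @param unknown_label sentinel for unannotated proteins.
#' @return a `MarkerAnnotation` (named character vector).
#' @export
marker_annotation <- function(assignments, unknown_label = "unknown") {
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("'assignments' must be named by protein identifiers")
  lab <- as.character(assignments)
  lab[is.na(lab) | !nzchar(lab)] <- unknown_label
  names(lab) <- names(assignments)
  structure(lab, unknown_label = unknown_label, class = "MarkerAnnotation")
}

#' @export
print.MarkerAnnotation <- function(x, ...) {
  tab <- marker_table(x)
  cat(sprintf("MarkerAnnotation: %d clusters, %d markers, %d unknown\n",
              length(tab), sum(tab), sum(unclass(x) == unknown_label(x))))
  if (length(tab)) print(tab)
  invisible(x)
}

#' @export
`[.MarkerAnnotation` <- function(x, i, ...) {
  marker_annotation(unclass(x)[i], unknown_label = unknown_label(x))
}

#' Cluster labels, marker counts and the unknown sentinel
#'
#' `cluster_labels()` returns the distinct non-unknown labels,
#' `marker_table()` the per-cluster marker counts, and `unknown_label()`
#' the sentinel label.
#'
#' @param mk a `MarkerAnnotation`.
#' @return see the individual descriptions.
#' @export
cluster_labels <- function(mk) {
  lab <- unique(unclass(mk))
  sort(lab[lab != unknown_label(mk)])
}

#' @rdname cluster_labels
#' @export
marker_table <- function(mk) {
  lab <- unclass(mk)
  lab <- lab[lab != unknown_label(mk)]
  table(factor(lab, levels = cluster_labels(mk)))
}

#' @rdname cluster_labels
#' @export
unknown_label <- function(mk) attr(mk, "unknown_label")

#' Attach a marker annotation to an experiment
#'
#' Writes the annotation into the experiment's feature metadata (column
#' `marker_column`, default `"markers"`), replacing any previous labels.
#' Proteins absent from `mk` become unknown.
#'
#' @param exp a `ProfileExperiment`.
#' @param mk a `MarkerAnnotation`.
#' @param marker_column metadata column to (over)write.
#' @return the annotated `ProfileExperiment`.
#' @export
set_markers <- function(exp, mk, marker_column = "markers") {
  stopifnot(inherits(mk, "MarkerAnnotation"))
  lab <- rep(unknown_label(mk), nrow(exp$values))
  names(lab) <- protein_ids(exp)
  hit <- intersect(names(mk), names(lab))
  lab[hit] <- unclass(mk)[hit]
  exp$fdata[[marker_column]] <- lab
  exp$marker_column <- marker_column
  exp$unknown_label <- unknown_label(mk)
  exp
}

## missing-value tokens recognised on input (case-insensitive)
.na_tokens <- c("", "NA", "NAN")

#' Read a profile experiment from delimited text
#'
#' Expects a header row. One column holds protein identifiers (`id_column`;
#' by default the first column). All columns that parse as numeric become
#' the fraction matrix, in file order; the remaining columns become feature
#' metadata. Empty cells, `"NA"` and `"NaN"` (case-insensitive) in fraction
#' columns are read as missing and retained as `NA` -- they are *not*
#' imputed. Empty or missing marker cells map to `unknown_label`.
#'
#' @param path input file.
#' @param marker_column name of the marker column, or `NULL` if none.
#' @param delimiter field separator, `"\t"` by default (use `","` for CSV).
#' @param id_column name of the identifier column; default first column.
#' @param unknown_label sentinel for unannotated proteins.
#' @param na_tokens strings treated as missing in fraction columns.
#' @return a `ProfileExperiment` (annotated when `marker_column` is given).
#' @seealso [write_experiment()] for the inverse operation.
#' @export
read_experiment <- function(path, marker_column = NULL, delimiter = "\t",
                            id_column = NULL, unknown_label = "unknown",
                            na_tokens = .na_tokens) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          na.strings = character(0),
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 3L) stop("need an id column and at least two data columns")
  if (is.null(id_column)) id_column <- names(df)[1L]
  if (!id_column %in% names(df))
    stop("id column '", id_column, "' not found")
  ids <- df[[id_column]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate protein identifiers: ", paste(dup, collapse = ", "))
  }
  rest <- df[setdiff(names(df), id_column)]
  is_na_tok <- function(x)
    is.na(x) | toupper(trimws(x)) %in% toupper(na_tokens)
  ## a column is numeric if every non-missing cell parses as a number
  numeric_col <- vapply(rest, function(x) {
    x <- x[!is_na_tok(x)]
    length(x) == 0L ||
      !anyNA(suppressWarnings(as.numeric(x)))
  }, logical(1))
  if (!is.null(marker_column)) {
    if (!marker_column %in% names(rest))
      stop("marker column '", marker_column, "' not found")
    numeric_col[marker_column] <- FALSE
  }
  frac_cols <- names(rest)[numeric_col]
  if (length(frac_cols) < 2L)
    stop("fewer than two numeric fraction columns found")
  vals <- vapply(rest[frac_cols], function(x) {
    x[is_na_tok(x)] <- NA_character_
    as.numeric(x)
  }, numeric(length(ids)))
  vals <- matrix(vals, nrow = length(ids),
                 dimnames = list(ids, frac_cols))
  meta_cols <- setdiff(names(rest), frac_cols)
  fdata <- if (length(meta_cols))
    data.frame(rest[meta_cols], row.names = ids, check.names = FALSE)
  else data.frame(row.names = ids)
  if (!is.null(marker_column)) {
    m <- fdata[[marker_column]]
    m[is_na_tok(m)] <- unknown_label
    fdata[[marker_column]] <- m
  }
  profile_experiment(vals, fdata = fdata, marker_column = marker_column,
                     unknown_label = unknown_label)
}

#' Write a profile experiment to delimited text
#'
#' Writes an `id` column, the fraction columns, then any feature metadata.
#' Missing values are written as empty cells so that
#' [read_experiment()] round-trips matrices, labels and missingness.
#'
#' @param exp a `ProfileExperiment`.
#' @param path output file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(exp, path, delimiter = "\t") {
  ## 17 significant digits so doubles survive the text round trip exactly
  vals <- apply(exp$values, 2L, function(x)
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
  vals <- as.data.frame(vals, stringsAsFactors = FALSE)
  df <- data.frame(id = protein_ids(exp), vals, exp$fdata,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Combine replicated experiments along fractions
#'
#' Restricts each replicate to the shared protein identifiers and
#' concatenates the fraction columns in input order, disambiguating
#' fraction names with a `.repN` suffix when needed. Feature metadata is
#' taken from the first experiment. Combining replicates typically
#' improves sub-cellular resolution because each protein is described by a
#' longer occupancy profile.
#'
#' @param ... two or more `ProfileExperiment` objects (or one list).
#' @return the combined `ProfileExperiment`.
#' @export
combine_replicates <- function(...) {
  exps <- list(...)
  if (length(exps) == 1L && is.list(exps[[1L]]) &&
      !inherits(exps[[1L]], "ProfileExperiment"))
    exps <- exps[[1L]]
  if (length(exps) < 2L) stop("need at least two experiments")
  stopifnot(all(vapply(exps, inherits, logical(1), "ProfileExperiment")))
  ids <- Reduce(intersect, lapply(exps, protein_ids))
  if (length(ids) == 0L)
    stop("no shared protein identifiers across replicates")
  mats <- lapply(seq_along(exps), function(i) {
    m <- exps[[i]]$values[ids, , drop = FALSE]
    colnames(m) <- paste0(colnames(m), ".rep", i)
    m
  })
  vals <- do.call(cbind, mats)
  ## suffixing makes collisions impossible unless inputs already carried
  ## the same suffixed name
  if (anyDuplicated(colnames(vals)))
    stop("duplicate fraction identifiers after replicate suffixing")
  profile_experiment(vals,
                     fdata = exps[[1L]]$fdata[ids, , drop = FALSE],
                     marker_column = exps[[1L]]$marker_column,
                     unknown_label = exps[[1L]]$unknown_label)
}

#' Zero-imputed copy for visualisation
#'
#' Returns a copy of the experiment with every missing entry replaced by
#' zero. This view is used only by dimensionality reduction and plotting;
#' distance computations always run on the raw matrix, where missing
#' values are handled by the pairwise-complete rule of
#' [profile_distance()].
#'
#' @param exp a `ProfileExperiment`.
#' @return a `ProfileExperiment` without missing values.
#' @export
zero_imputed_view <- function(exp) {
  v <- exp$values
  all_na <- rowSums(!is.na(v)) == 0L
  if (any(all_na))
    message(sum(all_na), " all-missing profile(s) became all-zero rows")
  v[is.na(v)] <- 0
  exp$values <- v
  exp
}

#' Proportion of missing quantitation values
#'
#' @param exp a `ProfileExperiment`.
#' @return proportion in `[0, 1]` of `NA` entries in the profile matrix.
#' @export
missing_fraction <- function(exp) {
  mean(is.na(exp$values))
}
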