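#' Samples-by-categories percentage matrix
#'
#' The result container of the package: per-sample percentage abundances per
#' category, where a category is a phylum, order, family, EPH group, EPT
#' group, or — for matrices read straight from a wide CSV — whatever the
#' file's columns are.  For matrices produced by [eco_plant()] each sample
#' row sums to 100 (exactly, before display rounding) and the `"Uncertain"`
#' sink, when present, is always the last category.
#'
#' @param values Numeric matrix, samples in rows, categories in columns,
#'   with complete dimnames.  All values must be finite and non-negative.
#' @param mode One of `"phylum"`, `"order"`, `"family"`, `"eph"`, `"ept"`,
#'   or `"raw"` for user-supplied wide matrices that are plotted as given.
#' @param depth Optional numeric vector of stratigraphic positions, named by
#'   sample.
#' @return An object of class `"abundance_matrix"`.
#' @seealso [eco_plant()], [read_wide_matrix()], [write_matrix()],
#'   [pollen_diagram()]
#' @export
abundance_matrix <- function(values, mode = "raw", depth = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (length(values) && (is.null(rownames(values)) || is.null(colnames(values))))
    ep_validation_error("matrix needs sample and category dimnames")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    # degenerate 0-row/0-column matrices silently lose their dimnames
    dimnames(values) <- list(rownames(values) %||% character(0),
                             colnames(values) %||% character(0))
  if (any(!is.finite(values)) || any(values < 0))
    ep_validation_error("matrix values must be finite and non-negative")
  mode <- tolower(mode)
  if (!mode %in% c(ANALYSIS_MODES, "raw"))
    ep_validation_error(sprintf("unknown matrix mode '%s'", mode))
  if (!is.null(depth)) depth <- depth[rownames(values)]
  structure(list(values = values, mode = mode, depth = depth),
            class = "abundance_matrix")
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Sample and category labels of an abundance matrix
#'
#' @param x An `"abundance_matrix"`.
#' @return Character vector of labels, in matrix order.
#' @export
samples <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  rownames(x$values)
}

#' @rdname samples
#' @export
categories <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  colnames(x$values)
}

#' @export
print.abundance_matrix <- function(x, decimals = 1L, ...) {
  cat(sprintf("Abundance matrix (%s mode): %d sample%s x %d categories\n",
              x$mode, nrow(x$values), if (nrow(x$values) == 1) "" else "s",
              ncol(x$values)))
  disp <- t(x$values)  # field convention: categories as rows
  disp[] <- round_half_up(disp, decimals)
  print(disp, ...)
  invisible(x)
}

#' @export
summary.abundance_matrix <- function(object, ...) {
  v <- object$values
  data.frame(sample = rownames(v),
             total = rowSums(v),
             n_categories = rowSums(v > 0),
             uncertain = if (UNCERTAIN %in% colnames(v)) v[, UNCERTAIN] else 0,
             row.names = NULL)
}

#' @export
as.data.frame.abundance_matrix <- function(x, ...) {
  v <- x$values
  data.frame(sample = rep(rownames(v), times = ncol(v)),
             category = rep(colnames(v), each = nrow(v)),
             percent = as.vector(v),
             stringsAsFactors = FALSE)
}

#' Read a wide samples-by-categories CSV (draw-curve dialect)
#'
#' Reads the second upload dialect: the first column must be named `Sample`
#' (any letter case) and every remaining column holds percentage abundances
#' for one category.  Values are taken exactly as given — no renormalisation,
#' no reference lookup — which is what lets users plot hand-combined or
#' hand-edited result tables.
#'
#' @param source Path to a CSV file (or a connection).
#' @return An `"abundance_matrix"` with `mode = "raw"`.
#' @examples
#' m <- read_wide_matrix(ep_example_path("wide"))
#' dim(m)
#' @export
read_wide_matrix <- function(source) {
  df <- read_csv_chars(source)
  if (ncol(df) < 1L || tolower(names(df)[1L]) != "sample")
    ep_format_error(sprintf(
      "first column of a wide matrix must be 'Sample', found '%s'",
      if (ncol(df)) names(df)[1L] else ""))
  if (ncol(df) < 2L)
    ep_format_error("wide matrix has no category columns")
  cats <- names(df)[-1L]
  if (anyDuplicated(cats))
    ep_format_error(sprintf("duplicate category column '%s'",
                            cats[duplicated(cats)][1L]))
  smp <- df[[1L]]
  if (any(!nzchar(smp)))
    ep_validation_error(sprintf("row %d: empty sample label",
                                which(!nzchar(smp))[1L]))
  if (anyDuplicated(smp))
    ep_validation_error(sprintf("duplicate sample '%s'",
                                smp[duplicated(smp)][1L]))
  vals <- matrix(NA_real_, nrow(df), length(cats),
                 dimnames = list(smp, cats))
  for (j in seq_along(cats)) {
    v <- parse_number(df[[j + 1L]])
    if (anyNA(v))
      ep_validation_error(sprintf(
        "row %d, column '%s': value '%s' is not numeric",
        which(is.na(v))[1L], cats[j], df[[j + 1L]][which(is.na(v))[1L]]))
    if (any(v < 0))
      ep_validation_error(sprintf(
        "row %d, column '%s': negative abundance", which(v < 0)[1L], cats[j]))
    vals[, j] <- v
  }
  abundance_matrix(vals, mode = "raw")
}

#' Write an abundance matrix to CSV
#'
#' Two layouts are offered.  `"samples_as_columns"` mirrors the result-table
#' convention of the field: the first column holds category names, one
#' further column per sample, with the `"Uncertain"` row last — the shape in
#' which grouped percentage tables are printed and passed to statistics
#' packages.  `"tidy"` emits long-format (sample, category, percent) triples
#' for downstream tools that prefer one observation per row.
#'
#' Rounding (half away from zero, `decimals` places, trailing zeros dropped
#' so `25.0` prints as `25`) applies to the written text only; the matrix
#' itself always carries full-precision values.
#'
#' @param m An `"abundance_matrix"`.
#' @param path Output file path, or `NULL` to return the lines.
#' @param layout `"samples_as_columns"` (default) or `"tidy"`.
#' @param decimals Non-negative integer; display precision (default 1).
#' @return Character vector of CSV lines, invisibly (also written to `path`
#'   when given).
#' @examples
#' m <- eco_plant(ep_example("assemblage"), "order")
#' cat(head(write_matrix(m), 4), sep = "\n")
#' @export
write_matrix <- function(m, path = NULL,
                         layout = c("samples_as_columns", "tidy"),
                         decimals = 1L) {
  stopifnot(inherits(m, "abundance_matrix"))
  layout <- match.arg(layout)
  if (!is.numeric(decimals) || length(decimals) != 1L || decimals < 0)
    ep_validation_error("`decimals` must be a non-negative integer")
  v <- m$values
  lines <- if (layout == "samples_as_columns") {
    c(csv_line(c("Sample", rownames(v))),
      vapply(seq_len(ncol(v)), function(j) {
        csv_line(c(colnames(v)[j], fmt_percent(v[, j], decimals)))
      }, character(1)))
  } else {
    c(csv_line(c("Sample", "Category", "Percent")),
      unlist(lapply(seq_len(nrow(v)), function(i) {
        vapply(seq_len(ncol(v)), function(j) {
          csv_line(c(rownames(v)[i], colnames(v)[j],
                     fmt_percent(v[i, j], decimals)))
        }, character(1))
      })))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
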