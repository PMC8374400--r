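#' Construct a sporomorph assemblage table
#'
#' An assemblage is an ordered long-format table of observations: one row
#' per (sample, genus) count or percentage.  Abundances may be raw grain
#' counts or percentages — the downstream percentage calculation renormalises
#' per sample, so the two are equivalent.  Duplicate (sample, genus) rows are
#' legal and are summed during aggregation.
#'
#' @param sample Character vector of sample labels.
#' @param genus Character vector of sporomorph genus names.
#' @param abundance Numeric vector of non-negative counts or percentages.
#' @param depth Optional numeric stratigraphic position per row (units as
#'   supplied); carried through for diagram ordering, never used in
#'   aggregation.
#' @return A data frame of class `"assemblage"` with columns `sample`,
#'   `genus`, `abundance` and (if given) `depth`, preserving input order.
#' @examples
#' assemblage(sample = c("S1", "S1"), genus = c("Cyathidites", "Calamospora"),
#'            abundance = c(12, 3))
#' @export
assemblage <- function(sample, genus, abundance, depth = NULL) {
  df <- data.frame(sample = as.character(sample),
                   genus = as.character(genus),
                   abundance = as.numeric(abundance),
                   stringsAsFactors = FALSE)
  if (!is.null(depth)) df$depth <- as.numeric(depth)
  validate_assemblage(df)
}

validate_assemblage <- function(df) {
  df$sample <- trimws(df$sample)
  df$genus <- trimws(df$genus)
  if (any(!nzchar(df$sample)))
    ep_validation_error(sprintf("row %d: empty sample label",
                                which(!nzchar(df$sample))[1L]))
  if (any(!nzchar(df$genus)))
    ep_validation_error(sprintf("row %d: empty genus name",
                                which(!nzchar(df$genus))[1L]))
  bad <- !is.finite(df$abundance) | df$abundance < 0
  if (any(bad))
    ep_validation_error(sprintf(
      "row %d: abundance must be a finite non-negative number",
      which(bad)[1L]))
  tot <- tapply(df$abundance, df$sample, sum)
  if (any(tot <= 0))
    ep_validation_error(sprintf(
      "sample '%s' has zero total abundance", names(tot)[tot <= 0][1L]))
  rownames(df) <- NULL
  attr(df, "sample_order") <- unique(df$sample)
  class(df) <- c("assemblage", "data.frame")
  df
}

#' Coerce a data frame to an assemblage
#'
#' Accepts any data frame with (case-insensitive) `Sample`, `Genus` and
#' `Abundance` columns, plus optional `Depth`, and validates it like
#' [read_assemblage()].  Assemblage objects pass through untouched.
#'
#' @param x A data frame or `"assemblage"`.
#' @return An `"assemblage"`.
#' @export
as_assemblage <- function(x) {
  if (inherits(x, "assemblage")) return(x)
  if (!is.data.frame(x))
    ep_validation_error("expected an assemblage or a data frame")
  si <- find_column(x, "Sample", what = "assemblage")
  gi <- find_column(x, "Genus", what = "assemblage")
  ai <- find_column(x, "Abundance", what = "assemblage")
  di <- find_column(x, "Depth", required = FALSE)
  assemblage(x[[si]], x[[gi]], x[[ai]],
             depth = if (is.null(di)) NULL else x[[di]])
}

#' Read a long-format assemblage CSV
#'
#' Reads the upload dialect used by all analysis modes: one row per
#' observation with columns `Sample`, `Genus`, `Abundance` and optionally
#' `Depth`.  Header names match in any letter case; extra columns are
#' ignored; a UTF-8 BOM is tolerated.  Abundance cells must be plain
#' non-negative decimal numbers (no thousands separators, no blanks); a bad
#' cell is reported with its data-row number.  Every sample must have a
#' positive total abundance.
#'
#' @param source Path to a CSV file (or a connection).
#' @return An `"assemblage"` data frame; see [assemblage()].
#' @examples
#' asm <- read_assemblage(ep_example_path("assemblage"))
#' head(asm)
#' tapply(asm$abundance, asm$sample, sum)
#' @export
read_assemblage <- function(source) {
  df <- read_csv_chars(source)
  si <- find_column(df, "Sample", what = "assemblage file")
  gi <- find_column(df, "Genus", what = "assemblage file")
  ai <- find_column(df, "Abundance", what = "assemblage file")
  di <- find_column(df, "Depth", required = FALSE)
  ab <- parse_number(df[[ai]])
  if (anyNA(ab))
    ep_validation_error(sprintf(
      "row %d: abundance '%s' is not a plain decimal number",
      which(is.na(ab))[1L], df[[ai]][which(is.na(ab))[1L]]))
  if (any(ab < 0))
    ep_validation_error(sprintf(
      "row %d: abundance %s is negative",
      which(ab < 0)[1L], df[[ai]][which(ab < 0)[1L]]))
  depth <- NULL
  if (!is.null(di)) {
    depth <- parse_number(df[[di]])
    depth[!nzchar(df[[di]])] <- NA_real_  # blank depth is allowed
    bad <- is.na(depth) & nzchar(df[[di]])
    if (any(bad))
      ep_validation_error(sprintf(
        "row %d: depth '%s' is not numeric",
        which(bad)[1L], df[[di]][which(bad)[1L]]))
  }
  assemblage(df[[si]], df[[gi]], ab, depth = depth)
}

#' Write an assemblage back to CSV
#'
#' Emits the same long-format dialect [read_assemblage()] reads, so that a
#' write/read round trip is the identity on (sample, genus, abundance)
#' triples.
#'
#' @param x An `"assemblage"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assemblage <- function(x, path) {
  x <- as_assemblage(x)
  has_depth <- "depth" %in% names(x)
  header <- c(if (has_depth) "Depth", "Sample", "Genus", "Abundance")
  num <- function(v) ifelse(is.na(v), "", format(v, digits = 15,
                                                 scientific = FALSE,
                                                 trim = TRUE))
  rows <- vapply(seq_len(nrow(x)), function(i) {
    csv_line(c(if (has_depth) num(x$depth[i]),
               x$sample[i], x$genus[i], num(x$abundance[i])))
  }, character(1))
  writeLines(c(csv_line(header), rows), path)
  invisible(path)
}

#' @export
as.data.frame.assemblage <- function(x, ...) {
  attr(x, "sample_order") <- NULL
  class(x) <- "data.frame"
  x
}

# Subsets are plain data frames: the sample-order attribute no longer
# matches, so coercing back through as_assemblage() revalidates.
#' @export
`[.assemblage` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- "data.frame"
    attr(out, "sample_order") <- NULL
  }
  out
}

#' @export
print.assemblage <- function(x, ...) {
  n_s <- length(attr(x, "sample_order"))
  cat(sprintf("Sporomorph assemblage: %d observations, %d sample%s, %d genera\n",
              nrow(x), n_s, if (n_s == 1) "" else "s",
              length(unique(genus_key(x$genus)))))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.assemblage <- function(object, ...) {
  so <- attr(object, "sample_order")
  tot <- vapply(so, function(s) sum(object$abundance[object$sample == s]),
                numeric(1))
  ng <- vapply(so, function(s)
    length(unique(genus_key(object$genus[object$sample == s]))), numeric(1))
  data.frame(sample = so, n_taxa = as.integer(ng), total_abundance = tot,
             row.names = NULL)
}
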