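#' Annotate assemblage rows with their category
#'
#' Joins the assemblage to the reference set on the shared genus key: each
#' observation gains the category its genus resolves to under `mode` (or
#' `"Uncertain"`).  Row order is preserved; nothing is grouped yet.
#'
#' @param assemblage An [assemblage] (or coercible data frame).
#' @param mode Analysis mode; see [lookup_category()].
#' @param refs A `"reference_set"`.
#' @return The assemblage data frame with an added `category` column.
#' @examples
#' head(annotate(ep_example("assemblage"), "order"))
#' @export
annotate <- function(assemblage, mode, refs = default_reference()) {
  asm <- as_assemblage(assemblage)
  out <- as.data.frame(asm)
  out$category <- lookup_category(asm$genus, mode, refs)
  attr(out, "sample_order") <- attr(asm, "sample_order")
  out
}

# --- exact-decimal percentage core -----------------------------------------
#
# Abundances originate as decimal text (counts or percentages from a CSV),
# so within one sample they are treated as exact decimals: each value is
# snapped to an integer numerator over a common power-of-ten denominator
# (up to 12 decimal places, 1e-9 relative snap tolerance), group and total
# sums are then exact integer sums, and each percentage is one correctly
# rounded division 100 * group / total.  Consequences: per-sample rows sum
# to 100 up to a final-addition ulp, and rescaling a whole sample by any
# decimal factor (counts vs. percent input) leaves every output bit
# unchanged, because the integer ratio is unchanged.  Values with no short
# decimal form fall back to plain double sums.
decimal_units <- function(x, max_places = 12L) {
  for (d in 0:max_places) {
    xd <- x * 10^d
    if (max(abs(xd)) > 2^52) break  # integer arithmetic no longer exact
    if (all(abs(xd - round(xd)) <= 1e-9 * pmax(1, abs(xd)))) return(round(xd))
  }
  NULL
}

percent_shares <- function(abundance, category, categories) {
  units <- decimal_units(abundance)
  if (is.null(units) || sum(units) > 2^53) units <- abundance  # double fallback
  total <- sum(units)
  group <- vapply(categories, function(cc) sum(units[category == cc]),
                  numeric(1))
  (100 * group) / total
}

#' Group annotated observations into a percentage matrix
#'
#' Sums abundance per (sample, category) and converts to percentages of the
#' sample's total uploaded abundance.  The `"Uncertain"` rows count in the
#' denominator: a sample half full of unlinkable sporomorphs shows its
#' linked categories at their true (diluted) share, with the dilution
#' visible as the Uncertain column.  Categories observed anywhere in the
#' data appear for every sample, as 0 where absent.
#'
#' @param annotated Data frame from [annotate()] (columns `sample`,
#'   `category`, `abundance`).
#' @param mode Analysis mode recorded on the result.
#' @param denominator `"all"` (default) divides by each sample's total
#'   including Uncertain rows; `"linked"` excludes them, giving percentages
#'   of the identifiable fraction only (the Uncertain column is then
#'   dropped).
#' @return An `"abundance_matrix"`, categories ordered alphabetically with
#'   `"Uncertain"` last.
#' @export
aggregate_percent <- function(annotated, mode = "raw",
                              denominator = c("all", "linked")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(annotated),
            all(c("sample", "category", "abundance") %in% names(annotated)))
  if (denominator == "linked") {
    keep <- annotated$category != UNCERTAIN
    if (!any(keep))
      ep_validation_error("no linked observations: nothing to normalise")
    annotated <- annotated[keep, , drop = FALSE]
  }
  smp <- attr(annotated, "sample_order") %||% unique(annotated$sample)
  cats <- unique(annotated$category)
  vals <- matrix(0, length(smp), length(cats), dimnames = list(smp, cats))
  for (s in smp) {
    rows <- annotated$sample == s
    tot <- sum(annotated$abundance[rows])
    if (!any(rows) || tot <= 0)
      ep_validation_error(sprintf(
        "sample '%s' has zero total abundance", s))
    vals[s, ] <- percent_shares(annotated$abundance[rows],
                                annotated$category[rows], cats)
  }
  depth <- NULL
  if ("depth" %in% names(annotated)) {
    depth <- vapply(smp, function(s)
      annotated$depth[annotated$sample == s][1L], numeric(1))
  }
  format_matrix(abundance_matrix(vals, mode = mode, depth = depth))
}

#' Put an abundance matrix in presentation order
#'
#' Sorts categories alphabetically (case-insensitive) with the
#' `"Uncertain"` sink forced last; samples stay in first-appearance order;
#' values are untouched.
#'
#' @param m An `"abundance_matrix"` (not `"raw"` mode matrices, whose column
#'   order belongs to the user).
#' @return The reordered matrix.
#' @export
format_matrix <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  cats <- colnames(m$values)
  unc <- cats == UNCERTAIN
  ord <- c(which(!unc)[order(tolower(cats[!unc]), method = "radix")],
           which(unc))
  m$values <- m$values[, ord, drop = FALSE]
  m
}

#' Eco-Plant / parent-plant percentage analysis of an assemblage
#'
#' The whole pipeline in one call: resolve every observation's genus to a
#' category under `mode` (parent-plant phylum, order or family through the
#' taxonomy table; EPH or EPT group through the ecogroup table), group by
#' (sample, category), and express group sums as percentages of each
#' sample's total abundance.  Genera with no known affinity fall into the
#' `"Uncertain"` category, which keeps the denominator honest: it is part of
#' the composition, merely uninformative.
#'
#' Because each sample is renormalised by its own total, raw grain counts
#' and percentage input give identical results, and the per-sample rows sum
#' to exactly 100.
#'
#' @param x An [assemblage], coercible data frame, or path to a long-format
#'   CSV.
#' @param mode `"phylum"`, `"order"`, `"family"`, `"eph"` or `"ept"`.
#' @param refs A `"reference_set"`; defaults to the bundled Mesozoic
#'   excerpt.
#' @param denominator See [aggregate_percent()].
#' @return An `"abundance_matrix"`; print it, [write_matrix()] it, or plot
#'   it with [pollen_diagram()].
#' @examples
#' m <- eco_plant(ep_example("assemblage"), "order")
#' m
#' eco_plant(ep_example("assemblage"), "eph")
#' @export
eco_plant <- function(x, mode, refs = default_reference(),
                      denominator = c("all", "linked")) {
  if (is.character(x) && length(x) == 1L) x <- read_assemblage(x)
  mode <- match_mode(mode)
  ann <- annotate(x, mode, refs)
  aggregate_percent(ann, mode = mode, denominator = match.arg(denominator))
}
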