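#' Read a genus-to-parent-plant taxonomy table
#'
#' Reads a comma-separated taxonomy reference in which each row assigns one
#' sporomorph genus to the taxonomic ranks of its most likely parent plant
#' (Kingdom, Phylum, Class, Order, Family).  The header is matched
#' case-insensitively and a UTF-8 byte-order mark is tolerated.  Empty rank
#' cells are stored as missing: a genus whose family is unknown is linked at
#' order level only, and a family-mode lookup on it resolves to the
#' `"Uncertain"` sink rather than borrowing a coarser rank.
#'
#' @param source Path to a CSV file (or a connection).  The header must
#'   contain a `Genus` column; `Kingdom`, `Phylum`, `Class`, `Order` and
#'   `Family` are recognised in any letter case; other columns are ignored.
#' @return A data frame of class `"taxonomy_ref"` with columns `genus`,
#'   `kingdom`, `phylum`, `class`, `order`, `family` (missing ranks are `NA`).
#' @details Duplicate genus keys (compared case-insensitively after trimming)
#'   are a load error, as is a row carrying no phylum, order or family at all.
#' @seealso [read_ecogroup()], [reference_set()], [lookup_category()]
#' @examples
#' tax <- read_taxonomy(ep_example_path("taxonomy"))
#' tax[tax$genus == "Aratrisporites", ]
#' @export
read_taxonomy <- function(source) {
  df <- read_csv_chars(source)
  gi <- find_column(df, "Genus", what = "taxonomy table")
  ranks <- c("kingdom", "phylum", "class", "order", "family")
  out <- data.frame(genus = df[[gi]], stringsAsFactors = FALSE)
  for (r in ranks) {
    ci <- find_column(df, r, required = FALSE)
    v <- if (is.null(ci)) rep(NA_character_, nrow(df)) else df[[ci]]
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    out[[r]] <- v
  }
  if (nrow(out)) {
    if (any(!nzchar(out$genus)))
      ep_validation_error(sprintf(
        "taxonomy row %d has an empty Genus cell",
        which(!nzchar(out$genus))[1L]))
    dup <- duplicated(genus_key(out$genus))
    if (any(dup))
      ep_validation_error(sprintf(
        "duplicate genus '%s' in taxonomy table", out$genus[dup][1L]))
    norank <- is.na(out$phylum) & is.na(out$order) & is.na(out$family)
    if (any(norank))
      ep_validation_error(sprintf(
        "taxonomy row for genus '%s' has no phylum, order or family",
        out$genus[norank][1L]))
  }
  class(out) <- c("taxonomy_ref", "data.frame")
  out
}

#' Read a genus-to-ecogroup (EPH/EPT) table
#'
#' Reads a comma-separated Eco-Plant reference assigning each sporomorph
#' genus a humidity group (EPH) and a temperature group (EPT).  EPH is one of
#' hydrophytes, hygrophytes, mesophytes, xerophytes or euryphytes; EPT is one
#' of megathermic, mesothermic, microthermic or eurythermic.  Both are closed
#' sets: any other value (for example "halophytes", which Mesozoic workers
#' fold into xerophytes) is a validation error naming the offending row.
#' Group names are matched case-insensitively and stored in lower case.
#'
#' @param source Path to a CSV file with columns `Genus`, `EPH`, `EPT`
#'   (any letter case; extra columns ignored).
#' @return A data frame of class `"ecogroup_ref"` with columns `genus`,
#'   `eph`, `ept`.
#' @seealso [read_taxonomy()], [reference_set()]
#' @examples
#' eco <- read_ecogroup(ep_example_path("ecogroup"))
#' table(eco$eph)
#' @export
read_ecogroup <- function(source) {
  df <- read_csv_chars(source)
  gi <- find_column(df, "Genus", what = "ecogroup table")
  hi <- find_column(df, "EPH", what = "ecogroup table")
  ti <- find_column(df, "EPT", what = "ecogroup table")
  out <- data.frame(genus = df[[gi]],
                    eph = tolower(df[[hi]]),
                    ept = tolower(df[[ti]]),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(!nzchar(out$genus)))
      ep_validation_error(sprintf(
        "ecogroup row %d has an empty Genus cell",
        which(!nzchar(out$genus))[1L]))
    dup <- duplicated(genus_key(out$genus))
    if (any(dup))
      ep_validation_error(sprintf(
        "duplicate genus '%s' in ecogroup table", out$genus[dup][1L]))
    bad <- !out$eph %in% EPH_LEVELS
    if (any(bad))
      ep_validation_error(sprintf(
        "row %d (genus '%s'): EPH value '%s' is not one of %s",
        which(bad)[1L], out$genus[bad][1L], out$eph[bad][1L],
        paste(EPH_LEVELS, collapse = ", ")))
    bad <- !out$ept %in% EPT_LEVELS
    if (any(bad))
      ep_validation_error(sprintf(
        "row %d (genus '%s'): EPT value '%s' is not one of %s",
        which(bad)[1L], out$genus[bad][1L], out$ept[bad][1L],
        paste(EPT_LEVELS, collapse = ", ")))
  }
  class(out) <- c("ecogroup_ref", "data.frame")
  out
}

#' Bundle taxonomy and ecogroup tables into one reference set
#'
#' The two tables are keyed by the same `Genus` field, which is what lets an
#' uploaded assemblage, the taxonomy and the ecogroup act as a single joined
#' dataset.  Neither table need cover the other's genera: a genus present
#' only in the taxonomy simply resolves to `"Uncertain"` in ecogroup modes.
#'
#' @param taxonomy A `"taxonomy_ref"` data frame from [read_taxonomy()], or
#'   `NULL` for an empty table.
#' @param ecogroup An `"ecogroup_ref"` data frame from [read_ecogroup()], or
#'   `NULL` for an empty table.
#' @return A list of class `"reference_set"` with elements `taxonomy` and
#'   `ecogroup`.
#' @export
reference_set <- function(taxonomy = NULL, ecogroup = NULL) {
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(genus = character(), kingdom = character(),
                           phylum = character(), class = character(),
                           order = character(), family = character(),
                           stringsAsFactors = FALSE)
    class(taxonomy) <- c("taxonomy_ref", "data.frame")
  }
  if (is.null(ecogroup)) {
    ecogroup <- data.frame(genus = character(), eph = character(),
                           ept = character(), stringsAsFactors = FALSE)
    class(ecogroup) <- c("ecogroup_ref", "data.frame")
  }
  stopifnot(inherits(taxonomy, "taxonomy_ref"),
            inherits(ecogroup, "ecogroup_ref"))
  structure(list(taxonomy = taxonomy, ecogroup = ecogroup),
            class = "reference_set")
}

#' Load the bundled Mesozoic reference excerpt
#'
#' Returns a [reference_set()] built from the reference tables installed with
#' the package: a 17-genus taxonomy and a 16-genus ecogroup excerpt of a
#' Mesozoic (Bryophyte/Pteridophyte/Gymnosperm) sporomorph flora.  Either
#' table can be replaced by a path to a full curated CSV with the same
#' schema, which is how the reference data are meant to be updated: the
#' tables and the algorithm are independent of one another.
#'
#' @param taxonomy,ecogroup Optional paths overriding the bundled CSVs.
#' @return A `"reference_set"`.
#' @examples
#' refs <- default_reference()
#' nrow(refs$taxonomy)
#' @export
default_reference <- function(taxonomy = NULL, ecogroup = NULL) {
  reference_set(
    read_taxonomy(taxonomy %||% ep_example_path("taxonomy")),
    read_ecogroup(ecogroup %||% ep_example_path("ecogroup"))
  )
}

#' Overlay one reference set on another
#'
#' Records in `overlay` replace records in `base` that share a genus key
#' (last writer wins); genera only in `overlay` are appended.  This supports
#' the usual update workflow: when a published study revises the affinity of
#' a genus, only the corrected rows need supplying, not a whole new table.
#'
#' @param base,overlay `"reference_set"` objects.
#' @return A merged `"reference_set"`.
#' @examples
#' refs <- default_reference()
#' fix <- reference_set(taxonomy = as_taxonomy(data.frame(
#'   Genus = "Annulispora", Phylum = "Bryophytes", Family = "Sphagnaceae")))
#' lookup_category("Annulispora", "family", merge_reference(refs, fix))
#' @export
merge_reference <- function(base, overlay) {
  stopifnot(inherits(base, "reference_set"), inherits(overlay, "reference_set"))
  merge_tab <- function(b, o) {
    drop <- genus_key(b$genus) %in% genus_key(o$genus)
    out <- rbind(b[!drop, , drop = FALSE], o)
    rownames(out) <- NULL
    class(out) <- class(b)
    out
  }
  reference_set(merge_tab(base$taxonomy, overlay$taxonomy),
                merge_tab(base$ecogroup, overlay$ecogroup))
}

#' Build a taxonomy table from a data frame
#'
#' Convenience wrapper applying the same column matching and validation as
#' [read_taxonomy()] to an in-memory data frame.
#'
#' @param df A data frame with a `Genus` column and any of `Kingdom`,
#'   `Phylum`, `Class`, `Order`, `Family` (case-insensitive).
#' @return A `"taxonomy_ref"` data frame.
#' @export
as_taxonomy <- function(df) {
  tc <- textConnection(paste(
    c(csv_line(names(df)),
      apply(df, 1L, function(r) csv_line(ifelse(is.na(r), "", r)))),
    collapse = "\n"))
  on.exit(close(tc))
  read_taxonomy(tc)
}

#' @rdname as_taxonomy
#' @export
as_ecogroup <- function(df) {
  tc <- textConnection(paste(
    c(csv_line(names(df)),
      apply(df, 1L, function(r) csv_line(ifelse(is.na(r), "", r)))),
    collapse = "\n"))
  on.exit(close(tc))
  read_ecogroup(tc)
}

#' Resolve genera to a category under an analysis mode
#'
#' The central lookup of the package.  Under modes `"phylum"`, `"order"` and
#' `"family"` a genus resolves through the taxonomy table to the named rank
#' of its parent plant; under `"eph"` and `"ept"` it resolves through the
#' ecogroup table to its Eco-Plant humidity or temperature group.  A genus
#' absent from the relevant table, or present but with an empty cell at the
#' requested rank, resolves to the sentinel `"Uncertain"`.  Absence is a
#' value, never an error: dispersed sporomorphs of unknown affinity are an
#' expected part of any assemblage, and their share is carried through the
#' percentage calculation as its own category.
#'
#' Genus names are matched after whitespace trimming and case folding, so a
#' capitalisation typo does not silently inflate the Uncertain share.
#'
#' @param genus Character vector of genus names.
#' @param mode One of `"phylum"`, `"order"`, `"family"`, `"eph"`, `"ept"`
#'   (case-insensitive).
#' @param refs A `"reference_set"`; defaults to the bundled excerpt.
#' @return Character vector the length of `genus`; `"Uncertain"` where no
#'   category is known.
#' @examples
#' refs <- default_reference()
#' lookup_category(c("Aratrisporites", "Quadraeculina"), "order", refs)
#' lookup_category("Aratrisporites", "eph", refs)
#' @export
lookup_category <- function(genus, mode, refs = default_reference()) {
  mode <- match_mode(mode)
  tab <- if (mode %in% TAXONOMY_MODES) refs$taxonomy else refs$ecogroup
  idx <- match(genus_key(genus), genus_key(tab$genus))
  val <- tab[[mode]][idx]
  val[is.na(val) | !nzchar(val)] <- UNCERTAIN
  val
}

#' List assemblage genera that resolve to Uncertain
#'
#' Returns, in first-appearance order, the genera of an assemblage that have
#' no category under the given mode.  Too large an unlinked share makes a
#' reconstruction insignificant, so this is the first thing to inspect when
#' an Uncertain column dominates the output.
#'
#' @param assemblage An [assemblage] (or coercible data frame).
#' @param mode Analysis mode as in [lookup_category()].
#' @param refs A `"reference_set"`.
#' @return Character vector of genus names (original spelling, no
#'   duplicates).
#' @examples
#' asm <- ep_example("assemblage")
#' unlinked_genera(asm, "order")
#' unlinked_genera(asm, "eph")
#' @export
unlinked_genera <- function(assemblage, mode, refs = default_reference()) {
  asm <- as_assemblage(assemblage)
  cat <- lookup_category(asm$genus, mode, refs)
  g <- asm$genus[cat == UNCERTAIN]
  g[!duplicated(genus_key(g))]
}

#' Write reference tables back to CSV
#'
#' Inverse of [read_taxonomy()] / [read_ecogroup()]: writing and re-reading
#' a table yields an identical mapping.  Missing ranks become empty cells.
#'
#' @param x A `"taxonomy_ref"` or `"ecogroup_ref"` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(x, path) {
  stopifnot(inherits(x, "taxonomy_ref"))
  cols <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    v <- unlist(x[i, c(tolower(cols[1:5]), "genus")], use.names = FALSE)
    csv_line(ifelse(is.na(v), "", v))
  }, character(1))
  writeLines(c(csv_line(cols), rows), path)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
write_ecogroup <- function(x, path) {
  stopifnot(inherits(x, "ecogroup_ref"))
  rows <- vapply(seq_len(nrow(x)), function(i) {
    csv_line(unlist(x[i, c("genus", "eph", "ept")], use.names = FALSE))
  }, character(1))
  writeLines(c(csv_line(c("Genus", "EPH", "EPT")), rows), path)
  invisible(path)
}
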