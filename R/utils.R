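# Internal helpers shared across the package.

UNCERTAIN <- "Uncertain"

EPH_LEVELS <- c("hydrophytes", "hygrophytes", "mesophytes", "xerophytes",
                "euryphytes")
EPT_LEVELS <- c("megathermic", "mesothermic", "microthermic", "eurythermic")

TAXONOMY_MODES <- c("phylum", "order", "family")
ECOGROUP_MODES <- c("eph", "ept")
ANALYSIS_MODES <- c(TAXONOMY_MODES, ECOGROUP_MODES)

ep_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ecoplant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ep_format_error <- function(msg) ep_stop(msg, "ecoplant_format_error")
ep_validation_error <- function(msg) ep_stop(msg, "ecoplant_validation_error")

# Case-insensitive, whitespace-trimmed key for genus matching.  Original
# spelling is preserved everywhere for display; only lookups fold case.
genus_key <- function(x) tolower(trimws(x))

match_mode <- function(mode) {
  if (length(mode) != 1L || is.na(mode) || !nzchar(trimws(mode)))
    ep_validation_error("`mode` must be a single analysis-mode name")
  m <- tolower(trimws(mode))
  if (!m %in% ANALYSIS_MODES)
    ep_validation_error(sprintf(
      "unknown analysis mode '%s' (expected one of: %s)",
      mode, paste(ANALYSIS_MODES, collapse = ", ")))
  m
}

# read.csv with the header rules all input dialects share: UTF-8 with BOM
# tolerance, comma-separated, everything read as character and trimmed here.
read_csv_chars <- function(source) {
  df <- utils::read.csv(source, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8-BOM")
  names(df) <- trimws(names(df))
  df[] <- lapply(df, trimws)
  df
}

# Locate a required/optional column by case-insensitive name.
find_column <- function(df, name, required = TRUE, what = "file") {
  hit <- which(tolower(names(df)) == tolower(name))
  if (length(hit) == 0L) {
    if (required)
      ep_format_error(sprintf("%s is missing required column '%s'", what, name))
    return(NULL)
  }
  hit[1L]
}

# Strict numeric parser: decimal point only, no thousands separators,
# no blanks.  Returns NA for anything unparseable.
parse_number <- function(x) {
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
  out <- rep(NA_real_, length(x))
  out[ok] <- as.numeric(x[ok])
  out
}

# Display rounding: half away from zero, as spreadsheet users expect.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a percentage for CSV/console output: fixed decimals, then trailing
# zeros (and a bare decimal point) dropped, so 25.0 prints as "25".
fmt_percent <- function(x, decimals = 1L) {
  s <- formatC(round_half_up(x, decimals), format = "f", digits = decimals)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

# Minimal CSV field escaping (RFC 4180): quote only when needed.
csv_field <- function(x) {
  x <- as.character(x)
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

csv_line <- function(fields) paste(csv_field(fields), collapse = ",")

`%||%` <- function(a, b) if (is.null(a)) b else a
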