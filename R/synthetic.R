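#' Generate a random sporomorph assemblage
#'
#' Simulates counted assemblages for testing and demonstration.  Each
#' sample draws per-genus proportions from a symmetric Dirichlet (unit
#' shape), splits total abundance between genera from `genus_pool` and a set
#' of invented unlinkable genera in the ratio `1 - unlinked_fraction` to
#' `unlinked_fraction`, and, for count data, draws grain counts from a
#' multinomial over those proportions — the sampling model of a palynologist
#' counting a fixed number of grains per slide.  Zero-count rows are
#' dropped.  The generator emulates compositional count/percentage structure
#' only; it makes no attempt at taphonomy, pollen productivity or transport
#' bias.
#'
#' @param n_samples Number of samples (default 10); sample `i` gets label
#'   `"S<i>"` and depth `i`.
#' @param genus_pool Character vector of genus names to draw from; defaults
#'   to every genus of the taxonomy table in `refs`.
#' @param total_per_sample Total grains counted per sample (default 300, a
#'   routine palynological counting target), or `"percent"` to emit exact
#'   Dirichlet percentages instead of counts.
#' @param unlinked_fraction Expected share of abundance given to invented
#'   genera absent from any reference table (default 0); their rows resolve
#'   to `"Uncertain"` in every mode.
#' @param seed Optional integer; when given, the caller's RNG state is left
#'   untouched and the output is reproducible.
#' @param refs Reference set used only to default `genus_pool`.
#' @return An `"assemblage"`.
#' @examples
#' asm <- random_assemblage(n_samples = 3, seed = 42)
#' summary(asm)
#' @export
random_assemblage <- function(n_samples = 10L, genus_pool = NULL,
                              total_per_sample = 300L,
                              unlinked_fraction = 0,
                              seed = NULL, refs = default_reference()) {
  if (n_samples < 1L) ep_validation_error("`n_samples` must be >= 1")
  if (!is.numeric(unlinked_fraction) || unlinked_fraction < 0 ||
      unlinked_fraction > 1)
    ep_validation_error("`unlinked_fraction` must be in [0, 1]")
  genus_pool <- genus_pool %||% refs$taxonomy$genus
  if (length(genus_pool) == 0L)
    ep_validation_error("`genus_pool` is empty")
  percent_mode <- identical(total_per_sample, "percent")
  if (!percent_mode &&
      (!is.numeric(total_per_sample) || total_per_sample < 1))
    ep_validation_error("`total_per_sample` must be >= 1 or \"percent\"")

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  n_unlinked <- if (unlinked_fraction > 0) 3L else 0L
  unlinked <- if (n_unlinked) sprintf("Ignotispora%02d", seq_len(n_unlinked))
  taxa <- c(genus_pool, unlinked)

  rows <- lapply(seq_len(n_samples), function(i) {
    p <- stats::rgamma(length(genus_pool), 1)
    p <- (1 - unlinked_fraction) * p / sum(p)
    if (n_unlinked) {
      q <- stats::rgamma(n_unlinked, 1)
      p <- c(p, unlinked_fraction * q / sum(q))
    }
    ab <- if (percent_mode) 100 * p
          else as.numeric(stats::rmultinom(1L, as.integer(total_per_sample), p))
    keep <- ab > 0
    data.frame(sample = sprintf("S%d", i), genus = taxa[keep],
               abundance = ab[keep], depth = as.numeric(i),
               stringsAsFactors = FALSE)
  })
  validate_assemblage(do.call(rbind, rows))
}
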