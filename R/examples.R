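EP_EXAMPLES <- c(taxonomy = "taxonomy-mesozoic.csv",
                 ecogroup = "ecogroup-mesozoic.csv",
                 assemblage = "assemblage-hjg.csv",
                 wide = "orders-wide.csv")

#' Bundled example and reference tables
#'
#' The package ships four small plain-CSV tables: the Mesozoic taxonomy and
#' ecogroup reference excerpts (17 and 16 genera), a worked two-sample
#' Triassic assemblage (`"assemblage"`, samples HJG 01 and HJG 02), and a
#' wide percentage matrix (`"wide"`, 8 samples x 4 categories) for
#' draw-curve mode.  `ep_example_path()` returns the installed file path;
#' `ep_example()` returns the table parsed through the package's own
#' loaders, so the examples exercise the same code path as user data.
#'
#' @param name One of `"taxonomy"`, `"ecogroup"`, `"assemblage"`, `"wide"`.
#' @return `ep_example_path()`: a file path. `ep_example()`: the parsed
#'   object (`"taxonomy_ref"`, `"ecogroup_ref"`, `"assemblage"` or
#'   `"abundance_matrix"` respectively).
#' @examples
#' ep_example("ecogroup")
#' @export
ep_example <- function(name = c("taxonomy", "ecogroup", "assemblage", "wide")) {
  name <- match.arg(name)
  path <- ep_example_path(name)
  switch(name,
         taxonomy = read_taxonomy(path),
         ecogroup = read_ecogroup(path),
         assemblage = read_assemblage(path),
         wide = read_wide_matrix(path))
}

#' @rdname ep_example
#' @export
ep_example_path <- function(name = c("taxonomy", "ecogroup", "assemblage",
                                     "wide")) {
  name <- match.arg(name)
  path <- system.file("extdata", EP_EXAMPLES[[name]], package = "ecoplant",
                      mustWork = TRUE)
  path
}
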