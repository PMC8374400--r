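#' Lay out a stratigraphic pollen diagram
#'
#' Computes the structure of a multi-panel percentage diagram without
#' touching a graphics device: one panel per category (in matrix order, so
#' `"Uncertain"` comes last for analysis matrices), one horizontal track per
#' sample on a shared vertical axis.  The layout object is what the tests
#' and callers introspect; [plot.diagram_layout()] does the actual drawing.
#'
#' @param m An `"abundance_matrix"`.
#' @param axis_order `"input"` keeps samples in matrix (first-appearance)
#'   order, top to bottom; `"depth"` sorts by stratigraphic depth
#'   (shallowest on top) and requires a depth for every sample.
#' @param panel_kind `"bars"` (one horizontal bar per sample, the classic
#'   style) or `"silhouette"` (a filled curve through the sample values).
#' @param scale_max Optional fixed horizontal maximum (percent) applied to
#'   every panel, e.g. 100 for comparable axes.  Default: each panel's
#'   maximum rounded up to the next multiple of 5 (at least 5).
#' @return A list of class `"diagram_layout"` with elements `panels` (each
#'   with `category`, `xmax` and per-sample `values`), `samples`,
#'   `panel_kind` and `axis_order`.
#' @examples
#' m <- eco_plant(ep_example("assemblage"), "order")
#' lay <- diagram_layout(m)
#' length(lay$panels); lay$samples
#' @export
diagram_layout <- function(m, axis_order = c("input", "depth"),
                           panel_kind = c("bars", "silhouette"),
                           scale_max = NULL) {
  stopifnot(inherits(m, "abundance_matrix"))
  axis_order <- match.arg(axis_order)
  panel_kind <- match.arg(panel_kind)
  v <- m$values
  if (nrow(v) == 0L || ncol(v) == 0L)
    ep_validation_error("cannot draw a diagram of an empty matrix")
  smp <- rownames(v)
  if (axis_order == "depth") {
    if (is.null(m$depth) || anyNA(m$depth))
      ep_validation_error("axis_order = 'depth' needs a depth for every sample")
    smp <- smp[order(m$depth)]
  }
  if (!is.null(scale_max)) {
    if (!is.numeric(scale_max) || any(scale_max <= 0))
      ep_validation_error("`scale_max` must be positive")
    xmax <- rep_len(scale_max, ncol(v))
  } else {
    xmax <- pmax(5, 5 * ceiling(apply(v, 2L, max) / 5))
  }
  panels <- lapply(seq_len(ncol(v)), function(j) {
    list(category = colnames(v)[j], xmax = xmax[j],
         values = v[smp, j], uncertain = colnames(v)[j] == UNCERTAIN)
  })
  structure(list(panels = panels, samples = smp,
                 panel_kind = panel_kind, axis_order = axis_order,
                 mode = m$mode),
            class = "diagram_layout")
}

#' @export
print.diagram_layout <- function(x, ...) {
  cat(sprintf("Pollen-diagram layout: %d panel%s x %d track%s (%s, %s order)\n",
              length(x$panels), if (length(x$panels) == 1) "" else "s",
              length(x$samples), if (length(x$samples) == 1) "" else "s",
              x$panel_kind, x$axis_order))
  cat("Panels:", paste(vapply(x$panels, `[[`, "", "category"),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Draw a pollen-diagram layout on the current device
#'
#' @param x A `"diagram_layout"` from [diagram_layout()].
#' @param fill Bar/silhouette fill colour for ordinary panels; the
#'   `"Uncertain"` panel is always drawn in light grey to set it apart.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.diagram_layout <- function(x, fill = "grey35", ...) {
  np <- length(x$panels)
  ns <- length(x$samples)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  label_w <- max(2.4, 0.55 * max(nchar(x$samples)))
  widths <- c(graphics::lcm(label_w), rep(1, np))
  graphics::layout(matrix(seq_len(np + 1L), nrow = 1L), widths = widths)
  ylim <- c(ns + 0.6, 0.4)  # first sample on top

  # shared sample-label column
  graphics::par(mar = c(3.2, 0.3, 6.5, 0.1))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = ylim, yaxs = "i")
  graphics::text(1, seq_len(ns), labels = x$samples, adj = 1, xpd = NA,
                 cex = 0.85)
  graphics::mtext("Sample", side = 3, line = 0.3, cex = 0.7, adj = 1)

  for (k in seq_len(np)) {
    p <- x$panels[[k]]
    col <- if (p$uncertain) "grey80" else fill
    graphics::par(mar = c(3.2, if (p$uncertain) 0.8 else 0.25, 6.5, 0.1))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, p$xmax), ylim = ylim,
                          xaxs = "i", yaxs = "i")
    if (x$panel_kind == "bars") {
      graphics::rect(0, seq_len(ns) - 0.35, p$values, seq_len(ns) + 0.35,
                     col = col, border = NA)
    } else {
      graphics::polygon(c(0, p$values, 0),
                        c(1, seq_len(ns), ns),
                        col = col, border = "grey20")
    }
    graphics::axis(1, at = c(0, p$xmax), cex.axis = 0.7, padj = -1,
                   tcl = -0.25)
    graphics::abline(v = 0, col = "grey40")
    graphics::box(col = "grey60")
    # rotated panel header, pollen-diagram style
    graphics::par(xpd = NA)
    graphics::text(0, 0.15, labels = p$category, srt = 45, adj = c(0, 0),
                   cex = 0.8)
    graphics::par(xpd = FALSE)
  }
  invisible(x)
}

device_for <- function(file, format = NULL, width = NULL, height = NULL) {
  format <- tolower(format %||% tools::file_ext(file))
  if (!format %in% c("pdf", "svg", "png"))
    ep_validation_error(sprintf(
      "unsupported output format '%s' (use pdf, svg or png)", format))
  switch(format,
         pdf = grDevices::pdf(file, width = width, height = height),
         svg = grDevices::svg(file, width = width, height = height),
         png = grDevices::png(file, width = width, height = height,
                              units = "in", res = 150))
}

#' Render an abundance matrix as a stratigraphic pollen diagram
#'
#' Draws the classic multi-panel percentage diagram: one panel per category,
#' one horizontal track per sample, all panels sharing the vertical sample
#' axis, the `"Uncertain"` panel (if any) last and greyed.  With `file` the
#' diagram is written as a PDF, SVG or PNG document (format inferred from
#' the extension); without it the current device is used.
#'
#' @inheritParams diagram_layout
#' @param file Optional output path ending in `.pdf`, `.svg` or `.png`.
#' @param format Optional explicit format overriding the extension.
#' @param width,height Device size in inches; defaults scale with the panel
#'   and track counts.
#' @return The `"diagram_layout"` actually drawn, invisibly — its `panels`
#'   and `samples` describe the rendered scene.
#' @examples
#' m <- eco_plant(ep_example("assemblage"), "order")
#' out <- file.path(tempdir(), "orders.pdf")
#' lay <- pollen_diagram(m, file = out)
#' length(lay$panels)
#' @export
pollen_diagram <- function(m, file = NULL, axis_order = "input",
                           panel_kind = "bars", scale_max = NULL,
                           format = NULL, width = NULL, height = NULL) {
  lay <- diagram_layout(m, axis_order = axis_order, panel_kind = panel_kind,
                        scale_max = scale_max)
  width <- width %||% max(6, 1 + 0.9 * length(lay$panels))
  height <- height %||% max(4, 1.8 + 0.28 * length(lay$samples))
  if (!is.null(file)) {
    device_for(file, format, width, height)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  plot(lay)
  invisible(lay)
}

#' @export
plot.abundance_matrix <- function(x, ...) {
  invisible(pollen_diagram(x, ...))
}

#' Plot a user-supplied wide matrix directly (draw-curve mode)
#'
#' Reads a wide samples-by-categories CSV with [read_wide_matrix()] and
#' renders it with [pollen_diagram()] exactly as given: no reference lookup,
#' no `"Uncertain"` column, no renormalisation.  This is the escape hatch
#' for plotting combined or edited result tables.
#'
#' @param source Path to a wide-format CSV (first column `Sample`).
#' @param file Output document path (`.pdf`, `.svg` or `.png`).
#' @param ... Further arguments passed to [pollen_diagram()].
#' @return The `"diagram_layout"` drawn, invisibly.
#' @examples
#' out <- file.path(tempdir(), "curves.pdf")
#' lay <- draw_curve(ep_example_path("wide"), out)
#' vapply(lay$panels, `[[`, "", "category")
#' @export
draw_curve <- function(source, file, ...) {
  m <- read_wide_matrix(source)
  invisible(pollen_diagram(m, file = file, ...))
}
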