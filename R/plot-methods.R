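# Simple base-graphics views of the analysis products.

#' Plot methods for analysis products
#'
#' Heat-map view of a \linkS4class{DCCM} (blue = anticorrelated, red =
#' correlated, white = independent) and a per-residue track for a
#' \linkS4class{BFactorProfile}.
#'
#' @param x the object to plot.
#' @param y ignored.
#' @param ... passed to the underlying base-graphics call.
#' @return the object, invisibly.
#' @name plot-methods
NULL

#' @rdname plot-methods
#' @export
setMethod("plot", signature(x = "DCCM", y = "missing"), function(x, y, ...) {
  m <- correlations(x)
  n <- nrow(m)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, xlab = "residue",
                  ylab = "residue", main = sprintf("DCCM (%s)", x@method),
                  useRaster = TRUE, ...)
  invisible(x)
})

#' @rdname plot-methods
#' @export
setMethod("plot", signature(x = "BFactorProfile", y = "missing"),
          function(x, y, ...) {
  ylab <- if (x@normalization == "raw") "B-factor (A^2)"
          else sprintf("B-factor (%s)", x@normalization)
  graphics::plot(seq_along(x@values), x@values, type = "l",
                 xlab = "residue index", ylab = ylab,
                 main = sprintf("B-factors (%s)", x@source), ...)
  invisible(x)
})
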