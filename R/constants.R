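#' Physical constants linking GC content, buoyant density and DNA molecular weight
#'
#' Bundles the coefficients used by the qSIP excess-atom-fraction transform:
#' the linear GC-vs-buoyant-density relation, the GC-dependent mean molecular
#' weight of a DNA nucleotide pair, the maximum mass gain of fully
#' \eqn{^{13}}C-labeled DNA, and the natural abundance of \eqn{^{13}}C.
#' Defaults are the values of the standard DNA-qSIP protocol; all are
#' overridable for sensitivity analyses.
#'
#' @param gc_slope Slope of buoyant density on GC content, g/mL per GC unit.
#' @param gc_intercept Buoyant density of GC = 0 DNA, g/mL.
#' @param mw_gc_slope Slope of light molecular weight on GC, g/mol.
#' @param mw_intercept Light molecular weight at GC = 0, g/mol.
#' @param heavy_gc_slope GC slope of the maximum heavy mass gain, g/mol
#'   (negative: high-GC DNA has slightly fewer labelable carbons per unit mass).
#' @param heavy_offset Maximum heavy mass gain at GC = 0, g/mol.
#' @param nat13c Natural \eqn{^{13}}C atom fraction (dimensionless).
#'
#' @return An object of class `isotope_constants` (a named list).
#' @examples
#' cst <- isotope_constants()
#' gc_from_density(1.6880, cst)
#' @export
isotope_constants <- function(gc_slope = 0.083506,
                              gc_intercept = 1.646057,
                              mw_gc_slope = 0.496,
                              mw_intercept = 307.691,
                              heavy_gc_slope = -0.4987282,
                              heavy_offset = 9.974564,
                              nat13c = 0.01111233) {
  stopifnot(
    is.numeric(gc_slope), gc_slope > 0,
    is.numeric(gc_intercept), gc_intercept > 0,
    is.numeric(mw_gc_slope), mw_gc_slope > 0,
    is.numeric(mw_intercept), mw_intercept > 0,
    is.numeric(heavy_gc_slope), heavy_gc_slope < 0,
    is.numeric(heavy_offset), heavy_offset > 0
  )
  if (!is.numeric(nat13c) || nat13c <= 0 || nat13c >= 0.02)
    stop("`nat13c` must lie in (0, 0.02)")
  structure(
    list(gc_slope = gc_slope, gc_intercept = gc_intercept,
         mw_gc_slope = mw_gc_slope, mw_intercept = mw_intercept,
         heavy_gc_slope = heavy_gc_slope, heavy_offset = heavy_offset,
         nat13c = nat13c),
    class = "isotope_constants"
  )
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat("qSIP isotope constants:\n")
  cat(sprintf("  density = %g + %g * GC  [g/mL]\n", x$gc_intercept, x$gc_slope))
  cat(sprintf("  M_light = %g + %g * GC  [g/mol]\n", x$mw_intercept, x$mw_gc_slope))
  cat(sprintf("  max heavy gain = %g %+g * GC  [g/mol]\n", x$heavy_offset, x$heavy_gc_slope))
  cat(sprintf("  natural 13C atom fraction = %g\n", x$nat13c))
  invisible(x)
}
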