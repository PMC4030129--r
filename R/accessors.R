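# Accessor methods and show() for the S4 classes.

#' @rdname enmdyn-accessors
#' @export
setMethod("nBeads", "CalphaModel", function(x) nrow(x@coords))

#' @rdname enmdyn-accessors
#' @export
setMethod("nBeads", "Trajectory", function(x) x@nBeads)

#' @rdname enmdyn-accessors
#' @export
setMethod("nBeads", "ElasticNetwork", function(x) nrow(x@refCoords))

#' @rdname enmdyn-accessors
#' @export
setMethod("coords", "CalphaModel", function(x, ...) x@coords)

#' @rdname enmdyn-accessors
#' @export
setMethod("coords", "ElasticNetwork", function(x, ...) x@refCoords)

#' @rdname enmdyn-accessors
#' @export
setMethod("masses", "CalphaModel", function(x) x@mass)

#' @rdname enmdyn-accessors
#' @export
setMethod("masses", "ElasticNetwork", function(x) x@masses)

#' @rdname enmdyn-accessors
#' @export
setMethod("residLabels", "CalphaModel", function(x) {
  paste0(x@resno, ifelse(nzchar(x@insert), x@insert, ""))
})

#' @rdname enmdyn-accessors
#' @export
setMethod("domains", "CalphaModel", function(x) x@domain)

#' @rdname enmdyn-accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) nrow(x@xyz))

#' @rdname enmdyn-accessors
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nrow(x@xyz))
  .unflatten(x@xyz[i, ])
})

#' @rdname enmdyn-accessors
#' @param internal for an ANM ModeSet, drop the near-zero rigid-body modes
#'   so that element k is internal mode k.
#' @export
setMethod("modeValues", "ModeSet", function(x, internal = TRUE, ...) {
  if (internal && x@source == "anm" && x@nZero > 0L)
    x@values[-seq_len(x@nZero)]
  else x@values
})

#' @rdname enmdyn-accessors
#' @export
setMethod("modeVector", "ModeSet", function(x, i, internal = TRUE, ...) {
  col <- if (internal && x@source == "anm") x@nZero + i else i
  if (any(col < 1L) || any(col > ncol(x@vectors)))
    stop("mode index out of range")
  .unflatten(x@vectors[, col])
})

#' @rdname enmdyn-accessors
#' @export
setMethod("numZeroModes", "ModeSet", function(x) x@nZero)

#' @rdname enmdyn-accessors
#' @export
setMethod("bfactors", "BFactorProfile", function(x) {
  setNames(x@values, x@resid)
})

#' @rdname enmdyn-accessors
#' @export
setMethod("bfactors", "CalphaModel", function(x) {
  setNames(x@bfactorExp, residLabels(x))
})

#' @rdname enmdyn-accessors
#' @export
setMethod("correlations", "DCCM", function(x) x@matrix)

setMethod("show", "CalphaModel", function(object) {
  n <- nBeads(object)
  tagged <- sum(!is.na(object@domain))
  cat(sprintf("CalphaModel: %d beads, chains %s\n", n,
              paste(unique(object@chain), collapse = ",")))
  cat(sprintf("  resid %s..%s; %d beads domain-tagged; %d chain break(s)\n",
              residLabels(object)[1L], residLabels(object)[n], tagged,
              max(0L, sum(object@chainBreak) - 1L)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d frames x %d beads, dt = %g ps, origin = %s%s\n",
    nFrames(object), nBeads(object), object@dt, object@origin,
    if (object@superposed) " (superposed)" else ""))
})

setMethod("show", "ElasticNetwork", function(object) {
  cat(sprintf(
    "ElasticNetwork: %d beads, %d springs (cutoff %g A, gamma %g, p = %g)%s\n",
    nBeads(object), nrow(object@edges), object@cutoff, object@gamma,
    object@weightExponent,
    if (object@connected) "" else " [disconnected]"))
})

setMethod("show", "ModeSet", function(object) {
  nz <- length(object@values) - object@nZero
  cat(sprintf("ModeSet (%s): %d modes (%d near-zero, %d internal)%s\n",
              object@source, length(object@values), object@nZero, nz,
              if (object@disconnected) " [disconnected network]" else ""))
})

setMethod("show", "PCAResult", function(object) {
  v <- modeValues(object@modes)
  tot <- sum(v)
  lead <- if (tot > 0) 100 * sum(v[seq_len(min(3L, length(v)))]) / tot else 0
  cat(sprintf(
    "PCAResult: %d frames, %d beads; PC1-3 carry %.1f%% of variance\n",
    nrow(object@projections), nrow(object@meanCoords), lead))
})

setMethod("show", "ClusterSelection", function(object) {
  cat(sprintf(
    "ClusterSelection: %d clusters over %d frames; selected #%d (%d frames)\n",
    length(object@scores), length(object@labels), object@selected,
    sum(object@labels == object@selected)))
})

setMethod("show", "BFactorProfile", function(object) {
  cat(sprintf("BFactorProfile (%s, %s): %d residues, mean %.3g\n",
              object@source, object@normalization, length(object@values),
              mean(object@values, na.rm = TRUE)))
})

setMethod("show", "DCCM", function(object) {
  off <- object@matrix[upper.tri(object@matrix)]
  cat(sprintf("DCCM (%s): %d x %d, off-diagonal range [%.2f, %.2f]\n",
              object@method, nrow(object@matrix), ncol(object@matrix),
              min(off), max(off)))
})

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(
    "SimulationParams: dt %g ps x %d steps (%.3g ns), T = %g K, friction %g ps^-1, save every %d, seed %d\n",
    object@dt, object@nSteps, object@dt * object@nSteps / 1000,
    object@temperature, object@friction, object@saveEvery, object@seed))
})
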