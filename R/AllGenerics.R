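#' @name enmdyn-accessors
#' @title Accessor generics for enmdyn objects
#'
#' @description Slot access for the core S4 classes: bead counts and
#' coordinates, masses, residue labels, domain tags, frame access for
#' trajectories, and eigenpair access for mode sets.
#'
#' @param x an enmdyn S4 object.
#' @param i frame or mode index.
#' @param ... passed to methods.
NULL

#' @rdname enmdyn-accessors
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("residLabels", function(x) standardGeneric("residLabels"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("modeValues", function(x, ...) standardGeneric("modeValues"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("modeVector", function(x, i, ...) standardGeneric("modeVector"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("numZeroModes", function(x) standardGeneric("numZeroModes"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("bfactors", function(x) standardGeneric("bfactors"))

#' @rdname enmdyn-accessors
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))
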