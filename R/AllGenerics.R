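#' @rdname EnrichmentTrack-class
#' @param x an object.
#' @export
setGeneric("enrichment", function(x) standardGeneric("enrichment"))

#' @rdname EnrichmentTrack-class
#' @export
setGeneric("windows", function(x) standardGeneric("windows"))

#' @rdname EnrichmentTrack-class
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @rdname EnrichmentTrack-class
#' @export
setGeneric("isControlSubtracted",
           function(x) standardGeneric("isControlSubtracted"))

#' Subtract a control enrichment track from a ChIP track
#'
#' Per-window difference of log2 local enrichments (a ratio on the linear
#' scale), mirroring the published analysis in which the local enrichment of
#' the control sections is subtracted from that of the ChIP sections.
#'
#' @param x ChIP-sample \linkS4class{EnrichmentTrack}.
#' @param control control-sample \linkS4class{EnrichmentTrack} on the
#'   identical window grid.
#' @return an \linkS4class{EnrichmentTrack} with
#'   \code{isControlSubtracted(x)} \code{TRUE}.
#' @export
setGeneric("subtractControl",
           function(x, control) standardGeneric("subtractControl"))

#' @rdname MotifModel-class
#' @param x an object.
#' @export
setGeneric("pwm", function(x) standardGeneric("pwm"))

#' @rdname MotifModel-class
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))

#' @rdname MotifModel-class
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @rdname MotifModel-class
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname KineticFit-class
#' @param x an object.
#' @export
setGeneric("ka", function(x) standardGeneric("ka"))

#' @rdname KineticFit-class
#' @export
setGeneric("kd", function(x) standardGeneric("kd"))

#' Equilibrium dissociation constant of a kinetic fit
#'
#' @param x a \linkS4class{KineticFit}.
#' @return \code{kd(x) / ka(x)}, in molar.
#' @export
setGeneric("KD", function(x) standardGeneric("KD"))

#' @rdname KineticFit-class
#' @export
setGeneric("rmax", function(x) standardGeneric("rmax"))
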