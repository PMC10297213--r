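# Generics, accessors and show methods.

#' @name morphoRD-accessors
#' @title Accessors for morphoRD classes
#' @description Small accessor generics: \code{maskMatrix} returns the logical
#'   lattice of a \linkS4class{CellMask}; \code{volume} its foreground pixel
#'   count; \code{fieldValues} the numeric matrix of a
#'   \linkS4class{GridField}; \code{componentId} its component label;
#'   \code{modelName}, \code{components}, \code{kineticParams} describe a
#'   \linkS4class{ModelSpec}; \code{kymMatrix} and \code{peakAnnotations}
#'   unwrap a \linkS4class{Kymograph}; \code{peakLag} the signal-vs-velocity
#'   peak lag of a \linkS4class{PeakSummary}.
#' @param x the object.
#' @return The underlying slot value (matrix, numeric, character or
#'   data.frame, depending on the accessor).
NULL

#' @rdname morphoRD-accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname morphoRD-accessors
#' @export
setMethod("maskMatrix", "CellMask", function(x) x@mask)

#' @rdname morphoRD-accessors
#' @export
setGeneric("volume", function(x) standardGeneric("volume"))
#' @rdname morphoRD-accessors
#' @export
setMethod("volume", "CellMask", function(x) sum(x@mask))

#' @rdname morphoRD-accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname morphoRD-accessors
#' @export
setMethod("fieldValues", "GridField", function(x) x@values)

#' @rdname morphoRD-accessors
#' @export
setGeneric("componentId", function(x) standardGeneric("componentId"))
#' @rdname morphoRD-accessors
#' @export
setMethod("componentId", "GridField", function(x) x@component)

#' @rdname morphoRD-accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))
#' @rdname morphoRD-accessors
#' @export
setMethod("modelName", "ModelSpec", function(x) x@name)

#' @rdname morphoRD-accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @rdname morphoRD-accessors
#' @export
setMethod("components", "ModelSpec", function(x) x@components)

#' @rdname morphoRD-accessors
#' @export
setGeneric("kineticParams", function(x) standardGeneric("kineticParams"))
#' @rdname morphoRD-accessors
#' @export
setMethod("kineticParams", "ModelSpec", function(x) x@params)

#' @rdname morphoRD-accessors
#' @export
setGeneric("kymMatrix", function(x) standardGeneric("kymMatrix"))
#' @rdname morphoRD-accessors
#' @export
setMethod("kymMatrix", "Kymograph", function(x) x@data)

#' @rdname morphoRD-accessors
#' @export
setGeneric("peakAnnotations", function(x) standardGeneric("peakAnnotations"))
#' @rdname morphoRD-accessors
#' @export
setMethod("peakAnnotations", "Kymograph", function(x) x@peaks)

#' @rdname morphoRD-accessors
#' @export
setGeneric("peakLag", function(x) standardGeneric("peakLag"))
#' @rdname morphoRD-accessors
#' @export
setMethod("peakLag", "PeakSummary", function(x) x@lag)

setMethod("show", "CellMask", function(object) {
  cat("CellMask:", nrow(object@mask), "x", ncol(object@mask), "frame,",
      sum(object@mask), "foreground pixels (V0 =", object@V0, ")\n")
})

setMethod("show", "GridField", function(object) {
  v <- object@values[object@mask@mask]
  cat("GridField '", object@component, "': ", nrow(object@values), " x ",
      ncol(object@values), ", range [", signif(min(v), 4), ", ",
      signif(max(v), 4), "] inside mask\n", sep = "")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec '", object@name, "'\n", sep = "")
  cat("  components:", paste(object@components, collapse = ", "), "\n")
  cat("  pairs:", length(object@pairs), "conserved active/inactive pairs\n")
  cat("  totals:", paste(names(object@totals), "=", object@totals,
                         collapse = ", "), "\n")
  cat("  actin input component:", object@actinComponent, "\n")
})

setMethod("show", "SolverConfig", function(object) {
  cat("SolverConfig: dt =", object@dt, ", dx =", object@dx,
      ", noise amplitude =", object@noiseAmp,
      paste0("(", object@noiseScaling, " scaling)"), "\n")
  cat("  ", object@rdItersPerEvent, "RD iterations per event cycle,",
      object@saveEvery, "per saved frame, seed", object@seed, "\n")
})

setMethod("show", "TrajectoryBundle", function(object) {
  cat("TrajectoryBundle:", nrow(object@x), "trajectories x", ncol(object@x),
      "frames\n")
})

setMethod("show", "Kymograph", function(object) {
  cat("Kymograph (", object@kind, "): ", nrow(object@data),
      " trajectories x ", ncol(object@data), " frames, ",
      nrow(object@peaks), " annotated peaks\n", sep = "")
})

setMethod("show", "PeakSummary", function(object) {
  cat("PeakSummary:", object@nPeaks, "velocity peaks\n")
  if (object@nPeaks > 0L)
    cat("  signal peak lag relative to velocity peak:", object@lag, "frames\n")
})

setMethod("show", "ContourSet", function(object) {
  cat("ContourSet over frames", min(object@frames), "-", max(object@frames),
      ":", nrow(object@outer), "outer,", nrow(object@inner), "inner,",
      nrow(object@mid), "mid points\n")
})
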