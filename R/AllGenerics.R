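#' Accessors for the core classes
#'
#' Small Bioconductor-style accessors so user code never touches slots.
#'
#' @param object one of the package's S4 objects.
#' @return the slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sinoValues", function(object) standardGeneric("sinoValues"))
#' @rdname accessors
#' @export
setMethod("sinoValues", "Sinogram", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setMethod("geometry", "Sinogram", function(object) object@geometry)

#' @rdname accessors
#' @export
setGeneric("muValues", function(object) standardGeneric("muValues"))
#' @rdname accessors
#' @export
setMethod("muValues", "MuMap", function(object) object@mu)

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setMethod("gridSpacing", "MuMap", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "LabeledPhantom", function(object) object@spacing)

#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(object) standardGeneric("tissueLabels"))
#' @rdname accessors
#' @export
setMethod("tissueLabels", "LabeledPhantom", function(object) {
  m <- object@labels
  structure(m, levels = object@classLevels)
})

#' @rdname accessors
#' @export
setGeneric("huMap", function(object) standardGeneric("huMap"))
#' @rdname accessors
#' @export
setMethod("huMap", "LabeledPhantom", function(object) object@hu)

#' @rdname accessors
#' @export
setGeneric("activityMap", function(object) standardGeneric("activityMap"))
#' @rdname accessors
#' @export
setMethod("activityMap", "LabeledPhantom", function(object) object@activity)

#' @rdname accessors
#' @export
setGeneric("phantomSpecOf", function(object) standardGeneric("phantomSpecOf"))
#' @rdname accessors
#' @export
setMethod("phantomSpecOf", "LabeledPhantom", function(object) object@spec)

#' @rdname accessors
#' @export
setGeneric("voiMembers", function(object) standardGeneric("voiMembers"))
#' @rdname accessors
#' @export
setMethod("voiMembers", "IsocontourVOI", function(object) object@members)

setMethod("show", "ProjectionGeometry", function(object) {
  cat(sprintf("ProjectionGeometry: %d angles over [0, pi), %d radial bins (%.2f mm)\n",
              object@nAngles, object@nRadialBins, object@binSpacing))
})

setMethod("show", "Sinogram", function(object) {
  v <- object@values
  cat(sprintf("Sinogram %d x %d | total %.4g | max %.4g\n",
              nrow(v), ncol(v), sum(v), max(v)))
})

setMethod("show", "MuMap", function(object) {
  cat(sprintf("MuMap %d x %d @ %.2f mm | mu in [%.4f, %.4f] 1/cm\n",
              nrow(object@mu), ncol(object@mu), object@spacing,
              min(object@mu), max(object@mu)))
})

setMethod("show", "LabeledPhantom", function(object) {
  tab <- table(factor(object@classLevels[object@labels],
                      levels = object@classLevels))
  cat(sprintf("LabeledPhantom %d x %d @ %.2f mm\n",
              nrow(object@hu), ncol(object@hu), object@spacing))
  cat("  voxels per class:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

setMethod("show", "CascadedGenerator", function(object) {
  s <- object@spec
  cat(sprintf("CascadedGenerator: %d cascade(s), U-Net depth %d, base %d channels%s\n",
              s$nCascades, s$unetDepth, s$baseChannels,
              if (length(object@params)) " [initialised]" else ""))
})

setMethod("show", "DeviationReport", function(object) {
  cat(sprintf("DeviationReport: %d organ ROI row(s), %d lesion row(s)\n",
              nrow(object@organ), nrow(object@lesions)))
  if (nrow(object@organ)) {
    ok <- is.finite(object@organ$pct_diff)
    cat(sprintf("  organ pct diff: mean %.2f%%, mean |pct| %.2f%%\n",
                mean(object@organ$pct_diff[ok]),
                mean(object@organ$abs_pct_diff[ok])))
  }
})
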