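#' @import methods
#' @importFrom stats rnorm rpois runif quantile median sd setNames
#' @importFrom utils head read.csv write.csv
NULL

TISSUE_CLASSES <- c("air", "lung", "soft", "bone", "lesion", "bladder")

#' Projection geometry for the 2D parallel-beam scanner model
#'
#' Describes the sampling of the sinogram domain: projection angles are
#' equally spaced over \eqn{[0, \pi)} and radial bins are centred on the
#' image centre.
#'
#' @slot nAngles number of projection angles over \eqn{[0, \pi)}.
#' @slot nRadialBins number of radial bins.
#' @slot binSpacing radial bin spacing in mm.
#' @export
setClass("ProjectionGeometry",
  representation(nAngles = "integer", nRadialBins = "integer",
                 binSpacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nAngles < 1L) msg <- c(msg, "nAngles must be >= 1")
    if (object@nRadialBins < 1L) msg <- c(msg, "nRadialBins must be >= 1")
    if (object@binSpacing <= 0) msg <- c(msg, "binSpacing must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Sinogram: projection-domain data
#'
#' Holds line integrals or counts on an (angle x radial bin) grid together
#' with the geometry that produced them.
#'
#' @slot values numeric matrix, nAngles x nRadialBins, nonnegative.
#' @slot geometry a [ProjectionGeometry-class].
#' @export
setClass("Sinogram",
  representation(values = "matrix", geometry = "ProjectionGeometry"),
  validity = function(object) {
    g <- object@geometry
    if (!all(dim(object@values) == c(g@nAngles, g@nRadialBins)))
      return("values must be nAngles x nRadialBins")
    if (any(object@values < 0)) return("sinogram values must be nonnegative")
    TRUE
  })

#' Linear attenuation coefficient map at 511 keV
#'
#' @slot mu numeric matrix of linear attenuation coefficients in 1/cm.
#' @slot spacing voxel spacing in mm (isotropic).
#' @export
setClass("MuMap",
  representation(mu = "matrix", spacing = "numeric"),
  validity = function(object) {
    if (any(object@mu < 0)) return("mu must be nonnegative")
    if (object@spacing <= 0) return("spacing must be > 0")
    TRUE
  })

#' Specification of a synthetic whole-body-like phantom slice
#'
#' All organ positions and sizes are expressed as fractions of the grid so a
#' spec is resolution independent. The tissue table fixes the per-class mean
#' Hounsfield units, HU texture SD and FDG-like activity concentration
#' (kBq/mL); the defaults put the bladder highest and the lungs lowest.
#'
#' @slot gridSize voxels per axis (square 2D slice).
#' @slot voxelSpacing voxel size in mm.
#' @slot organParams named list of ellipse parameters (fractions of grid).
#' @slot lesionList list of lesions: each list(center = c(fr, fc),
#'   radius_mm, multiplier).
#' @slot respiratoryState scalar in [0, 1]; 0 is the expiration reference.
#' @slot maxShiftVox maximal caudal diaphragm displacement in voxels at
#'   respiratoryState 1.
#' @slot bowelGasSeed integer seed for the air-filled bowel ellipses.
#' @slot tissueTable data.frame with columns class, hu, hu_sd, activity.
#' @slot seed integer master seed for the HU texture fields.
#' @export
setClass("PhantomSpec",
  representation(gridSize = "integer", voxelSpacing = "numeric",
                 organParams = "list", lesionList = "list",
                 respiratoryState = "numeric", maxShiftVox = "numeric",
                 bowelGasSeed = "integer", tissueTable = "data.frame",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@gridSize < 16L) msg <- c(msg, "gridSize must be >= 16")
    if (object@voxelSpacing <= 0) msg <- c(msg, "voxelSpacing must be > 0")
    if (object@respiratoryState < 0 || object@respiratoryState > 1)
      msg <- c(msg, "respiratoryState must be in [0, 1]")
    if (!all(c("class", "hu", "hu_sd", "activity") %in%
             names(object@tissueTable)))
      msg <- c(msg, "tissueTable needs columns class, hu, hu_sd, activity")
    for (les in object@lesionList)
      if (les$radius_mm <= 0) msg <- c(msg, "lesion radii must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Labelled phantom: tissue classes, HU and activity on one grid
#'
#' Ground truth for everything downstream: the HU map stands in for an
#' acquired CT and the activity map for the tracer distribution imaged as
#' non-attenuation-corrected PET.
#'
#' @slot labels integer matrix of tissue classes (values index
#'   \code{classLevels}).
#' @slot classLevels character vector naming the label integers.
#' @slot hu numeric matrix of Hounsfield units in [-1024, 3071].
#' @slot activity numeric matrix of activity concentration (kBq/mL), >= 0.
#' @slot spacing voxel spacing in mm.
#' @slot spec the generating [PhantomSpec-class] (kept so deterministic
#'   re-deformation, e.g. a different respiratory state, is possible).
#' @export
setClass("LabeledPhantom",
  representation(labels = "matrix", classLevels = "character",
                 hu = "matrix", activity = "matrix", spacing = "numeric",
                 spec = "PhantomSpec"),
  validity = function(object) {
    msg <- character()
    if (any(object@hu < -1024 | object@hu > 3071))
      msg <- c(msg, "hu must lie in [-1024, 3071]")
    if (any(object@activity < 0)) msg <- c(msg, "activity must be >= 0")
    if (!all(dim(object@labels) == dim(object@hu)) ||
        !all(dim(object@hu) == dim(object@activity)))
      msg <- c(msg, "labels, hu and activity must share one grid")
    air <- which(object@labels == match("air", object@classLevels))
    if (length(air) && any(object@activity[air] > 0))
      msg <- c(msg, "air voxels must carry zero activity")
    if (length(msg)) msg else TRUE
  })

#' Reconstruction parameters for OSEM/MLEM
#'
#' The clinical protocol that inspired the defaults used a 400 x 400 matrix
#' with 21 subsets, 2 iterations and a 2-mm Gaussian post-filter; the
#' desk-scale defaults keep the same structure at tractable size.
#'
#' @slot matrixSize reconstructed image size (voxels per axis).
#' @slot nSubsets number of ordered subsets (1 = plain MLEM).
#' @slot nIterations number of full iterations.
#' @slot postfilterFwhm Gaussian post-filter FWHM in mm (0 disables).
#' @export
setClass("ReconParams",
  representation(matrixSize = "integer", nSubsets = "integer",
                 nIterations = "integer", postfilterFwhm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
    if (object@nSubsets < 1L) msg <- c(msg, "nSubsets must be >= 1")
    if (object@postfilterFwhm < 0) msg <- c(msg, "postfilterFwhm must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Cascaded U-Net generator for PET_NAC to pseudo-CT translation
#'
#' The generator is a chain of small U-Nets; the first consumes the
#' normalized PET_NAC slice, each later cascade consumes the PET_NAC slice
#' stacked with the previous cascade's prediction and refines it.
#'
#' @slot spec list: nCascades, unetDepth, baseChannels, kernel.
#' @slot params nested list of convolution weights per cascade.
#' @slot norm list of normalization parameters (PET percentile, CT range).
#' @export
setClass("CascadedGenerator",
  representation(spec = "list", params = "list", norm = "list"),
  validity = function(object) {
    if (object@spec$nCascades < 1L) return("nCascades must be >= 1")
    if (length(object@params) &&
        length(object@params) != object@spec$nCascades)
      return("params must hold one entry per cascade")
    TRUE
  })

#' Conditional discriminator
#'
#' A strided convolutional binary classifier applied to a (CT candidate,
#' PET_NAC) channel-stacked pair; returns a real-vs-fake probability in
#' (0, 1). Its intermediate activations double as the feature extractor for
#' the perceptual and style-content losses.
#'
#' @slot spec list: channels per layer, kernel.
#' @slot params nested list of convolution weights.
#' @export
setClass("PatchDiscriminator",
  representation(spec = "list", params = "list"))

#' Circular region of interest
#'
#' @slot center voxel coordinates c(row, col) of the ROI centre.
#' @slot radiusMM radius in mm.
#' @slot label organ label (e.g. "liver", "left lung", or a phantom-class
#'   analog such as "soft").
#' @export
setClass("CircularROI",
  representation(center = "numeric", radiusMM = "numeric", label = "character"),
  validity = function(object) {
    if (length(object@center) != 2) return("center must be c(row, col)")
    if (object@radiusMM <= 0) return("radiusMM must be > 0")
    TRUE
  })

#' Isocontour volume of interest
#'
#' Connected set (face connectivity) of voxels at or above a fraction of a
#' local maximum, containing that maximum.
#'
#' @slot members integer matrix (one row per voxel, columns row/col).
#' @slot peak voxel coordinates of the local maximum.
#' @slot peakValue image value at the maximum.
#' @slot fraction threshold fraction of the local maximum (default 0.5).
#' @export
setClass("IsocontourVOI",
  representation(members = "matrix", peak = "numeric", peakValue = "numeric",
                 fraction = "numeric"))

#' Deviation report: the quantitative comparison of two reconstructions
#'
#' @slot organ data.frame of per-ROI SUV deviation metrics.
#' @slot lesions data.frame of per-lesion SUV_mean/SUV_max deviation metrics.
#' @slot hu data.frame of per-ROI mean HU in CT and pseudo-CT.
#' @slot blandAltman list of Bland-Altman records (HU; lesion SUVs).
#' @slot boxStats list of box-plot summaries of the percent deviations.
#' @export
setClass("DeviationReport",
  representation(organ = "data.frame", lesions = "data.frame",
                 hu = "data.frame", blandAltman = "list", boxStats = "list"))
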