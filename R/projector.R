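#' @importFrom Rcpp sourceCpp
#' @useDynLib petacgan, .registration = TRUE
NULL

# cache of sparse system matrices, keyed by (n, geometry, spacing)
.sysmat_cache <- new.env(parent = emptyenv())

#' Construct a projection geometry
#'
#' @param nAngles number of angles over \eqn{[0, \pi)}.
#' @param nRadialBins number of radial bins.
#' @param binSpacing radial bin spacing in mm.
#' @return a [ProjectionGeometry-class].
#' @export
projectionGeometry <- function(nAngles, nRadialBins, binSpacing) {
  new("ProjectionGeometry", nAngles = as.integer(nAngles),
      nRadialBins = as.integer(nRadialBins), binSpacing = binSpacing)
}

#' Default geometry covering an n x n grid
#'
#' Radial sampling at the voxel pitch, extended (odd count) to cover the
#' grid diagonal so no ray through the support is lost.
#'
#' @param n grid size (voxels per axis).
#' @param spacing voxel spacing in mm.
#' @param nAngles number of angles (default 96).
#' @return a [ProjectionGeometry-class].
#' @export
defaultGeometry <- function(n, spacing, nAngles = 96L) {
  nrad <- 2L * ceiling(n * sqrt(2) / 2) + 1L
  projectionGeometry(nAngles, nrad, spacing)
}

#' Sparse system matrix for a geometry / grid combination
#'
#' Joseph-style length-weighted intersection matrix P with
#' \code{dim(P) = c(nAngles * nRadialBins, n^2)}; weights are in cm so
#' \code{P \%*\% as.vector(img)} is the discrete line integral
#' \eqn{\int f\, dl} (value x cm). Matrices are cached per geometry.
#'
#' @param geom a [ProjectionGeometry-class].
#' @param n image grid size.
#' @param spacing voxel spacing in mm.
#' @return a \code{dgCMatrix}.
#' @export
systemMatrix <- function(geom, n, spacing) {
  if (geom@nRadialBins * geom@binSpacing < n * spacing * sqrt(2) - 1e-9)
    stop("radial extent does not cover the grid diagonal")
  key <- paste(n, geom@nAngles, geom@nRadialBins, geom@binSpacing, spacing,
               sep = "|")
  if (!is.null(.sysmat_cache[[key]])) return(.sysmat_cache[[key]])
  tr <- cpp_system_triplets(n, geom@nAngles, geom@nRadialBins,
                            geom@binSpacing, spacing)
  P <- Matrix::sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$x,
                            dims = c(geom@nAngles * geom@nRadialBins, n * n))
  .sysmat_cache[[key]] <- P
  P
}

#' Forward projection (discrete Radon transform)
#'
#' Length-weighted line integrals of a nonnegative square image along each
#' ray of the geometry; linear in the image. Integrals are in value x cm.
#'
#' @param image numeric square matrix (nonnegative).
#' @param geom a [ProjectionGeometry-class].
#' @param spacing voxel spacing in mm.
#' @return a [Sinogram-class].
#' @export
forwardProject <- function(image, geom, spacing) {
  if (nrow(image) != ncol(image)) stop("image must be square")
  if (any(image < 0)) stop("image must be nonnegative")
  P <- systemMatrix(geom, nrow(image), spacing)
  v <- as.numeric(P %*% as.vector(image))
  new("Sinogram", values = matrix(pmax(v, 0), geom@nAngles, geom@nRadialBins),
      geometry = geom)
}

#' Back projection (adjoint of [forwardProject()])
#'
#' @param sino a [Sinogram-class].
#' @param n image grid size.
#' @param spacing voxel spacing in mm.
#' @return numeric n x n matrix.
#' @export
backProject <- function(sino, n, spacing) {
  P <- systemMatrix(sino@geometry, n, spacing)
  matrix(as.numeric(Matrix::crossprod(P, as.vector(sino@values))), n, n)
}

#' Attenuation (transmission) factors along each ray
#'
#' Beer-Lambert: \eqn{\exp(-\int \mu\, dl)} per ray, values in (0, 1]. Rays
#' missing the object have factor 1.
#'
#' @param muMap a [MuMap-class] (mu in 1/cm).
#' @param geom a [ProjectionGeometry-class].
#' @return a [Sinogram-class] of transmission factors.
#' @export
attenuationFactors <- function(muMap, geom) {
  s <- forwardProject(muValues(muMap), geom, gridSpacing(muMap))
  new("Sinogram", values = exp(-s@values), geometry = geom)
}
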