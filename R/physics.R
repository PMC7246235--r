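#' Convert Hounsfield units to 511-keV linear attenuation coefficients
#'
#' Piecewise-linear ("bilinear") conversion:
#' \deqn{\mu = \mu_w (HU + 1000)/1000 \quad (HU \le 0)}
#' \deqn{\mu = \mu_w + HU \cdot s_b \quad (HU > 0)}
#' with water \eqn{\mu_w = 0.096} 1/cm and bone slope
#' \eqn{s_b = 5 \times 10^{-5}} 1/cm per HU by default. The vendor curve is
#' unpublished; this is a standard stand-in, both parameters configurable.
#' HU below -1024 are clamped with a warning; mu is floored at 0 (HU in
#' (-1024, -1000) would otherwise map slightly negative).
#'
#' @param hu numeric matrix of Hounsfield units.
#' @param spacing voxel spacing in mm.
#' @param muWater attenuation of water at 511 keV, 1/cm.
#' @param boneSlope slope above 0 HU, 1/cm per HU.
#' @return a [MuMap-class].
#' @examples
#' m <- huToMu(matrix(c(-1000, 0, 1000), 1, 3), spacing = 4)
#' muValues(m)  # 0, 0.096, 0.146
#' @export
huToMu <- function(hu, spacing, muWater = 0.096, boneSlope = 5e-5) {
  if (any(hu < -1024)) {
    warning("HU below -1024 clamped")
    hu <- pmax(hu, -1024)
  }
  mu <- ifelse(hu <= 0, muWater * (hu + 1000) / 1000, muWater + hu * boneSlope)
  new("MuMap", mu = pmax(mu, 0), spacing = spacing)
}

#' Simulate a PET acquisition (Poisson counts)
#'
#' Expected counts per ray are
#' \code{countScale * forwardProject(activity) * attenuationFactors(mu)};
#' observed counts are Poisson with that mean, seeded.
#'
#' @param activity activity image (kBq/mL), nonnegative square matrix.
#' @param muMap a [MuMap-class] for the attenuating anatomy.
#' @param geom a [ProjectionGeometry-class].
#' @param countScale counts per (kBq/mL x cm), > 0. Controls noise level.
#' @param seed integer seed; NULL for noiseless expected means.
#' @return a [Sinogram-class] of counts (expected means if seed is NULL).
#' @export
simulateAcquisition <- function(activity, muMap, geom, countScale, seed = 1L) {
  stopifnot(countScale > 0)
  proj <- forwardProject(activity, geom, gridSpacing(muMap))
  acf <- attenuationFactors(muMap, geom)
  mean <- countScale * proj@values * acf@values
  if (is.null(seed)) {
    counts <- mean
  } else {
    set.seed(seed)
    counts <- matrix(rpois(length(mean), mean), nrow(mean), ncol(mean))
  }
  new("Sinogram", values = counts, geometry = geom)
}

#' Construct reconstruction parameters
#'
#' @param matrixSize image size, voxels per axis (default 128).
#' @param nSubsets ordered subsets (default 8; 1 gives plain MLEM).
#' @param nIterations full iterations (default 4).
#' @param postfilterFwhm Gaussian post-filter FWHM in mm (default 2, the
#'   clinical protocol's value; 0 disables).
#' @return a [ReconParams-class].
#' @export
reconParams <- function(matrixSize = 128L, nSubsets = 8L, nIterations = 4L,
                        postfilterFwhm = 2) {
  new("ReconParams", matrixSize = as.integer(matrixSize),
      nSubsets = as.integer(nSubsets), nIterations = as.integer(nIterations),
      postfilterFwhm = postfilterFwhm)
}

#' Clinical-protocol reconstruction preset
#'
#' The source scanner protocol: 400 x 400 matrix, 21 subsets, 2 iterations,
#' 2-mm Gaussian filter. Provided as a documented preset; desk-scale work
#' uses [reconParams()] defaults.
#'
#' @return a [ReconParams-class].
#' @export
clinicalReconParams <- function() {
  reconParams(matrixSize = 400L, nSubsets = 21L, nIterations = 2L,
              postfilterFwhm = 2)
}

#' OSEM/MLEM reconstruction with attenuation in the system model
#'
#' Multiplicative EM update with the attenuation-weighted projector as
#' system model; ordered subsets partition the angles (interleaved). With
#' \code{nSubsets = 1} this is plain MLEM. Passing an all-ones ACF sinogram
#' reconstructs without attenuation correction (the PET_NAC image). Voxels
#' with zero sensitivity are excluded from the update (left at zero).
#' Nonnegativity is preserved by construction.
#'
#' @param counts a [Sinogram-class] of counts.
#' @param acf a [Sinogram-class] of transmission factors in (0, 1], or the
#'   string "ones" for no attenuation correction.
#' @param params a [ReconParams-class]; \code{nSubsets} must divide the
#'   geometry's angle count.
#' @param spacing voxel spacing of the reconstruction grid in mm.
#' @param countScale same scale as used in the acquisition model (default 1;
#'   only affects the global scaling of the estimate).
#' @return numeric matrix (matrixSize x matrixSize), post-filtered if
#'   requested.
#' @export
mlemReconstruct <- function(counts, acf, params, spacing, countScale = 1) {
  geom <- counts@geometry
  nAng <- geom@nAngles
  if (identical(acf, "ones"))
    acf <- new("Sinogram", values = matrix(1, nAng, geom@nRadialBins),
               geometry = geom)
  if (!all(dim(acf@values) == dim(counts@values)))
    stop("counts and acf shapes differ")
  if (any(acf@values <= 0) || any(acf@values > 1 + 1e-12))
    stop("acf values must lie in (0, 1]")
  if (nAng %% params@nSubsets != 0L)
    stop("nSubsets must divide the number of angles")
  n <- params@matrixSize
  P <- systemMatrix(geom, n, spacing)

  nsub <- params@nSubsets
  subsets <- lapply(seq_len(nsub), function(k) {
    angles <- seq(k, nAng, by = nsub)
    rows <- as.vector(outer(angles, (seq_len(geom@nRadialBins) - 1L) * nAng,
                            "+"))
    Ps <- P[rows, , drop = FALSE]
    a <- as.vector(acf@values)[rows] * countScale
    sens <- as.numeric(Matrix::crossprod(Ps, a))
    list(P = Ps, a = a, y = as.vector(counts@values)[rows], sens = sens)
  })

  x <- rep(1, n * n)
  zeroSens <- Reduce(`&`, lapply(subsets, function(s) s$sens <= 0))
  if (any(zeroSens)) x[zeroSens] <- 0
  for (it in seq_len(params@nIterations)) {
    for (s in subsets) {
      m <- s$a * as.numeric(s$P %*% x)
      ratio <- ifelse(m > 0, s$y / m, 0)
      upd <- as.numeric(Matrix::crossprod(s$P, s$a * ratio))
      ok <- s$sens > 0
      x[ok] <- x[ok] * upd[ok] / s$sens[ok]
    }
  }
  img <- matrix(x, n, n)
  if (params@postfilterFwhm > 0)
    img <- gaussianPostfilter(img, params@postfilterFwhm, spacing)
  img
}

#' Gaussian post-filter
#'
#' Separable Gaussian convolution with
#' \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}, kernel truncated at
#' 4 sigma and normalized to unit sum; at the image borders the truncated
#' kernel is renormalized (normalized convolution), so constant images are
#' exactly invariant and interior intensity is preserved. FWHM 0 is the
#' identity.
#'
#' @param image numeric matrix.
#' @param fwhmMM filter FWHM in mm (>= 0).
#' @param spacing voxel spacing in mm.
#' @return filtered matrix.
#' @export
gaussianPostfilter <- function(image, fwhmMM, spacing) {
  if (fwhmMM < 0) stop("fwhm must be >= 0")
  if (fwhmMM == 0) return(image)
  sigma <- fwhmMM / (2 * sqrt(2 * log(2))) / spacing
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  band <- function(n) {
    M <- matrix(0, n, n)
    for (d in seq(-r, r)) {
      i <- seq_len(n); j <- i + d
      ok <- j >= 1 & j <= n
      M[cbind(i[ok], j[ok])] <- M[cbind(i[ok], j[ok])] + k[d + r + 1]
    }
    M / rowSums(M)   # border renormalization
  }
  n1 <- nrow(image); n2 <- ncol(image)
  B1 <- band(n1)
  B2 <- if (n2 == n1) B1 else band(n2)
  B1 %*% image %*% t(B2)
}
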