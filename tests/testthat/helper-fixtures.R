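# small shared fixtures; everything is generated in code

smallSpec <- function(seed = 1L, ...) {
  phantomSpec(gridSize = 64L, voxelSpacing = 4, seed = seed, ...)
}

smallGeom <- function(n = 64L, spacing = 4, nAngles = 48L) {
  defaultGeometry(n, spacing, nAngles)
}

smallRecon <- function(n = 64L, subsets = 8L, iters = 4L, fwhm = 2) {
  reconParams(matrixSize = n, nSubsets = subsets, nIterations = iters,
              postfilterFwhm = fwhm)
}

# an independent, deliberately naive MLEM reference: plain dense-ish loop
# over the full system matrix, no subsets, used to cross-check the OSEM code
referenceMlem <- function(counts, acf, nIter, n, spacing, countScale = 1) {
  P <- systemMatrix(counts@geometry, n, spacing)
  a <- as.vector(acf@values) * countScale
  y <- as.vector(counts@values)
  sens <- as.numeric(Matrix::crossprod(P, a))
  x <- rep(1, n * n)
  x[sens <= 0] <- 0
  for (it in seq_len(nIter)) {
    m <- a * as.numeric(P %*% x)
    ratio <- ifelse(m > 0, y / m, 0)
    upd <- as.numeric(Matrix::crossprod(P, a * ratio))
    ok <- sens > 0
    x[ok] <- x[ok] * upd[ok] / sens[ok]
  }
  matrix(x, n, n)
}

onesSinogram <- function(geom) {
  new("Sinogram", values = matrix(1, geom@nAngles, geom@nRadialBins),
      geometry = geom)
}
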