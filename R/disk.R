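#' Anti-aliased uniform disk image
#'
#' Centred uniform disk with supersampled (fractional-coverage) edge
#' voxels, so discrete line integrals approximate the analytic chord
#' integrals of the continuous disk closely — the standard digital-phantom
#' construction for projector oracles.
#'
#' @param n grid size (voxels per axis).
#' @param spacing voxel spacing in mm.
#' @param radiusMM disk radius in mm.
#' @param value disk value (default 1).
#' @param supersample subsamples per axis per voxel (default 8).
#' @return n x n matrix.
#' @export
diskPhantom <- function(n, spacing, radiusMM, value = 1, supersample = 8L) {
  r2 <- (radiusMM / spacing)^2
  ctr <- (n + 1) / 2
  off <- (seq_len(supersample) - 0.5) / supersample - 0.5
  img <- matrix(0, n, n)
  for (dr in off) for (dc in off) {
    rows <- row(img) + dr - ctr
    cols <- col(img) + dc - ctr
    img <- img + (rows^2 + cols^2 <= r2)
  }
  img * value / supersample^2
}
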