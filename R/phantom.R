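#' Default organ layout for the 2D coronal whole-body-like slice
#'
#' Ellipse centres/semi-axes as fractions of the grid (row = cranio-caudal,
#' col = left-right). `band` is the thoraco-abdominal row band inside which
#' respiratory deformation is allowed to act; `abdomen` is the box in which
#' air-filled bowel ellipses are drawn.
#'
#' @return named list of organ parameters.
#' @export
defaultOrganParams <- function() {
  list(
    body       = list(center = c(0.52, 0.50), semi = c(0.46, 0.32)),
    lung_left  = list(center = c(0.30, 0.38), semi = c(0.11, 0.09)),
    lung_right = list(center = c(0.30, 0.62), semi = c(0.11, 0.09)),
    liver      = list(center = c(0.47, 0.63), semi = c(0.085, 0.12),
                      activity_mult = 1.6),
    spine      = list(center = c(0.46, 0.50), semi = c(0.30, 0.030)),
    bladder    = list(center = c(0.82, 0.50), semi = c(0.045, 0.055)),
    abdomen    = list(rows = c(0.50, 0.72), cols = c(0.36, 0.64)),
    band       = c(0.18, 0.62),
    n_bowel_gas = c(1L, 3L),
    bowel_gas_semi_vox = c(1.0, 2.2)
  )
}

#' Default tissue table: HU means, HU texture SD and FDG-like activity
#'
#' Activity is in kBq/mL; with the synthetic cohort's dose/weight
#' distribution (about 317 MBq / 75 kg) soft tissue lands near SUV 1,
#' the bladder highest and the lungs lowest.
#'
#' @return data.frame with columns class, hu, hu_sd, activity.
#' @export
defaultTissueTable <- function() {
  data.frame(
    class    = TISSUE_CLASSES,
    hu       = c(-1000, -750,  40, 700,  45,   0),
    hu_sd    = c(    5,   40,  20,  80,  20,  10),
    activity = c(    0,  0.5,   4,   3,  20,  40),
    stringsAsFactors = FALSE
  )
}

#' Construct a phantom specification
#'
#' @param gridSize voxels per axis (square slice), default 64.
#' @param voxelSpacing voxel size in mm, default 4 (so a 64-voxel slice spans
#'   25.6 cm, a plausible body width).
#' @param organParams see [defaultOrganParams()].
#' @param lesionList list of lesions, each
#'   \code{list(center = c(fr, fc), radius_mm, multiplier)} with center as
#'   grid fractions.
#' @param respiratoryState scalar in [0, 1]; 0 = expiration reference.
#' @param maxShiftVox caudal diaphragm shift (voxels) at state 1, default 4.
#' @param bowelGasSeed seed for the air-filled bowel ellipses.
#' @param tissueTable see [defaultTissueTable()].
#' @param seed master seed for HU texture.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(gridSize = 64, seed = 1)
#' ph <- generatePhantom(spec)
#' @export
phantomSpec <- function(gridSize = 64L, voxelSpacing = 4,
                        organParams = defaultOrganParams(),
                        lesionList = list(),
                        respiratoryState = 0, maxShiftVox = 4,
                        bowelGasSeed = 1L,
                        tissueTable = defaultTissueTable(), seed = 1L) {
  new("PhantomSpec", gridSize = as.integer(gridSize),
      voxelSpacing = voxelSpacing, organParams = organParams,
      lesionList = lesionList, respiratoryState = respiratoryState,
      maxShiftVox = maxShiftVox, bowelGasSeed = as.integer(bowelGasSeed),
      tissueTable = tissueTable, seed = as.integer(seed))
}

# fraction-coordinate ellipse mask on an n x n grid
.ellipseMask <- function(n, center, semi) {
  fr <- (row(matrix(0, n, n)) - 0.5) / n
  fc <- (col(matrix(0, n, n)) - 0.5) / n
  ((fr - center[1]) / semi[1])^2 + ((fc - center[2]) / semi[2])^2 <= 1
}

#' Generate a labelled phantom slice from a specification
#'
#' Rasterizes the organ ellipses into a tissue label map, then derives the
#' HU map (per-class mean + seeded Gaussian texture, clipped to
#' [-1024, 3071]) and the activity map (per-class FDG-like level, organ
#' multipliers, lesion overrides; air carries zero activity). The lung lower
#' boundary is displaced caudally in proportion to the respiratory state, so
#' a spec regenerated at a different state yields a deterministically
#' deformed phantom with identical texture elsewhere.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [LabeledPhantom-class].
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  n <- spec@gridSize
  op <- spec@organParams
  tt <- spec@tissueTable
  lab <- matrix(match("air", TISSUE_CLASSES), n, n)
  idx <- function(cl) match(cl, TISSUE_CLASSES)

  body <- .ellipseMask(n, op$body$center, op$body$semi)
  lab[body] <- idx("soft")

  organMult <- matrix(1, n, n)
  liver <- .ellipseMask(n, op$liver$center, op$liver$semi) & body
  organMult[liver] <- op$liver$activity_mult

  # respiratory deformation: lung bottom extended caudally, apex fixed
  shiftFrac <- spec@respiratoryState * spec@maxShiftVox / n
  for (lung in list(op$lung_left, op$lung_right)) {
    ctr <- lung$center + c(shiftFrac / 2, 0)
    sem <- lung$semi + c(shiftFrac / 2, 0)
    m <- .ellipseMask(n, ctr, sem) & body
    lab[m] <- idx("lung")
  }

  spine <- .ellipseMask(n, op$spine$center, op$spine$semi) & body
  lab[spine] <- idx("bone")
  bladder <- .ellipseMask(n, op$bladder$center, op$bladder$semi) & body
  lab[bladder] <- idx("bladder")

  # air-filled bowel: random ellipses in the abdominal box, independent seed
  set.seed(spec@bowelGasSeed)
  gasRange <- seq(op$n_bowel_gas[1], op$n_bowel_gas[2])
  nGas <- if (length(gasRange) == 1L) gasRange else sample(gasRange, 1L)
  fr <- (row(lab) - 0.5) / n; fc <- (col(lab) - 0.5) / n
  abd <- fr >= op$abdomen$rows[1] & fr <= op$abdomen$rows[2] &
         fc >= op$abdomen$cols[1] & fc <= op$abdomen$cols[2]
  for (g in seq_len(nGas)) {
    ctr <- c(runif(1, op$abdomen$rows[1], op$abdomen$rows[2]),
             runif(1, op$abdomen$cols[1], op$abdomen$cols[2]))
    sem <- runif(2, op$bowel_gas_semi_vox[1], op$bowel_gas_semi_vox[2]) / n
    m <- .ellipseMask(n, ctr, sem) & abd & lab == idx("soft")
    lab[m] <- idx("air")
  }

  # lesions override the local class; centres must lie inside the body
  lesionMult <- matrix(NA_real_, n, n)
  for (les in spec@lesionList) {
    c01 <- les$center
    inBody <- ((c01[1] - op$body$center[1]) / op$body$semi[1])^2 +
              ((c01[2] - op$body$center[2]) / op$body$semi[2])^2 <= 1
    if (!inBody)
      stop("lesion centred at (", c01[1], ", ", c01[2],
           ") lies outside the body outline")
    rFrac <- les$radius_mm / spec@voxelSpacing / n
    m <- .ellipseMask(n, c01, c(rFrac, rFrac)) & body
    lab[m] <- idx("lesion")
    lesionMult[m] <- les$multiplier
  }

  # HU: class mean + per-class seeded texture field (locality: changing a
  # voxel's label changes only that voxel's HU)
  hu <- matrix(0, n, n)
  noise <- vector("list", length(TISSUE_CLASSES))
  for (k in seq_along(TISSUE_CLASSES)) {
    set.seed(spec@seed + 1000L * k)
    noise[[k]] <- matrix(rnorm(n * n), n, n)
  }
  for (k in seq_along(TISSUE_CLASSES)) {
    m <- lab == k
    hu[m] <- tt$hu[tt$class == TISSUE_CLASSES[k]] +
             tt$hu_sd[tt$class == TISSUE_CLASSES[k]] * noise[[k]][m]
  }
  hu <- pmin(pmax(hu, -1024), 3071)

  act <- matrix(0, n, n)
  for (k in seq_along(TISSUE_CLASSES)) {
    m <- lab == k
    act[m] <- tt$activity[tt$class == TISSUE_CLASSES[k]]
  }
  act <- act * organMult
  softAct <- tt$activity[tt$class == "soft"]
  lm <- !is.na(lesionMult)
  act[lm] <- softAct * lesionMult[lm]
  act[lab == idx("air")] <- 0

  new("LabeledPhantom", labels = lab, classLevels = TISSUE_CLASSES,
      hu = hu, activity = act, spacing = spec@voxelSpacing, spec = spec)
}

#' Deform a phantom to a different respiratory state
#'
#' Displaces the diaphragm (lung lower boundary) caudally by
#' \code{state * maxShiftVox} voxels with the smooth lateral falloff of the
#' lung ellipse; tissue outside the thoraco-abdominal band is untouched.
#' Implemented as deterministic regeneration from the stored spec, so the
#' texture fields are voxel-identical wherever the labels are unchanged.
#'
#' @param phantom a [LabeledPhantom-class].
#' @param state respiratory state in [0, 1] (0 = expiration reference).
#' @return a [LabeledPhantom-class] at the requested state.
#' @export
applyRespiratoryState <- function(phantom, state) {
  if (!is.numeric(state) || length(state) != 1 || state < 0 || state > 1)
    stop("state must be a scalar in [0, 1]")
  spec <- phantom@spec
  if (state == spec@respiratoryState) return(phantom)
  spec@respiratoryState <- state
  generatePhantom(spec)
}

#' Mask of the diaphragm band
#'
#' Voxels within `halfWidth` rows of the lung/soft interface, restricted to
#' columns containing lung — the region where respiratory-mismatch
#' ("banana") artifacts appear.
#'
#' @param phantom a [LabeledPhantom-class] (the PET-state anatomy).
#' @param halfWidth band half-width in voxels (default 3).
#' @return logical matrix.
#' @export
diaphragmBandMask <- function(phantom, halfWidth = 3) {
  lungIdx <- match("lung", phantom@classLevels)
  lab <- phantom@labels
  mask <- matrix(FALSE, nrow(lab), ncol(lab))
  for (j in which(apply(lab == lungIdx, 2, any))) {
    bottom <- max(which(lab[, j] == lungIdx))
    rows <- max(1, bottom - halfWidth):min(nrow(lab), bottom + halfWidth)
    mask[rows, j] <- TRUE
  }
  mask
}

#' Row index of the diaphragm (lung/soft interface) in a given column
#'
#' Utility used by the respiratory-mismatch analyses: the last lung-labelled
#' row in the column, or NA if the column contains no lung.
#'
#' @param phantom a [LabeledPhantom-class].
#' @param col column index (default: centre column of the right lung field).
#' @return integer row index or NA.
#' @export
diaphragmRow <- function(phantom, col = NULL) {
  lungIdx <- match("lung", phantom@classLevels)
  if (is.null(col)) {
    cols <- which(apply(phantom@labels == lungIdx, 2, any))
    if (!length(cols)) return(NA_integer_)
    col <- cols[ceiling(length(cols) * 3 / 4)]
  }
  rows <- which(phantom@labels[, col] == lungIdx)
  if (!length(rows)) return(NA_integer_)
  max(rows)
}
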