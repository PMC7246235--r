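#' Write a 2D image to NIfTI with isotropic spacing
#'
#' @param img numeric matrix.
#' @param path output path (.nii or .nii.gz).
#' @param spacing voxel spacing in mm.
#' @return the path, invisibly.
#' @export
writeImageNifti <- function(img, path, spacing) {
  nii <- RNifti::asNifti(img)
  RNifti::pixdim(nii) <- rep(spacing, length(dim(img)))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a 2D image written by [writeImageNifti()]
#'
#' @param path NIfTI file path.
#' @return numeric matrix with a `spacing` attribute (mm).
#' @export
readImageNifti <- function(path) {
  nii <- RNifti::readNifti(path)
  img <- as.array(nii)
  d <- dim(img)
  if (length(d) == 3 && d[3] == 1L) img <- img[, , 1L]
  structure(as.matrix(img), spacing = RNifti::pixdim(nii)[1])
}

#' Generate a paired synthetic dataset of activity / CT slices
#'
#' Creates \code{n} phantom pairs with per-case anatomical jitter, random
#' lesions, and per-case injected dose and body weight drawn from the
#' emulated cohort's distribution (317.3 +/- 8.6 MBq; 75.1 +/- 16 kg). A
#' fraction \code{mismatchFraction} of cases has the CT generated at a
#' different (inspiration-like) respiratory state than the activity map, and
#' with an independently re-drawn bowel-gas configuration — the two artifact
#' scenarios analysed downstream. Each case writes three NIfTI images:
#' the activity map (PET-state anatomy), the acquired CT (CT-state anatomy)
#' and the PET-state-aligned CT (ground-truth attenuation for simulation,
#' and the "oracle pseudo-CT" for mismatch analyses).
#'
#' @param n number of cases (>= 1).
#' @param baseSpec a [PhantomSpec-class] the per-case specs are derived from.
#' @param mismatchFraction fraction of cases with PET/CT respiratory-state
#'   mismatch, in [0, 1].
#' @param seed integer master seed.
#' @param outDir output directory (created if needed).
#' @param lesionRate expected number of lesions per case (Poisson), default 1.
#' @return the manifest data.frame (also written to
#'   \code{file.path(outDir, "manifest.csv")}); columns id, activity_path,
#'   ct_path, true_ct_path, dose_MBq, weight_kg, resp_state_pet,
#'   resp_state_ct, seed.
#' @export
makeDataset <- function(n, baseSpec, mismatchFraction, seed, outDir,
                        lesionRate = 1) {
  stopifnot(n >= 1, mismatchFraction >= 0, mismatchFraction <= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nMis <- round(n * mismatchFraction)
  set.seed(seed)
  misIdx <- if (nMis > 0) sort(sample.int(n, nMis)) else integer()

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    caseSeed <- as.integer(seed + 13L * i)
    set.seed(caseSeed)
    spec <- baseSpec
    # per-case anatomical jitter on organ centres/sizes
    op <- spec@organParams
    for (nm in c("body", "lung_left", "lung_right", "liver", "bladder")) {
      op[[nm]]$center <- op[[nm]]$center + runif(2, -0.015, 0.015)
      op[[nm]]$semi <- op[[nm]]$semi * runif(2, 0.92, 1.08)
    }
    spec@organParams <- op
    spec@seed <- caseSeed
    spec@bowelGasSeed <- caseSeed + 1L
    # random lesions in the torso
    nles <- rpois(1, lesionRate)
    les <- list()
    for (l in seq_len(nles)) {
      ctr <- c(runif(1, 0.30, 0.70), runif(1, 0.40, 0.60))
      les[[l]] <- list(center = ctr,
                       radius_mm = runif(1, 1.2, 2.5) * spec@voxelSpacing,
                       multiplier = runif(1, 3, 8))
    }
    spec@lesionList <- les

    dose <- max(rnorm(1, 317.3, 8.6), 100)
    weight <- min(max(rnorm(1, 75.1, 16), 40), 140)
    respPet <- 0
    respCt <- if (i %in% misIdx) runif(1, 0.5, 1) else respPet

    specPet <- spec
    specPet@respiratoryState <- respPet
    phPet <- generatePhantom(specPet)
    if (i %in% misIdx) {
      specCt <- spec
      specCt@respiratoryState <- respCt
      specCt@bowelGasSeed <- caseSeed + 2L   # bowel displaced on acquired CT
      phCt <- generatePhantom(specCt)
    } else phCt <- phPet

    id <- sprintf("case%03d", i)
    actPath <- file.path(outDir, paste0(id, "_activity.nii.gz"))
    ctPath <- file.path(outDir, paste0(id, "_ct.nii.gz"))
    trueCtPath <- file.path(outDir, paste0(id, "_truect.nii.gz"))
    writeImageNifti(activityMap(phPet), actPath, spec@voxelSpacing)
    writeImageNifti(huMap(phCt), ctPath, spec@voxelSpacing)
    writeImageNifti(huMap(phPet), trueCtPath, spec@voxelSpacing)

    rows[[i]] <- data.frame(
      id = id,
      activity_path = basename(actPath),
      ct_path = basename(ctPath),
      true_ct_path = basename(trueCtPath),
      dose_MBq = round(dose, 4), weight_kg = round(weight, 4),
      resp_state_pet = respPet, resp_state_ct = round(respCt, 6),
      seed = caseSeed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset manifest
#'
#' @param dir dataset directory containing manifest.csv.
#' @return manifest data.frame with a `dir` attribute.
#' @export
readManifest <- function(dir) {
  m <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  attr(m, "dir") <- dir
  m
}
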