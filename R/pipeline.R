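# face-connectivity connected components of a logical matrix
.connComp <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (v - 1L) %% n1 + 1L
      j <- (v - 1L) %/% n1 + 1L
      for (nb in c(if (i > 1) v - 1L, if (i < n1) v + 1L,
                   if (j > 1) v - n1, if (j < n2) v + n1)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

#' Derive the patient body mask from a CT image
#'
#' Largest face-connected component of voxels above a HU threshold
#' (default -500), with interior holes (air components not touching the
#' image border) filled. "Background" downstream means everything outside
#' this mask.
#'
#' @param ct HU image (matrix).
#' @param thresholdHU threshold (default -500).
#' @return logical matrix.
#' @export
deriveBodyMask <- function(ct, thresholdHU = -500) {
  mask <- ct > thresholdHU
  if (!any(mask)) stop("empty body mask: no voxels above threshold")
  lab <- .connComp(mask)
  sizes <- tabulate(lab[lab > 0L])
  body <- lab == which.max(sizes)
  # fill holes: background components not touching the border are interior
  bg <- .connComp(!body)
  if (max(bg) > 0L) {
    border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    interior <- setdiff(seq_len(max(bg)), border[border > 0L])
    body[bg %in% interior] <- TRUE
  }
  body
}

#' Copy the acquired CT's background into a pseudo-CT
#'
#' Inside the body mask the pseudo-CT is kept; outside, voxels are taken
#' from the acquired CT (scanner table, positioning devices, air), matching
#' the dual-reconstruction protocol in which both attenuation maps share
#' one background.
#'
#' @param ctGan pseudo-CT (matrix, HU).
#' @param ctAcquired acquired CT on the same grid.
#' @param bodyMask logical matrix.
#' @return patched pseudo-CT matrix.
#' @export
backgroundTransfer <- function(ctGan, ctAcquired, bodyMask) {
  if (!all(dim(ctGan) == dim(ctAcquired)) ||
      !all(dim(ctGan) == dim(bodyMask)))
    stop("grids do not match")
  out <- ctAcquired
  out[bodyMask] <- ctGan[bodyMask]
  out
}

#' Reconstruct one acquisition twice: with acquired CT and with pseudo-CT
#'
#' Both reconstructions share the counts, geometry and reconstruction
#' parameters; only the attenuation map differs, exactly as in a dual
#' reconstruction of one scan.
#'
#' @param counts a [Sinogram-class] of counts.
#' @param ctAcquired acquired CT (HU matrix).
#' @param ctGanPatched background-patched pseudo-CT on the same grid.
#' @param params a [ReconParams-class].
#' @param spacing voxel spacing in mm.
#' @param countScale acquisition count scale.
#' @param muWater,boneSlope HU-to-mu conversion parameters, see [huToMu()].
#' @return list(pet_ac, pet_gan) of reconstructed images.
#' @export
reconstructPair <- function(counts, ctAcquired, ctGanPatched, params,
                            spacing, countScale = 1, muWater = 0.096,
                            boneSlope = 5e-5) {
  if (!all(dim(ctAcquired) == dim(ctGanPatched)))
    stop("CT grids do not match")
  geom <- counts@geometry
  acfAc <- attenuationFactors(huToMu(ctAcquired, spacing, muWater,
                                     boneSlope), geom)
  acfGan <- attenuationFactors(huToMu(ctGanPatched, spacing, muWater,
                                      boneSlope), geom)
  list(pet_ac = mlemReconstruct(counts, acfAc, params, spacing, countScale),
       pet_gan = mlemReconstruct(counts, acfGan, params, spacing,
                                 countScale))
}

#' Train-and-evaluate translation experiment
#'
#' The package's core experiment in one call: generate a paired synthetic
#' cohort, assemble (PET_NAC, CT) training pairs, train the conditional GAN,
#' translate the held-out cases' PET_NAC into pseudo-CTs, reconstruct each
#' held-out acquisition twice (acquired CT vs background-patched pseudo-CT)
#' and quantify SUV deviations over the soft-tissue organ ROIs, alongside
#' the same deviations for the uncorrected (NAC) image as the
#' do-nothing baseline.
#'
#' @param nTrain,nTest training and held-out case counts.
#' @param epochs training epochs.
#' @param gridSize,spacing phantom grid (voxels) and voxel size (mm).
#' @param nAngles projection angles.
#' @param countScale acquisition count scale.
#' @param mismatchFraction respiratory-mismatch fraction of the training
#'   cohort. Held-out cases are generated respiratory-matched: this
#'   experiment measures translation fidelity; mismatch scenarios have
#'   their own analysis (see [diaphragmBandMask()]).
#' @param seed master seed for every stochastic step.
#' @param outDir working directory for the dataset.
#' @param lrG,lrD,batchSize optimisation schedule; the short desk-scale
#'   schedule uses a larger step and smaller batches than a long clinical
#'   training would.
#' @param softLabels ROI labels counted as soft tissue for the headline
#'   deviation.
#' @return list: `gan_abs_pct` / `nac_abs_pct` (mean absolute percent SUV
#'   deviation over soft-tissue ROIs, PET_GAN vs PET_AC and PET_NAC vs
#'   PET_AC), `hu_bland_altman` (per-ROI HU agreement across held-out
#'   cases), `perCase` (data.frame), `history`, `generator`.
#' @export
translationExperiment <- function(nTrain = 200L, nTest = 10L, epochs = 20L,
                                  gridSize = 64L, spacing = 4,
                                  nAngles = 48L, countScale = 20,
                                  mismatchFraction = 0.15, seed = 1L,
                                  outDir = tempfile("petacgan_exp"),
                                  lrG = 1e-3, lrD = 5e-4, batchSize = 4L,
                                  softLabels = c("blood pool", "liver",
                                                 "spleen")) {
  baseSpec <- phantomSpec(gridSize = gridSize, voxelSpacing = spacing,
                          seed = seed)
  trainDir <- file.path(outDir, "train")
  testDir <- file.path(outDir, "test")
  man <- makeDataset(nTrain, baseSpec, mismatchFraction, seed, trainDir)
  manTest <- makeDataset(nTest, baseSpec, 0, seed + 500000L, testDir)
  geom <- defaultGeometry(gridSize, spacing, nAngles)
  rp <- reconParams(matrixSize = gridSize, nSubsets = 8L, nIterations = 4L,
                    postfilterFwhm = 2)
  pairs <- prepareTrainingPairs(man, trainDir, geom, rp,
                                countScale = countScale, seed = seed)
  gen <- buildGenerator(seed = seed)
  disc <- buildDiscriminator(seed = seed + 1L)
  fit <- trainTranslator(pairs, gen, disc,
                         config = trainConfig(epochs = epochs,
                                              batchSize = batchSize,
                                              lrG = lrG, lrD = lrD,
                                              seed = seed))

  rois <- phantomOrganRois(generatePhantom(baseSpec))
  soft <- Filter(function(r) r@label %in% softLabels, rois)
  rows <- vector("list", nTest)
  huG <- c(); huC <- c()
  for (k in seq_len(nTest)) {
    r <- manTest[k, ]
    act <- readImageNifti(file.path(testDir, r$activity_path))
    ct <- readImageNifti(file.path(testDir, r$ct_path))
    trueCt <- readImageNifti(file.path(testDir, r$true_ct_path))
    counts <- simulateAcquisition(act, huToMu(trueCt, spacing), geom,
                                  countScale, seed = seed + 7000L + k)
    nac <- mlemReconstruct(counts, "ones", rp, spacing,
                           countScale = countScale)
    ctGan <- translateVolume(nac, fit$generator)
    mask <- deriveBodyMask(ct)
    ctp <- backgroundTransfer(ctGan, ct, mask)
    pr <- reconstructPair(counts, ct, ctp, rp, spacing,
                          countScale = countScale)
    md <- list(dose_MBq = r$dose_MBq, weight_kg = r$weight_kg)
    repG <- evaluateRun(pr$pet_ac, pr$pet_gan, ct, ctp, soft, list(),
                        spacing, md)
    repN <- evaluateRun(pr$pet_ac, nac, ct, ct, soft, list(), spacing, md)
    rows[[k]] <- data.frame(id = r$id,
                            gan_abs_pct = mean(repG@organ$abs_pct_diff),
                            nac_abs_pct = mean(repN@organ$abs_pct_diff))
    huG <- c(huG, repG@hu$hu_gan); huC <- c(huC, repG@hu$hu_ct)
  }
  perCase <- do.call(rbind, rows)
  list(gan_abs_pct = mean(perCase$gan_abs_pct),
       nac_abs_pct = mean(perCase$nac_abs_pct),
       hu_bland_altman = blandAltman(huG, huC),
       perCase = perCase, history = fit$history, generator = fit$generator)
}

#' Default full-run configuration
#'
#' Desk-scale defaults: 64 x 64 slices at 4 mm, 48 angles, 8 subsets x 4
#' iterations with a 2-mm post-filter, and a small cascaded GAN.
#'
#' @param outDir run directory.
#' @param seed master seed.
#' @return nested config list understood by [fullRun()].
#' @export
defaultRunConfig <- function(outDir = tempfile("petacgan_run"), seed = 1L) {
  list(
    out_dir = outDir, seed = as.integer(seed),
    phantom = list(grid_size = 64L, voxel_spacing = 4,
                   n_train = 40L, n_test = 5L, mismatch_fraction = 0.2,
                   lesion_rate = 1),
    physics = list(n_angles = 48L, count_scale = 20,
                   n_subsets = 8L, n_iterations = 4L, postfilter_fwhm = 2),
    gan = list(n_cascades = 4L, unet_depth = 2L, base_channels = 8L,
               epochs = 6L, batch_size = 4L, lr_g = 1e-3, lr_d = 5e-4,
               lambda_adv = 1, lambda_perceptual = 10, lambda_style = 10,
               lambda_content = 10),
    evaluation = list(lesion_fraction = 0.5))
}

#' Run the full pipeline: simulate, train, translate, reconstruct, evaluate
#'
#' Orchestrates the whole experiment on synthetic data: dataset generation,
#' PET_NAC reconstruction of the training cases, GAN training, pseudo-CT
#' translation of held-out cases, background transfer, dual reconstruction
#' (PET_AC with acquired CT, PET_GAN with pseudo-CT) and the quantitative
#' evaluation. Writes the dataset, a checkpoint, per-case reports and a
#' provenance JSON into the run directory. Fully deterministic for a fixed
#' config.
#'
#' @param config nested config list (see [defaultRunConfig()]) or the path
#'   of a YAML file holding one.
#' @return list with `manifest`, `history`, `reports` (per test case
#'   [DeviationReport-class]s), `summary` (aggregate data.frame) and
#'   `runDir`.
#' @export
fullRun <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- config$phantom; phy <- config$physics; g <- config$gan
  seed <- config$seed

  baseSpec <- phantomSpec(gridSize = ph$grid_size,
                          voxelSpacing = ph$voxel_spacing, seed = seed)
  nTot <- ph$n_train + ph$n_test
  dataDir <- file.path(config$out_dir, "data")
  manifest <- makeDataset(nTot, baseSpec, ph$mismatch_fraction, seed,
                          dataDir, lesionRate = ph$lesion_rate)
  trainIdx <- seq_len(ph$n_train)
  testIdx <- ph$n_train + seq_len(ph$n_test)

  geom <- defaultGeometry(ph$grid_size, ph$voxel_spacing,
                          nAngles = phy$n_angles)
  rp <- reconParams(matrixSize = ph$grid_size, nSubsets = phy$n_subsets,
                    nIterations = phy$n_iterations,
                    postfilterFwhm = phy$postfilter_fwhm)

  pairs <- prepareTrainingPairs(manifest[trainIdx, ], dataDir, geom, rp,
                                countScale = phy$count_scale, seed = seed)
  gen <- buildGenerator(generatorSpec(g$n_cascades, g$unet_depth,
                                      g$base_channels), seed = seed)
  disc <- buildDiscriminator(seed = seed + 1L)
  fit <- trainTranslator(pairs, gen, disc,
                         lossWeights(g$lambda_adv, g$lambda_perceptual,
                                     g$lambda_style, g$lambda_content),
                         trainConfig(g$epochs, g$batch_size, g$lr_g, g$lr_d,
                                     seed = seed))
  ckpt <- file.path(config$out_dir, "generator.rds")
  saveTranslator(fit$generator, ckpt)

  reports <- list()
  for (i in testIdx) {
    r <- manifest[i, ]
    act <- readImageNifti(file.path(dataDir, r$activity_path))
    ct <- readImageNifti(file.path(dataDir, r$ct_path))
    trueCt <- readImageNifti(file.path(dataDir, r$true_ct_path))
    sp <- ph$voxel_spacing
    counts <- simulateAcquisition(act, huToMu(trueCt, sp), geom,
                                  phy$count_scale, seed = seed + 7000L + i)
    nac <- mlemReconstruct(counts, "ones", rp, sp,
                           countScale = phy$count_scale)
    ctGan <- translateVolume(nac, fit$generator)
    mask <- deriveBodyMask(ct)
    ctGanPatched <- backgroundTransfer(ctGan, ct, mask)
    pr <- reconstructPair(counts, ct, ctGanPatched, rp, sp,
                          countScale = phy$count_scale)
    rois <- phantomOrganRois(generatePhantom(baseSpec))
    rep <- evaluateRun(pr$pet_ac, pr$pet_gan, ct, ctGanPatched, rois,
                       lesionSeeds = list(), spacing = sp,
                       metadata = list(dose_MBq = r$dose_MBq,
                                       weight_kg = r$weight_kg),
                       outDir = file.path(config$out_dir, r$id))
    reports[[r$id]] <- rep
  }
  organAll <- do.call(rbind, lapply(names(reports), function(id)
    cbind(case = id, reports[[id]]@organ)))
  summary <- data.frame(
    n_cases = length(reports),
    mean_pct_diff = mean(organAll$pct_diff, na.rm = TRUE),
    mean_abs_pct_diff = mean(organAll$abs_pct_diff, na.rm = TRUE))
  write.csv(organAll, file.path(config$out_dir, "organ_metrics.csv"),
            row.names = FALSE)
  prov <- list(config = config,
               package_version = as.character(utils::packageVersion("petacgan")),
               history_final = as.list(fit$history[nrow(fit$history), ]))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, history = fit$history, reports = reports,
       summary = summary, runDir = config$out_dir)
}
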