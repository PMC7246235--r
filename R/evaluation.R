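#' Compute a standardized uptake value image
#'
#' Body-weight SUV with the 1 g/mL tissue-density convention:
#' \deqn{SUV = C_{kBq/mL} \cdot w_{kg} / D_{MBq}}
#' (the unit factors cancel exactly in these units).
#'
#' @param activity activity-concentration image in kBq/mL (nonnegative).
#' @param doseMBq injected dose in MBq (> 0).
#' @param weightKg body weight in kg (> 0).
#' @return SUV matrix (dimensionless).
#' @examples
#' computeSUV(matrix(5), 300, 75)  # 1.25
#' @export
computeSUV <- function(activity, doseMBq, weightKg) {
  if (doseMBq <= 0 || weightKg <= 0)
    stop("dose and weight must be positive")
  activity * weightKg / doseMBq
}

#' Construct a circular ROI
#'
#' @param center voxel coordinates c(row, col).
#' @param radiusMM radius in mm.
#' @param label organ label.
#' @return a [CircularROI-class].
#' @export
circularROI <- function(center, radiusMM, label = "roi") {
  new("CircularROI", center = as.numeric(center), radiusMM = radiusMM,
      label = label)
}

# voxel membership of a circular ROI (same set for any co-registered image)
.roiVoxels <- function(dims, roi, spacing) {
  rVox <- roi@radiusMM / spacing
  rows <- row(matrix(0, dims[1], dims[2])) - roi@center[1]
  cols <- col(matrix(0, dims[1], dims[2])) - roi@center[2]
  m <- which(rows^2 + cols^2 <= max(rVox, 1e-9)^2)
  if (!length(m)) {  # degenerate ROI: the single containing voxel
    m <- round(roi@center[1]) + dims[1] * (round(roi@center[2]) - 1)
  }
  m
}

#' Mean image value over a circular ROI
#'
#' The voxel set is determined once by centre/radius, so applying the same
#' ROI to co-registered images uses identical voxels (the "copy to
#' PET_GAN" semantics: no re-placement).
#'
#' @param image numeric matrix.
#' @param roi a [CircularROI-class].
#' @param spacing voxel spacing in mm.
#' @return scalar mean.
#' @export
extractRoiMean <- function(image, roi, spacing) {
  if (roi@center[1] < 1 || roi@center[1] > nrow(image) ||
      roi@center[2] < 1 || roi@center[2] > ncol(image))
    stop("ROI centre out of bounds")
  mean(image[.roiVoxels(dim(image), roi, spacing)])
}

#' Standard organ-analog ROIs for a phantom
#'
#' Circular ROIs at the phantom analogs of the clinical protocol's organ
#' set: both lungs, a mediastinal soft-tissue ("blood pool") site, liver,
#' bladder and two spine (bone) sites.
#'
#' @param phantom a [LabeledPhantom-class].
#' @param radiusMM ROI radius in mm (default 2 voxels' worth).
#' @return named list of [CircularROI-class].
#' @export
phantomOrganRois <- function(phantom, radiusMM = 2 * gridSpacing(phantom)) {
  op <- phantomSpecOf(phantom)@organParams
  n <- nrow(huMap(phantom))
  sp <- gridSpacing(phantom)
  at <- function(fr) fr * n + 0.5
  mk <- function(c01, label, r = radiusMM)
    circularROI(c(at(c01[1]), at(c01[2])), r, label)
  # sites chosen to stay inside their organ under the dataset's anatomical
  # jitter: mediastinal/abdominal soft sites clear of lung, spine, liver,
  # bladder and the bowel-gas box; spine ROIs are narrower than the column
  list(
    left_lung = mk(op$lung_left$center - c(0.02, 0), "left lung"),
    right_lung = mk(op$lung_right$center - c(0.02, 0), "right lung"),
    blood_pool = mk(c(0.73, 0.40), "blood pool"),
    liver = mk(op$liver$center, "liver"),
    soft_abdomen = mk(c(0.62, 0.30), "spleen"),
    bladder = mk(op$bladder$center, "bladder"),
    spine_th = mk(c(op$spine$center[1] - 0.12, op$spine$center[2]), "Th8",
                  r = 1.2 * sp),
    spine_l = mk(c(op$spine$center[1] + 0.12, op$spine$center[2]), "L3",
                 r = 1.2 * sp))
}

#' Isocontour VOI around a focal uptake site
#'
#' Finds the local maximum within `searchRadius` voxels of the seed, then
#' grows the face-connected component of voxels at or above
#' \code{fraction * max} that contains the maximum. Recomputed
#' independently per image (isocontours are adjusted after ROI transfer).
#'
#' @param image numeric matrix (e.g. SUV).
#' @param seedPoint voxel coordinates c(row, col) near the lesion.
#' @param fraction threshold fraction of the local max (default 0.5).
#' @param searchRadius search radius in voxels for the local max (default 3).
#' @return an [IsocontourVOI-class].
#' @export
isocontourVoi <- function(image, seedPoint, fraction = 0.5,
                          searchRadius = 3) {
  n1 <- nrow(image); n2 <- ncol(image)
  i0 <- round(seedPoint[1]); j0 <- round(seedPoint[2])
  ii <- max(1, i0 - searchRadius):min(n1, i0 + searchRadius)
  jj <- max(1, j0 - searchRadius):min(n2, j0 + searchRadius)
  sub <- image[ii, jj, drop = FALSE]
  if (max(sub) <= 0)
    stop("no positive uptake near the seed point")
  w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  peak <- c(ii[w[1]], jj[w[2]])
  thr <- fraction * image[peak[1], peak[2]]
  mask <- image >= thr
  lab <- .connComp(mask)
  comp <- lab == lab[peak[1], peak[2]]
  mem <- which(comp, arr.ind = TRUE)
  new("IsocontourVOI", members = mem, peak = as.numeric(peak),
      peakValue = image[peak[1], peak[2]], fraction = fraction)
}

#' The four SUV deviation metrics between paired measurements
#'
#' difference (GAN - AC), absolute difference, percent difference
#' \eqn{100 (GAN - AC)/AC} and absolute percent difference. Percent
#' metrics are flagged missing (NA with `pct_defined = FALSE`) when the
#' reference is zero.
#'
#' @param suvGan scalar measurement on PET_GAN.
#' @param suvAc scalar reference measurement on PET_AC.
#' @return one-row data.frame: diff, abs_diff, pct_diff, abs_pct_diff,
#'   pct_defined.
#' @export
deviationMetrics <- function(suvGan, suvAc) {
  d <- suvGan - suvAc
  if (suvAc == 0) {
    data.frame(diff = d, abs_diff = abs(d), pct_diff = NA_real_,
               abs_pct_diff = NA_real_, pct_defined = FALSE)
  } else {
    p <- 100 * d / suvAc
    data.frame(diff = d, abs_diff = abs(d), pct_diff = p,
               abs_pct_diff = abs(p), pct_defined = TRUE)
  }
}

#' Voxel-wise percent difference map
#'
#' \eqn{100 (GAN - AC)/AC} wherever the reference exceeds a floor
#' (default 1\% of its maximum); elsewhere the map is 0 and the validity
#' mask FALSE, so air never produces division blow-ups.
#'
#' @param petGan,petAc co-registered images.
#' @param floor validity floor (default \code{0.01 * max(petAc)}).
#' @return list(map, valid).
#' @export
differenceMap <- function(petGan, petAc, floor = 0.01 * max(petAc)) {
  if (!all(dim(petGan) == dim(petAc))) stop("images are not co-registered")
  valid <- petAc > floor
  map <- matrix(0, nrow(petAc), ncol(petAc))
  map[valid] <- 100 * (petGan[valid] - petAc[valid]) / petAc[valid]
  list(map = map, valid = valid)
}

#' Bland-Altman agreement analysis
#'
#' Differences a - b; limits of agreement at the mean difference plus or
#' minus 2 sample standard deviations (n - 1).
#'
#' @param valuesA,valuesB equal-length paired samples (n >= 2).
#' @return list: mean_diff, sd_diff, loa_low, loa_high, means, diffs.
#' @export
blandAltman <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB)) stop("samples must be paired")
  if (length(valuesA) < 2) stop("need at least 2 pairs")
  d <- valuesA - valuesB
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, sd_diff = s, loa_low = m - 2 * s, loa_high = m + 2 * s,
       means = (valuesA + valuesB) / 2, diffs = d)
}

#' Box-plot summary statistics
#'
#' Mean, median, linear-interpolation quartiles, whiskers at the most
#' extreme sample points within 1.5 IQR of the box, and outliers beyond.
#'
#' @param sample nonempty numeric vector.
#' @return list: mean, median, q1, q3, whisker_low, whisker_high, outliers.
#' @export
boxStats <- function(sample) {
  sample <- sample[is.finite(sample)]
  if (!length(sample)) stop("empty sample")
  q <- as.numeric(quantile(sample, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  lowFence <- q[1] - 1.5 * iqr
  highFence <- q[2] + 1.5 * iqr
  inside <- sample[sample >= lowFence & sample <= highFence]
  list(mean = mean(sample), median = median(sample), q1 = q[1], q3 = q[2],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(sample[sample < lowFence | sample > highFence]))
}

#' Full quantitative evaluation of a dual reconstruction
#'
#' Computes SUV images for both reconstructions, extracts per-organ ROI
#' deviation metrics (identical voxel sets on both images), per-lesion
#' SUV_mean/SUV_max metrics with the isocontour VOI recomputed
#' independently per image, per-ROI mean HU on CT and pseudo-CT with
#' Bland-Altman agreement, and box-plot summaries of the percent
#' deviations. Optionally writes a tidy CSV and a summary JSON.
#'
#' @param petAc,petGan reconstructed activity images (kBq/mL).
#' @param ct,ctGan acquired CT and (patched) pseudo-CT in HU.
#' @param rois list of [CircularROI-class].
#' @param lesionSeeds list of voxel coordinates c(row, col) of focal
#'   uptake sites (possibly empty).
#' @param spacing voxel spacing in mm.
#' @param metadata list with dose_MBq and weight_kg.
#' @param fraction isocontour fraction (default 0.5).
#' @param outDir optional output directory for report files.
#' @return a [DeviationReport-class].
#' @export
evaluateRun <- function(petAc, petGan, ct, ctGan, rois, lesionSeeds = list(),
                        spacing, metadata, fraction = 0.5, outDir = NULL) {
  suvAc <- computeSUV(petAc, metadata$dose_MBq, metadata$weight_kg)
  suvGan <- computeSUV(petGan, metadata$dose_MBq, metadata$weight_kg)

  organRows <- lapply(rois, function(roi) {
    a <- extractRoiMean(suvAc, roi, spacing)
    g <- extractRoiMean(suvGan, roi, spacing)
    cbind(data.frame(label = roi@label, suv_ac = a, suv_gan = g),
          deviationMetrics(g, a))
  })
  organ <- do.call(rbind, c(organRows, list(make.row.names = FALSE)))

  lesRows <- lapply(seq_along(lesionSeeds), function(k) {
    sAc <- isocontourVoi(suvAc, lesionSeeds[[k]], fraction)
    sGan <- isocontourVoi(suvGan, lesionSeeds[[k]], fraction)
    vAc <- suvAc[voiMembers(sAc)]; vGan <- suvGan[voiMembers(sGan)]
    rbind(cbind(data.frame(lesion = k, metric = "suv_mean",
                           suv_ac = mean(vAc), suv_gan = mean(vGan)),
                deviationMetrics(mean(vGan), mean(vAc))),
          cbind(data.frame(lesion = k, metric = "suv_max",
                           suv_ac = max(vAc), suv_gan = max(vGan)),
                deviationMetrics(max(vGan), max(vAc))))
  })
  lesions <- if (length(lesRows))
    do.call(rbind, c(lesRows, list(make.row.names = FALSE)))
  else data.frame(lesion = integer(), metric = character(),
                  suv_ac = numeric(), suv_gan = numeric(),
                  diff = numeric(), abs_diff = numeric(),
                  pct_diff = numeric(), abs_pct_diff = numeric(),
                  pct_defined = logical())

  huRows <- lapply(rois, function(roi)
    data.frame(label = roi@label,
               hu_ct = extractRoiMean(ct, roi, spacing),
               hu_gan = extractRoiMean(ctGan, roi, spacing)))
  hu <- do.call(rbind, c(huRows, list(make.row.names = FALSE)))

  ba <- list(hu = blandAltman(hu$hu_gan, hu$hu_ct))
  if (nrow(lesions) >= 4) {
    mm <- lesions[lesions$metric == "suv_mean", ]
    xx <- lesions[lesions$metric == "suv_max", ]
    if (nrow(mm) >= 2) ba$lesion_suv_mean <- blandAltman(mm$suv_gan,
                                                         mm$suv_ac)
    if (nrow(xx) >= 2) ba$lesion_suv_max <- blandAltman(xx$suv_gan,
                                                        xx$suv_ac)
  }
  bs <- list(organ_pct = boxStats(organ$pct_diff))

  rep <- new("DeviationReport", organ = organ, lesions = lesions, hu = hu,
             blandAltman = ba, boxStats = bs)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(organ, file.path(outDir, "organ_metrics.csv"),
              row.names = FALSE)
    if (nrow(lesions))
      write.csv(lesions, file.path(outDir, "lesion_metrics.csv"),
                row.names = FALSE)
    write.csv(hu, file.path(outDir, "hu_metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(bland_altman = lapply(ba, function(x) x[c("mean_diff", "sd_diff",
                                                     "loa_low", "loa_high")]),
           box_stats = bs),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  rep
}
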