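test_that("SUV computation follows the body-weight convention", {
  expect_equal(computeSUV(matrix(5), 300, 75)[1], 1.25)
  expect_equal(computeSUV(matrix(0), 300, 75)[1], 0)
  expect_equal(computeSUV(matrix(5), 300, 150)[1], 2.5)  # linear in weight
  expect_error(computeSUV(matrix(5), 0, 75), "positive")
  expect_error(computeSUV(matrix(5), 300, -1), "positive")
})

test_that("circular ROI means use one fixed voxel set", {
  img <- matrix(7, 32, 32)
  roi <- circularROI(c(16, 16), 10, "x")
  expect_equal(extractRoiMean(img, roi, 4), 7)

  # copy semantics: the same ROI on co-registered images reads the same
  # voxels — encode membership with an indicator image
  ind <- matrix(0, 32, 32)
  ind[petacgan:::.roiVoxels(c(32, 32), roi, 4)] <- 1
  expect_equal(extractRoiMean(ind, roi, 4), 1)

  # degenerate radius: single containing voxel
  tiny <- circularROI(c(5, 9), 0.5, "tiny")
  img2 <- matrix(seq_len(32 * 32), 32, 32)
  expect_equal(extractRoiMean(img2, tiny, 4), img2[5, 9])

  expect_error(extractRoiMean(img, circularROI(c(100, 5), 4, "o"), 4),
               "bounds")
})

test_that("isocontour VOIs threshold at a fraction of the local max", {
  # 1D profile 4 6 10 6 4 at 50%: members are the voxels valued 10, 6, 6
  prof <- matrix(c(4, 6, 10, 6, 4), 1, 5)
  v <- isocontourVoi(prof, c(1, 3), 0.5)
  expect_setequal(prof[voiMembers(v)], c(10, 6, 6))

  # uniform hot disk: the whole disk is included
  img <- matrix(0, 32, 32)
  disk <- (row(img) - 16)^2 + (col(img) - 16)^2 <= 36
  img[disk] <- 5
  v2 <- isocontourVoi(img, c(16, 16), 0.5)
  expect_equal(nrow(voiMembers(v2)), sum(disk))

  # two hot spots separated by a sub-threshold gap: only the seeded one
  img3 <- matrix(0, 21, 21)
  img3[5:7, 5:7] <- 10
  img3[15:17, 15:17] <- 9
  img3[10, 10] <- 2      # below 50% of either max
  v3 <- isocontourVoi(img3, c(6, 6), 0.5)
  expect_equal(nrow(voiMembers(v3)), 9)
  expect_true(all(img3[voiMembers(v3)] == 10))

  expect_error(isocontourVoi(matrix(0, 9, 9), c(5, 5)), "positive uptake")
})

test_that("deviation metrics implement the four printed formulas", {
  r <- deviationMetrics(2.0, 2.5)
  expect_equal(r$diff, -0.5); expect_equal(r$abs_diff, 0.5)
  expect_equal(r$pct_diff, -20); expect_equal(r$abs_pct_diff, 20)

  z <- deviationMetrics(1.7, 1.7)
  expect_true(all(unlist(z[c("diff", "abs_diff", "pct_diff",
                             "abs_pct_diff")]) == 0))
  expect_equal(deviationMetrics(1.1, 1.0)$pct_diff, 10, tolerance = 1e-12)

  # zero reference: percent metrics flagged missing, not NaN
  zr <- deviationMetrics(1, 0)
  expect_false(zr$pct_defined)
  expect_true(is.na(zr$pct_diff))
  expect_equal(zr$diff, 1)

  # antisymmetry: swapping arguments negates diff and maps
  # pct -> -100 pct / (100 + pct)
  a <- 1.3; b <- 2.1
  f <- deviationMetrics(a, b); g <- deviationMetrics(b, a)
  expect_equal(g$diff, -f$diff)
  expect_equal(g$pct_diff, -100 * f$pct_diff / (100 + f$pct_diff),
               tolerance = 1e-12)
  expect_equal(g$abs_diff, f$abs_diff)
})

test_that("difference maps mask low-signal voxels instead of dividing", {
  ac <- matrix(c(0, 1, 2, 4), 2, 2)
  r <- differenceMap(ac * 1.05, ac)
  expect_equal(r$map[r$valid], rep(5, sum(r$valid)), tolerance = 1e-12)
  expect_false(r$valid[1, 1])
  expect_equal(r$map[1, 1], 0)

  same <- differenceMap(ac, ac)
  expect_true(all(same$map == 0))

  expect_error(differenceMap(matrix(0, 2, 2), matrix(0, 3, 3)),
               "co-registered")
})

test_that("Bland-Altman limits are mean difference +/- 2 sample SD", {
  r <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$mean_diff, 0); expect_equal(r$sd_diff, 0)
  expect_equal(c(r$loa_low, r$loa_high), c(0, 0))

  # diffs {-1, +1}: sd = sqrt(2) with n-1, loa = +/- 2 sqrt(2)
  r2 <- blandAltman(c(0, 2), c(1, 1))
  expect_equal(r2$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(r2$loa_low, -2 * sqrt(2), tolerance = 1e-12)
  expect_equal(r2$loa_high, 2 * sqrt(2), tolerance = 1e-12)
  expect_true(r2$loa_low <= r2$mean_diff && r2$mean_diff <= r2$loa_high)

  # adding a constant to both series changes nothing
  a <- rnorm(10); b <- rnorm(10)
  r3 <- blandAltman(a, b); r4 <- blandAltman(a + 5, b + 5)
  expect_equal(r3[c("mean_diff", "sd_diff", "loa_low", "loa_high")],
               r4[c("mean_diff", "sd_diff", "loa_low", "loa_high")])
  expect_error(blandAltman(1, numeric(0)), "paired")
  expect_error(blandAltman(1, 1), "at least 2")
})

test_that("box statistics follow the 1.5 IQR fence rule", {
  r <- boxStats(c(1, 2, 3, 4, 5))
  expect_equal(r$median, 3); expect_equal(r$q1, 2); expect_equal(r$q3, 4)
  expect_length(r$outliers, 0)
  expect_equal(r$whisker_low, 1); expect_equal(r$whisker_high, 5)

  cst <- boxStats(rep(2.5, 6))
  expect_true(all(unlist(cst[c("mean", "median", "q1", "q3", "whisker_low",
                               "whisker_high")]) == 2.5))
  expect_length(cst$outliers, 0)

  out <- boxStats(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)   # beyond q3 + 1.5 IQR
  expect_equal(out$whisker_high, 4)
  expect_error(boxStats(numeric(0)), "empty")
})

test_that("evaluateRun assembles a complete, internally consistent report", {
  set.seed(12)
  ph <- generatePhantom(smallSpec(
    seed = 6,
    lesionList = list(list(center = c(0.45, 0.58), radius_mm = 8,
                           multiplier = 6))))
  act <- activityMap(ph); ct <- huMap(ph)
  rois <- phantomOrganRois(ph)
  lesionSeed <- list(c(0.45 * 64, 0.58 * 64))
  md <- list(dose_MBq = 317, weight_kg = 75)

  # identity run: everything must be exactly zero
  rep0 <- evaluateRun(act, act, ct, ct, rois, lesionSeed, 4, md)
  expect_true(all(rep0@organ$diff == 0))
  expect_true(all(rep0@organ$pct_diff == 0))
  expect_true(all(rep0@lesions$diff == 0))
  expect_equal(rep0@blandAltman$hu$loa_low, 0)
  expect_equal(rep0@blandAltman$hu$loa_high, 0)

  # row counts: one row per organ; two metric rows per lesion
  expect_equal(nrow(rep0@organ), length(rois))
  expect_equal(nrow(rep0@lesions), 2 * length(lesionSeed))

  # perturbed run: aggregate equals the mean of per-ROI percent deviations
  gan <- act * 1.07
  rep1 <- evaluateRun(act, gan, ct, ct, rois, lesionSeed, 4, md)
  expect_equal(rep1@boxStats$organ_pct$mean, mean(rep1@organ$pct_diff),
               tolerance = 1e-12)
  expect_equal(rep1@organ$pct_diff, rep(7, length(rois)), tolerance = 1e-9)

  # organ ROI voxel sets are shared; lesion VOIs are recomputed per image:
  # grow an above-threshold arm attached to the lesion on one image only
  shifted <- act
  peak <- max(act[27:31, 35:39])
  shifted[29, 39:44] <- peak
  repL <- evaluateRun(act, shifted, ct, ct, rois, lesionSeed, 4, md)
  vAc <- isocontourVoi(computeSUV(act, 317, 75), lesionSeed[[1]], 0.5)
  vGan <- isocontourVoi(computeSUV(shifted, 317, 75), lesionSeed[[1]], 0.5)
  expect_gt(nrow(voiMembers(vGan)), nrow(voiMembers(vAc)))

  # report files
  d <- withr::local_tempdir()
  evaluateRun(act, gan, ct, ct, rois, lesionSeed, 4, md, outDir = d)
  expect_true(file.exists(file.path(d, "organ_metrics.csv")))
  expect_true(file.exists(file.path(d, "summary.json")))
})
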