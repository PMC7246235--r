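test_that("HU to mu conversion matches the bilinear curve", {
  m <- huToMu(matrix(c(-1000, 0, 1000), 1, 3), spacing = 4)
  expect_equal(muValues(m)[1], 0)
  expect_equal(muValues(m)[2], 0.096)
  expect_equal(muValues(m)[3], 0.096 + 1000 * 5e-5)  # 0.146
  # configurable parameters
  m2 <- huToMu(matrix(0), 4, muWater = 0.1)
  expect_equal(muValues(m2)[1], 0.1)
  # clamp below -1024 with warning; never negative
  expect_warning(m3 <- huToMu(matrix(-2000), 4), "clamped")
  expect_gte(muValues(m3)[1], 0)
})

test_that("forward projection matches analytic disk chords", {
  g <- smallGeom(64, 4, 48)
  img <- diskPhantom(64, 4, 80, value = 2)   # radius 8 cm, value 2
  s <- forwardProject(img, g, 4)
  mid <- (ncol(sinoValues(s)) + 1) / 2
  cent <- sinoValues(s)[, mid]
  expect_lt(max(abs(cent - 2 * 2 * 8) / (2 * 2 * 8)), 0.01)

  # rotational symmetry: every angle sees the same central profile
  off <- sinoValues(s)[, mid + 10]
  expect_lt(diff(range(off)) / mean(off), 0.03)

  # zero image, zero sinogram; linearity to machine precision
  expect_true(all(sinoValues(forwardProject(img * 0, g, 4)) == 0))
  img2 <- diskPhantom(64, 4, 40, value = 1)
  lin <- sinoValues(forwardProject(2 * img + 3 * img2, g, 4))
  expect_equal(lin, 2 * sinoValues(forwardProject(img, g, 4)) +
                    3 * sinoValues(forwardProject(img2, g, 4)),
               tolerance = 1e-12)
})

test_that("attenuation factors follow Beer-Lambert on a disk", {
  g <- smallGeom(64, 4, 48)
  mu0 <- new("MuMap", mu = matrix(0, 64, 64), spacing = 4)
  expect_true(all(sinoValues(attenuationFactors(mu0, g)) == 1))

  # 20-cm water disk: central transmission exp(-0.096 * 20)
  mu <- new("MuMap", mu = diskPhantom(64, 4, 100, value = 0.096),
            spacing = 4)
  a <- attenuationFactors(mu, g)
  mid <- (ncol(sinoValues(a)) + 1) / 2
  cent <- sinoValues(a)[, mid]
  expect_lt(max(abs(cent - exp(-1.92)) / exp(-1.92)), 0.01)
  # rays missing the object are unattenuated; all factors in (0, 1]
  expect_equal(unname(sinoValues(a)[1, 1]), 1)
  expect_true(all(sinoValues(a) > 0 & sinoValues(a) <= 1))

  # monotone: raising mu anywhere can only lower the factors
  mu2 <- new("MuMap", mu = muValues(mu) + 0.01, spacing = 4)
  expect_true(all(sinoValues(attenuationFactors(mu2, g)) <=
                  sinoValues(a) + 1e-12))
})

test_that("acquisition simulation is seeded Poisson with the right mean", {
  g <- smallGeom(64, 4, 48)
  act <- diskPhantom(64, 4, 80, value = 5)
  mu <- new("MuMap", mu = diskPhantom(64, 4, 80, value = 0.096), spacing = 4)
  expect_true(all(sinoValues(simulateAcquisition(act * 0, mu, g, 10)) == 0))
  s1 <- simulateAcquisition(act, mu, g, 10, seed = 4)
  s2 <- simulateAcquisition(act, mu, g, 10, seed = 4)
  expect_identical(sinoValues(s1), sinoValues(s2))

  expected <- simulateAcquisition(act, mu, g, 50, seed = NULL)
  expect_gt(sum(sinoValues(expected)), 1e6)
  observed <- simulateAcquisition(act, mu, g, 50, seed = 9)
  ratio <- sum(sinoValues(observed)) / sum(sinoValues(expected))
  expect_gt(ratio, 0.95); expect_lt(ratio, 1.05)
})

test_that("MLEM recovers consistent data and OSEM matches plain MLEM", {
  g <- smallGeom(64, 4, 48)
  act <- diskPhantom(64, 4, 80, value = 5)
  mu <- new("MuMap", mu = diskPhantom(64, 4, 80, value = 0.096), spacing = 4)
  counts <- simulateAcquisition(act, mu, g, 10, seed = NULL)  # noiseless
  acf <- attenuationFactors(mu, g)

  rp <- smallRecon(subsets = 1L, iters = 50L, fwhm = 0)
  rec <- mlemReconstruct(counts, acf, rp, 4, countScale = 10)
  roi <- circularROI(c(32.5, 32.5), 40, "disk")
  expect_lt(abs(extractRoiMean(rec, roi, 4) - 5) / 5, 0.02)
  expect_true(all(rec >= 0))

  # independent single-loop MLEM reference agrees iterate-for-iterate
  ref <- referenceMlem(counts, acf, 50L, 64L, 4, countScale = 10)
  expect_equal(rec, ref, tolerance = 1e-10)

  # ordered subsets accelerate but converge to the same activity level
  rp8 <- smallRecon(subsets = 8L, iters = 6L, fwhm = 0)
  rec8 <- mlemReconstruct(counts, acf, rp8, 4, countScale = 10)
  expect_lt(abs(extractRoiMean(rec8, roi, 4) - 5) / 5, 0.02)

  # NAC reconstruction underestimates the disk centre
  nac <- mlemReconstruct(counts, "ones", rp, 4, countScale = 10)
  centre <- circularROI(c(32.5, 32.5), 12, "centre")
  expect_lt(extractRoiMean(nac, centre, 4), extractRoiMean(rec, centre, 4))
})

test_that("Gaussian post-filter has the configured width and invariances", {
  expect_identical(gaussianPostfilter(diag(5), 0, 1), diag(5))
  const <- matrix(3.5, 20, 20)
  expect_equal(gaussianPostfilter(const, 4, 2), const, tolerance = 1e-12)
  expect_error(gaussianPostfilter(const, -1, 2), ">= 0")

  # delta -> profile with FWHM 2 mm at 1 mm spacing (within 10%)
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  f <- gaussianPostfilter(img, 2, 1)
  expect_equal(sum(f), 1, tolerance = 1e-3)   # intensity preserved
  prof <- f[21, ]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  # sub-voxel half-max crossings by linear interpolation
  lo <- above[1] - (prof[above[1]] - half) /
        (prof[above[1]] - prof[above[1] - 1])
  hi <- above[2] + (prof[above[2]] - half) /
        (prof[above[2]] - prof[above[2] + 1])
  expect_lt(abs((hi - lo) - 2) / 2, 0.1)
})
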