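test_that("generator honours the cascade shape contract", {
  gen <- buildGenerator(generatorSpec(nCascades = 4, unetDepth = 2,
                                      baseChannels = 4), seed = 1)
  y <- matrix(runif(64 * 64), 64, 64)
  r <- generatorForward(gen, y)
  expect_equal(dim(r$y_hat), c(64, 64))
  expect_length(r$intermediates, 4)
  for (m in r$intermediates) expect_equal(dim(m), c(64, 64))

  # degenerate single-cascade case: a plain U-Net
  gen1 <- buildGenerator(generatorSpec(nCascades = 1, unetDepth = 2,
                                       baseChannels = 4), seed = 1)
  r1 <- generatorForward(gen1, y)
  expect_length(r1$intermediates, 1)
  expect_identical(r1$y_hat, r1$intermediates[[1]])

  # inference determinism for fixed weights
  expect_identical(generatorForward(gen, y)$y_hat, r$y_hat)

  # grid not divisible by 2^depth is rejected
  expect_error(generatorForward(gen, matrix(0, 30, 30)), "divisible")
})

test_that("volume translation is slice-independent and HU-bounded", {
  gen <- buildGenerator(generatorSpec(nCascades = 2, unetDepth = 2,
                                      baseChannels = 4), seed = 3)
  set.seed(4)
  vol <- array(runif(32 * 32 * 5, 0, 10), c(32, 32, 5))
  out <- translateVolume(vol, gen)
  expect_equal(dim(out), dim(vol))
  expect_true(all(out >= -1024 & out <= 3071))

  # permuting input slices permutes output slices identically
  p <- c(3, 1, 5, 2, 4)
  expect_equal(translateVolume(vol[, , p], gen), out[, , p],
               tolerance = 1e-12)

  # a single-slice volume equals calling the generator on that slice
  one <- translateVolume(vol[, , 2], gen)
  expect_equal(one, out[, , 2], tolerance = 1e-12)
})

test_that("training runs, logs every component and is seed-reproducible", {
  set.seed(21)
  pairs <- lapply(1:8, function(i) {
    y <- matrix(runif(32 * 32, 0, 10), 32, 32)
    list(y = y, x = (y / 10) * 2000 - 1000)
  })
  gen <- buildGenerator(generatorSpec(nCascades = 2, unetDepth = 2,
                                      baseChannels = 4), seed = 1)
  disc <- buildDiscriminator(seed = 2)
  cfg <- trainConfig(epochs = 3, batchSize = 4, seed = 9)
  fit <- trainTranslator(pairs, gen, disc, config = cfg)
  expect_equal(nrow(fit$history), 3)
  expect_true(all(c("adv", "perceptual", "style", "content", "loss_d",
                    "mae") %in% names(fit$history)))
  expect_true(all(is.finite(as.matrix(fit$history[, -1]))))

  fit2 <- trainTranslator(pairs, gen, disc, config = cfg)
  expect_identical(fit$history$mae, fit2$history$mae)
  expect_identical(fit$generator@params[[1]]$out$w,
                   fit2$generator@params[[1]]$out$w)

  # adversarial weight 0: pure supervised feature regression still runs
  fit0 <- trainTranslator(pairs, gen, disc,
                          weights = lossWeights(adv = 0),
                          config = trainConfig(epochs = 1, batchSize = 4,
                                               seed = 9))
  expect_equal(nrow(fit0$history), 1)
})

test_that("supervised toy task: training beats the untrained generator", {
  # x_ct is an affine function of y_nac; a short schedule must cut the
  # mean absolute error to a fraction of the untrained network's
  set.seed(33)
  pairs <- lapply(1:32, function(i) {
    y <- matrix(runif(32 * 32, 0, 10), 32, 32)
    list(y = y, x = (y / 10) * 2000 - 1000)
  })
  gen <- buildGenerator(generatorSpec(nCascades = 2, unetDepth = 2,
                                      baseChannels = 4), seed = 1)
  disc <- buildDiscriminator(seed = 2)
  norm <- gen@norm
  untrainedMae <- mean(vapply(pairs, function(p) {
    yh <- generatorForward(gen, normalizePet(p$y, norm))$y_hat
    mean(abs(yh - normalizeCt(p$x, norm)))
  }, numeric(1)))
  fit <- trainTranslator(pairs, gen, disc,
                         config = trainConfig(epochs = 10, batchSize = 8,
                                              lrG = 1e-3, lrD = 5e-4,
                                              seed = 5))
  finalMae <- tail(fit$history$mae, 1)
  expect_lt(finalMae, 0.5 * untrainedMae)
})

test_that("checkpoints round-trip through save and load", {
  gen <- buildGenerator(generatorSpec(nCascades = 2, unetDepth = 1,
                                      baseChannels = 2), seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  saveTranslator(gen, path)
  expect_true(file.exists(paste0(path, ".json")))
  gen2 <- loadTranslator(path)
  y <- matrix(runif(16 * 16), 16, 16)
  expect_identical(generatorForward(gen, y)$y_hat,
                   generatorForward(gen2, y)$y_hat)
})
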