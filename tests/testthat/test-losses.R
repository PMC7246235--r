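test_that("adversarial loss matches the min-max formula", {
  expect_equal(adversarialLoss(0.5, 0.5), -2 * log(2), tolerance = 1e-12)
  expect_equal(adversarialLoss(0.9, 0.1), log(0.9) + log(0.9),
               tolerance = 1e-12)
  # supremum 0 as D becomes perfect (bounded by the clamp)
  expect_gt(adversarialLoss(1, 0), -1e-6)
  expect_lte(adversarialLoss(1, 0), 0)
  # batch form: D == 0.5 gives -2 log 2 for any batch size
  expect_equal(adversarialLoss(rep(0.5, 7), rep(0.5, 7)), -2 * log(2),
               tolerance = 1e-12)
})

test_that("perceptual loss is a weighted feature MSE", {
  f <- list(array(runif(32), c(4, 4, 2)), array(runif(16), c(4, 4, 1)))
  expect_equal(perceptualLoss(f, f), 0)
  g <- lapply(f, function(x) x + 2)           # constant offset c = 2
  expect_equal(perceptualLoss(f[1], g[1]), 4, tolerance = 1e-12)
  # doubling a layer weight doubles its contribution
  l1 <- perceptualLoss(f, g, c(1, 1))
  l2 <- perceptualLoss(f, g, c(2, 1))
  expect_equal(l2 - l1, perceptualLoss(f[1], g[1]), tolerance = 1e-12)
  expect_error(perceptualLoss(f, list(f[[1]], array(0, c(2, 2, 1)))),
               "mismatch")
})

test_that("style-content loss uses normalized Gram statistics", {
  f <- list(array(runif(32, 0.1, 1), c(4, 4, 2)))
  expect_equal(styleContentLoss(f, f), 0)

  # constant single-channel maps: normalized Gram is c^2, so the style term
  # is (c1^2 - c2^2)^2; content term is (c1 - c2)^2
  c1 <- 0.7; c2 <- 0.3; N <- 25
  a <- list(matrix(c1, 5, 5)); b <- list(matrix(c2, 5, 5))
  expect_equal(styleContentLoss(a, b, styleWeights = 1, contentWeights = 0),
               (c1^2 - c2^2)^2, tolerance = 1e-12)
  expect_equal(styleContentLoss(a, b, styleWeights = 0, contentWeights = 1),
               (c1 - c2)^2, tolerance = 1e-12)

  # style term is invariant to permuting pixel order
  x <- array(runif(18), c(3, 3, 2)); y <- array(runif(18), c(3, 3, 2))
  p <- sample(9)
  xp <- array(apply(x, 3, function(s) s[p]), dim(x))
  yp <- array(apply(y, 3, function(s) s[p]), dim(y))
  expect_equal(
    styleContentLoss(list(x), list(y), styleWeights = 1, contentWeights = 0),
    styleContentLoss(list(xp), list(yp), styleWeights = 1,
                     contentWeights = 0),
    tolerance = 1e-12)

  # nonnegative, zero iff identical
  expect_gt(styleContentLoss(list(x), list(y)), 0)
})

test_that("loss weights are validated", {
  expect_error(lossWeights(adv = -1), "nonnegative")
  expect_error(lossWeights(0, 0, 0, 0), "at least one")
  w <- lossWeights()
  expect_equal(w$adv, 1); expect_equal(w$perceptual, 10)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(11)
  gen <- buildGenerator(generatorSpec(nCascades = 2, unetDepth = 1,
                                      baseChannels = 2), seed = 5)
  disc <- buildDiscriminator(seed = 7)
  y <- matrix(runif(16 * 16), 16, 16)
  xt <- matrix(runif(16 * 16, -1, 1), 16, 16)
  w <- lossWeights()

  gLoss <- function(g) {
    r <- generatorForward(g, y)
    df <- discriminatorForward(disc, r$y_hat, y)
    dr <- discriminatorForward(disc, xt, y)
    fF <- df$features; fR <- dr$features
    w$adv * log(max(1 - df$p, 1e-7)) +
      w$perceptual * perceptualLoss(fF[c("f1", "f2", "f3")],
                                    fR[c("f1", "f2", "f3")]) +
      w$style * styleContentLoss(fF[c("f1", "f2", "f3")],
                                 fR[c("f1", "f2", "f3")],
                                 contentWeights = rep(0, 3)) +
      w$content * mean((fF$f0 - fR$f0)^2)
  }
  r <- generatorForward(gen, y, keepCache = TRUE)
  df <- discriminatorForward(disc, r$y_hat, y, keepCache = TRUE)
  dr <- discriminatorForward(disc, xt, y)
  fF <- df$features; fR <- dr$features
  gfeats <- list(
    f0 = petacgan:::.gradFeatMSE(fF$f0, fR$f0, w$content),
    f1 = petacgan:::.gradFeatMSE(fF$f1, fR$f1, w$perceptual) +
         petacgan:::.gradStyle(fF$f1, fR$f1, w$style),
    f2 = petacgan:::.gradFeatMSE(fF$f2, fR$f2, w$perceptual) +
         petacgan:::.gradStyle(fF$f2, fR$f2, w$style),
    f3 = petacgan:::.gradFeatMSE(fF$f3, fR$f3, w$perceptual) +
         petacgan:::.gradStyle(fF$f3, fR$f3, w$style))
  rb <- petacgan:::.discriminatorBackward(disc, df$cache,
                                          gz = -w$adv * df$p, gfeats)
  grads <- petacgan:::.generatorBackward(gen, r$caches, rb$gct[, , 1])

  eps <- 1e-6
  for (cc in 1:2) {
    for (t in 1:3) {   # output convolution weights
      i <- sample(length(gen@params[[cc]]$out$w), 1)
      gp <- gen; gp@params[[cc]]$out$w[i] <- gp@params[[cc]]$out$w[i] + eps
      gm <- gen; gm@params[[cc]]$out$w[i] <- gm@params[[cc]]$out$w[i] - eps
      num <- (gLoss(gp) - gLoss(gm)) / (2 * eps)
      expect_equal(grads[[cc]]$out$w[i], num, tolerance = 1e-3)
    }
    # bottleneck convolution weight and instance-norm scale
    i <- sample(length(gen@params[[cc]]$bott$conv$w), 1)
    gp <- gen; gp@params[[cc]]$bott$conv$w[i] <-
      gp@params[[cc]]$bott$conv$w[i] + eps
    gm <- gen; gm@params[[cc]]$bott$conv$w[i] <-
      gm@params[[cc]]$bott$conv$w[i] - eps
    num <- (gLoss(gp) - gLoss(gm)) / (2 * eps)
    expect_equal(grads[[cc]]$bott$conv$w[i], num, tolerance = 1e-3)
    gp <- gen; gp@params[[cc]]$bott$norm$g[1] <-
      gp@params[[cc]]$bott$norm$g[1] + eps
    gm <- gen; gm@params[[cc]]$bott$norm$g[1] <-
      gm@params[[cc]]$bott$norm$g[1] - eps
    num <- (gLoss(gp) - gLoss(gm)) / (2 * eps)
    expect_equal(grads[[cc]]$bott$norm$g[1], num, tolerance = 1e-3)
  }

  # discriminator parameter gradients on its own objective
  dLoss <- function(d) {
    -adversarialLoss(discriminatorForward(d, xt, y)$p,
                     discriminatorForward(d, r$y_hat, y)$p)
  }
  drc <- discriminatorForward(disc, xt, y, keepCache = TRUE)
  dfc <- discriminatorForward(disc, r$y_hat, y, keepCache = TRUE)
  gD <- petacgan:::.addGrads(
    petacgan:::.discriminatorBackward(disc, drc$cache,
                                      gz = -(1 - drc$p))$grads,
    petacgan:::.discriminatorBackward(disc, dfc$cache, gz = dfc$p)$grads)
  for (comp in c("c1", "head")) for (t in 1:3) {
    i <- sample(length(disc@params[[comp]]$w), 1)
    dp <- disc; dp@params[[comp]]$w[i] <- dp@params[[comp]]$w[i] + eps
    dm <- disc; dm@params[[comp]]$w[i] <- dm@params[[comp]]$w[i] - eps
    num <- (dLoss(dp) - dLoss(dm)) / (2 * eps)
    expect_equal(gD[[comp]]$w[i], num, tolerance = 1e-3)
  }
})
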