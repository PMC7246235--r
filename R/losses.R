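#' Adversarial (min-max) loss
#'
#' \deqn{L_{adv} = E[\log D(x_{CT}, y_{NAC})] +
#'       E[\log(1 - D(\hat{x}_{CT}, y_{NAC}))]}
#' The discriminator maximizes this; the generator minimizes it through the
#' second term. Probabilities are clamped to \code{[eps, 1 - eps]} so the
#' logs stay finite.
#'
#' @param dReal discriminator probabilities on real pairs, in (0, 1).
#' @param dFake discriminator probabilities on generated pairs.
#' @param eps clamp width (default 1e-7).
#' @return scalar loss value (<= 0; supremum 0 at perfect discrimination).
#' @examples
#' adversarialLoss(0.5, 0.5)  # -2 log 2
#' @export
adversarialLoss <- function(dReal, dFake, eps = 1e-7) {
  dReal <- pmin(pmax(dReal, eps), 1 - eps)
  dFake <- pmin(pmax(dFake, eps), 1 - eps)
  mean(log(dReal)) + mean(log(1 - dFake))
}

#' Perceptual loss: weighted feature-space mean squared error
#'
#' @param featuresFake list of feature arrays of the generated image.
#' @param featuresReal list of matching feature arrays of the real image.
#' @param layerWeights nonnegative weight per layer (default all 1).
#' @return scalar loss, 0 iff the feature stacks are identical.
#' @export
perceptualLoss <- function(featuresFake, featuresReal,
                           layerWeights = rep(1, length(featuresFake))) {
  stopifnot(length(featuresFake) == length(featuresReal),
            length(layerWeights) == length(featuresFake))
  tot <- 0
  for (l in seq_along(featuresFake)) {
    a <- featuresFake[[l]]; b <- featuresReal[[l]]
    if (!all(dim(.asCube(a)) == dim(.asCube(b))))
      stop("feature shape mismatch in layer ", l)
    tot <- tot + layerWeights[l] * mean((a - b)^2)
  }
  tot
}

# Gram matrix of a feature cube, normalized by channels x pixels
.gram <- function(f) {
  f <- .asCube(f)
  C <- dim(f)[3]; N <- prod(dim(f)[1:2])
  F <- matrix(f, N, C)
  crossprod(F) / (C * N)
}

#' Style-content loss
#'
#' Style term: weighted sum over layers of the squared Frobenius difference
#' of normalized Gram matrices (Gram = \eqn{F^T F / (C N)} for an
#' N-pixel, C-channel feature map); pixel-order invariant. Content term:
#' weighted mean squared feature difference. Returns their sum.
#'
#' @param featuresFake,featuresReal matched lists of feature arrays.
#' @param styleWeights nonnegative style weight per layer.
#' @param contentWeights nonnegative content weight per layer.
#' @return scalar loss, 0 iff the feature stacks are identical.
#' @export
styleContentLoss <- function(featuresFake, featuresReal,
                             styleWeights = rep(1, length(featuresFake)),
                             contentWeights = rep(1, length(featuresFake))) {
  stopifnot(length(featuresFake) == length(featuresReal))
  tot <- 0
  for (l in seq_along(featuresFake)) {
    a <- featuresFake[[l]]; b <- featuresReal[[l]]
    if (!all(dim(.asCube(a)) == dim(.asCube(b))))
      stop("feature shape mismatch in layer ", l)
    if (styleWeights[l] > 0) {
      dG <- .gram(a) - .gram(b)
      tot <- tot + styleWeights[l] * sum(dG^2)
    }
    if (contentWeights[l] > 0)
      tot <- tot + contentWeights[l] * mean((a - b)^2)
  }
  tot
}

# gradient of styleWeights-weighted style term w.r.t. the fake feature cube
.gradStyle <- function(fFake, fReal, w) {
  f <- .asCube(fFake)
  C <- dim(f)[3]; N <- prod(dim(f)[1:2])
  F <- matrix(f, N, C)
  dG <- 2 * (.gram(fFake) - .gram(fReal))
  g <- F %*% (dG + t(dG)) / (C * N)
  array(w * g, dim = dim(f))
}

# gradient of a weighted feature MSE w.r.t. the fake feature cube
.gradFeatMSE <- function(fFake, fReal, w) {
  a <- .asCube(fFake); b <- .asCube(fReal)
  w * 2 * (a - b) / length(a)
}

#' Loss weights for generator training
#'
#' @param adv adversarial weight (default 1).
#' @param perceptual perceptual-loss weight (default 10).
#' @param style style-term weight (default 10).
#' @param content content-term weight (default 10).
#' @return validated list of weights.
#' @export
lossWeights <- function(adv = 1, perceptual = 10, style = 10, content = 10) {
  w <- c(adv, perceptual, style, content)
  if (any(w < 0)) stop("loss weights must be nonnegative")
  if (all(w == 0)) stop("at least one loss weight must be positive")
  list(adv = adv, perceptual = perceptual, style = style, content = content)
}
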