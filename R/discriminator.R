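#' Discriminator specification
#'
#' A conditional binary classifier: three stride-2 convolutions with leaky
#' ReLU, a final convolution to one channel, global average and a sigmoid.
#' Its input is the channel-stacked (CT candidate, PET_NAC) pair; its
#' intermediate activations are the feature stack used by the perceptual
#' and style-content losses.
#'
#' @param channels channels of the three strided layers (default 8, 16, 32).
#' @param kernel convolution kernel size (default 3).
#' @return spec list for [buildDiscriminator()].
#' @export
discriminatorSpec <- function(channels = c(8L, 16L, 32L), kernel = 3L) {
  stopifnot(length(channels) == 3, all(channels >= 1))
  list(channels = as.integer(channels), kernel = as.integer(kernel))
}

#' Build (initialise) a discriminator
#'
#' @param spec a [discriminatorSpec()] list.
#' @param seed RNG seed for weight initialisation.
#' @return a [PatchDiscriminator-class].
#' @export
buildDiscriminator <- function(spec = discriminatorSpec(), seed = 2L) {
  set.seed(seed)
  ch <- spec$channels; k <- spec$kernel
  params <- list(
    c1 = .makeConv(2L, ch[1], k = k, stride = 2L),
    c2 = .makeConv(ch[1], ch[2], k = k, stride = 2L),
    n2 = .makeInorm(ch[2]),
    c3 = .makeConv(ch[2], ch[3], k = k, stride = 2L),
    n3 = .makeInorm(ch[3]),
    head = .makeConv(ch[3], 1L, k = k, stride = 1L, gain = 0.5))
  new("PatchDiscriminator", spec = spec, params = params)
}

#' Run the discriminator on a (CT candidate, PET_NAC) pair
#'
#' @param disc a [PatchDiscriminator-class].
#' @param ct CT candidate slice (normalized, matrix).
#' @param y PET_NAC slice (normalized, matrix).
#' @param keepCache keep per-layer caches for backpropagation.
#' @return list with `p` (probability in (0, 1)), `z` (pre-sigmoid logit),
#'   `features` (list: f0 = the CT channel itself, f1..f3 = activations of
#'   the three strided layers) and, if requested, `cache`.
#' @export
discriminatorForward <- function(disc, ct, y, keepCache = FALSE) {
  p <- disc@params
  x <- .concatC(.asCube(ct), .asCube(y))
  pre1 <- .convFwd(p$c1, x);  a1 <- .lreluFwd(pre1)
  pre2 <- .convFwd(p$c2, a1); in2 <- .inormFwd(p$n2, pre2)
  a2 <- .lreluFwd(in2$y)
  pre3 <- .convFwd(p$c3, a2); in3 <- .inormFwd(p$n3, pre3)
  a3 <- .lreluFwd(in3$y)
  h <- .convFwd(p$head, a3)
  z <- mean(h)
  prob <- 1 / (1 + exp(-z))
  out <- list(p = prob, z = z,
              features = list(f0 = .asCube(ct), f1 = a1, f2 = a2, f3 = a3))
  if (keepCache)
    out$cache <- list(x = x, pre1 = pre1, a1 = a1, pre2 = pre2, in2 = in2,
                      a2 = a2, pre3 = pre3, in3 = in3, a3 = a3, h = h)
  out
}

# Backpropagate a logit gradient gz plus optional feature-stack gradients
# (gf1..gf3 on the activations, gf0 on the CT channel) through the
# discriminator. Returns parameter gradients and the gradient w.r.t. the CT
# input channel.
.discriminatorBackward <- function(disc, cache, gz, gfeats = NULL) {
  p <- disc@params
  gh <- array(gz / length(cache$h), dim = dim(cache$h))
  r4 <- .convBwd(p$head, cache$a3, gh)
  ga3 <- r4$gx
  if (!is.null(gfeats$f3)) ga3 <- ga3 + gfeats$f3
  i3 <- .inormBwd(p$n3, cache$pre3, cache$in3$stats,
                  .lreluBwd(cache$in3$y, ga3))
  r3 <- .convBwd(p$c3, cache$a2, i3$gx)
  ga2 <- r3$gx
  if (!is.null(gfeats$f2)) ga2 <- ga2 + gfeats$f2
  i2 <- .inormBwd(p$n2, cache$pre2, cache$in2$stats,
                  .lreluBwd(cache$in2$y, ga2))
  r2 <- .convBwd(p$c2, cache$a1, i2$gx)
  ga1 <- r2$gx
  if (!is.null(gfeats$f1)) ga1 <- ga1 + gfeats$f1
  r1 <- .convBwd(p$c1, cache$x, .lreluBwd(cache$pre1, ga1))
  gct <- r1$gx[, , 1L, drop = FALSE]
  if (!is.null(gfeats$f0)) gct <- gct + gfeats$f0
  grads <- list(
    c1 = list(meta = p$c1$meta, w = r1$gw, b = as.numeric(r1$gb)),
    c2 = list(meta = p$c2$meta, w = r2$gw, b = as.numeric(r2$gb)),
    n2 = list(meta = p$n2$meta, g = i2$gg, b = i2$gb),
    c3 = list(meta = p$c3$meta, w = r3$gw, b = as.numeric(r3$gb)),
    n3 = list(meta = p$n3$meta, g = i3$gg, b = i3$gb),
    head = list(meta = p$head$meta, w = r4$gw, b = as.numeric(r4$gb)))
  list(grads = grads, gct = gct)
}
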