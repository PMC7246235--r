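#' Generator specification
#'
#' Four cascaded U-Nets by default: the first maps the normalized PET_NAC
#' slice to a pseudo-CT estimate, each subsequent cascade consumes the
#' PET_NAC slice stacked with the previous estimate and refines it.
#'
#' @param nCascades number of cascaded U-Nets (default 4).
#' @param unetDepth pooling levels per U-Net (default 2); input grids must
#'   be divisible by \code{2^unetDepth}.
#' @param baseChannels channels at full resolution (default 8; doubled per
#'   level).
#' @param kernel convolution kernel size (default 3).
#' @return spec list for [buildGenerator()].
#' @export
generatorSpec <- function(nCascades = 4L, unetDepth = 2L, baseChannels = 8L,
                          kernel = 3L) {
  stopifnot(nCascades >= 1, unetDepth >= 1, baseChannels >= 1)
  list(nCascades = as.integer(nCascades), unetDepth = as.integer(unetDepth),
       baseChannels = as.integer(baseChannels), kernel = as.integer(kernel))
}

#' Default intensity normalization parameters
#'
#' PET_NAC slices are scaled by their 99.5th intensity percentile, then
#' gamma-compressed (exponent 0.5): the hottest structure (typically the
#' bladder) sets the scale, and without compression soft tissue and lung
#' would occupy only a few percent of the input range. CT is mapped
#' affinely from [-1024, 3071] to [-1, 1]. All transforms are stored on
#' the generator for inversion.
#'
#' @return list of normalization parameters.
#' @export
defaultNormalization <- function() {
  list(petQuantile = 0.995, petClip = 3, petGamma = 0.5,
       ctMin = -1024, ctMax = 3071)
}

normalizePet <- function(act, norm) {
  s <- as.numeric(quantile(act, norm$petQuantile))
  if (!is.finite(s) || s <= 0) s <- 1
  gamma <- if (is.null(norm$petGamma)) 1 else norm$petGamma
  pmin(act / s, norm$petClip)^gamma
}

normalizeCt <- function(hu, norm) {
  2 * (hu - norm$ctMin) / (norm$ctMax - norm$ctMin) - 1
}

denormalizeCt <- function(x, norm) {
  x <- pmin(pmax(x, -1), 1)
  (x + 1) / 2 * (norm$ctMax - norm$ctMin) + norm$ctMin
}

# conv + instance norm block (the output layer is conv-only + tanh)
.makeBlock <- function(cin, cout, k) {
  list(conv = .makeConv(cin, cout, k = k), norm = .makeInorm(cout))
}

.buildUnet <- function(cin, depth, base, k) {
  enc <- vector("list", depth)
  cprev <- cin
  for (l in seq_len(depth)) {
    enc[[l]] <- .makeBlock(cprev, base * 2^(l - 1), k)
    cprev <- base * 2^(l - 1)
  }
  bott <- .makeBlock(base * 2^(depth - 1), base * 2^depth, k)
  dec <- vector("list", depth)
  for (l in seq_len(depth)) {   # dec[[l]] merges at level l
    dec[[l]] <- .makeBlock(base * 2^l + base * 2^(l - 1), base * 2^(l - 1),
                           k)
  }
  out <- .makeConv(base, 1L, k = k, gain = 0.5)
  list(enc = enc, bott = bott, dec = dec, out = out)
}

.blockFwd <- function(blk, x) {
  pre <- .convFwd(blk$conv, x)
  inr <- .inormFwd(blk$norm, pre)
  list(y = .lreluFwd(inr$y), pre = pre, ny = inr$y, stats = inr$stats)
}

# gy is the gradient on the block's activation output
.blockBwd <- function(blk, xin, fw, gy) {
  gny <- .lreluBwd(fw$ny, gy)
  ir <- .inormBwd(blk$norm, fw$pre, fw$stats, gny)
  cr <- .convBwd(blk$conv, xin, ir$gx)
  list(gx = cr$gx,
       grads = list(conv = list(meta = blk$conv$meta, w = cr$gw,
                                b = as.numeric(cr$gb)),
                    norm = list(meta = blk$norm$meta, g = ir$gg,
                                b = ir$gb)))
}

#' Build (initialise) a cascaded U-Net generator
#'
#' @param spec a [generatorSpec()] list.
#' @param seed RNG seed for the weight initialisation.
#' @param norm normalization parameters, see [defaultNormalization()].
#' @return a [CascadedGenerator-class].
#' @export
buildGenerator <- function(spec = generatorSpec(), seed = 1L,
                           norm = defaultNormalization()) {
  set.seed(seed)
  params <- vector("list", spec$nCascades)
  for (cc in seq_len(spec$nCascades)) {
    cin <- if (cc == 1L) 1L else 2L
    params[[cc]] <- .buildUnet(cin, spec$unetDepth, spec$baseChannels,
                               spec$kernel)
  }
  new("CascadedGenerator", spec = spec, params = params, norm = norm)
}

.unetFwd <- function(u, x, depth) {
  cache <- list(e_in = vector("list", depth), e_fw = vector("list", depth),
                d_in = vector("list", depth), d_fw = vector("list", depth))
  cur <- x
  eAct <- vector("list", depth)
  for (l in seq_len(depth)) {
    cache$e_in[[l]] <- cur
    fw <- .blockFwd(u$enc[[l]], cur)
    cache$e_fw[[l]] <- fw
    eAct[[l]] <- fw$y
    cur <- cpp_avgpool2_fwd(fw$y)
  }
  cache$b_in <- cur
  bfw <- .blockFwd(u$bott, cur)
  cache$b_fw <- bfw
  cur <- bfw$y
  for (l in rev(seq_len(depth))) {
    up <- cpp_upsample2_fwd(cur)
    cat_in <- .concatC(up, eAct[[l]])
    cache$d_in[[l]] <- cat_in
    fw <- .blockFwd(u$dec[[l]], cat_in)
    cache$d_fw[[l]] <- fw
    cur <- fw$y
  }
  cache$o_in <- cur
  opre <- .convFwd(u$out, cur)
  y <- tanh(opre)
  cache$y <- y
  list(y = y, cache = cache)
}

.unetBwd <- function(u, cache, gy, depth) {
  # grads mirror the parameter structure (enc, bott, dec, out) so the
  # index-walking Adam/accumulation helpers line up
  g <- list(enc = vector("list", depth), bott = NULL,
            dec = vector("list", depth), out = NULL)
  gpre <- gy * (1 - cache$y^2)
  r <- .convBwd(u$out, cache$o_in, gpre)
  g$out <- list(meta = u$out$meta, w = r$gw, b = as.numeric(r$gb))
  gcur <- r$gx
  gskip <- vector("list", depth)
  for (l in seq_len(depth)) {
    br <- .blockBwd(u$dec[[l]], cache$d_in[[l]], cache$d_fw[[l]], gcur)
    g$dec[[l]] <- br$grads
    nskip <- dim(cache$e_fw[[l]]$y)[3]
    sp <- .splitC(br$gx, dim(br$gx)[3] - nskip)
    gskip[[l]] <- sp[[2]]
    gcur <- cpp_upsample2_bwd(sp[[1]])
  }
  br <- .blockBwd(u$bott, cache$b_in, cache$b_fw, gcur)
  g$bott <- br$grads
  gcur <- br$gx
  for (l in rev(seq_len(depth))) {
    gact <- cpp_avgpool2_bwd(gcur) + gskip[[l]]
    br <- .blockBwd(u$enc[[l]], cache$e_in[[l]], cache$e_fw[[l]], gact)
    g$enc[[l]] <- br$grads
    gcur <- br$gx
  }
  list(grads = g, gx = gcur)
}

#' Run the generator on one normalized PET_NAC slice
#'
#' @param gen a [CascadedGenerator-class].
#' @param y normalized PET_NAC slice (matrix); its side lengths must be
#'   divisible by \code{2^unetDepth}.
#' @param keepCache keep the per-layer caches needed for backpropagation.
#' @return list with `y_hat` (final normalized pseudo-CT slice),
#'   `intermediates` (one slice per cascade) and, if requested, `caches`.
#' @export
generatorForward <- function(gen, y, keepCache = FALSE) {
  spec <- gen@spec
  d <- 2^spec$unetDepth
  if (any(dim(y) %% d != 0))
    stop("grid must be divisible by 2^unetDepth = ", d)
  ycube <- .asCube(y)
  prev <- NULL
  inter <- vector("list", spec$nCascades)
  caches <- if (keepCache) vector("list", spec$nCascades) else NULL
  for (cc in seq_len(spec$nCascades)) {
    xin <- if (cc == 1L) ycube else .concatC(ycube, prev)
    r <- .unetFwd(gen@params[[cc]], xin, spec$unetDepth)
    if (keepCache) caches[[cc]] <- c(r["cache"], list(xin = xin))
    prev <- r$y
    inter[[cc]] <- r$y[, , 1L]
  }
  list(y_hat = inter[[spec$nCascades]], intermediates = inter,
       caches = caches)
}

# backprop dL/d y_hat through all cascades; returns per-cascade param grads
.generatorBackward <- function(gen, caches, gfinal) {
  spec <- gen@spec
  gOut <- .asCube(gfinal)
  grads <- vector("list", spec$nCascades)
  for (cc in rev(seq_len(spec$nCascades))) {
    r <- .unetBwd(gen@params[[cc]], caches[[cc]]$cache, gOut, spec$unetDepth)
    grads[[cc]] <- r$grads
    if (cc > 1L) gOut <- r$gx[, , 2L, drop = FALSE]
  }
  grads
}

#' Translate a PET_NAC volume slice-by-slice into a pseudo-CT volume
#'
#' Each axial slice is normalized, translated independently and
#' denormalized to HU (clipped to [-1024, 3071]); there is no inter-slice
#' coupling. A matrix input is treated as a single-slice volume and
#' returned as a matrix.
#'
#' @param vol matrix (single slice) or 3D array (H, W, nSlices) of PET_NAC
#'   intensities.
#' @param gen a trained [CascadedGenerator-class].
#' @return pseudo-CT in HU, same shape as the input.
#' @export
translateVolume <- function(vol, gen) {
  single <- is.matrix(vol)
  if (single) vol <- array(vol, dim = c(dim(vol), 1L))
  out <- array(0, dim = dim(vol))
  for (s in seq_len(dim(vol)[3])) {
    y <- normalizePet(vol[, , s], gen@norm)
    r <- generatorForward(gen, y)
    out[, , s] <- denormalizeCt(r$y_hat, gen@norm)
  }
  if (single) out[, , 1L] else out
}
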