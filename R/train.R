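#' Training configuration
#'
#' The source method does not publish optimiser settings; these defaults
#' (Adam with learning rate 2e-4, batch 8) are the conventional choice for
#' conditional image-to-image GANs.
#'
#' @param epochs training epochs (>= 1).
#' @param batchSize minibatch size.
#' @param lrG,lrD generator / discriminator learning rates.
#' @param seed RNG seed (threads through shuffling; weight init is seeded
#'   at build time).
#' @param augment random left-right flipping of each (PET_NAC, CT) pair
#'   during training (default TRUE); cuts overfitting on small cohorts.
#' @param checkpointPath optional path for the final checkpoint
#'   (see [saveTranslator()]).
#' @param verbose print a line per epoch.
#' @return validated config list.
#' @export
trainConfig <- function(epochs = 20L, batchSize = 8L, lrG = 2e-4, lrD = 2e-4,
                        seed = 1L, augment = TRUE, checkpointPath = NULL,
                        verbose = FALSE) {
  stopifnot(epochs >= 1, batchSize >= 1, lrG > 0, lrD > 0)
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       lrG = lrG, lrD = lrD, seed = as.integer(seed),
       augment = isTRUE(augment), checkpointPath = checkpointPath,
       verbose = isTRUE(verbose))
}

#' Assemble (PET_NAC, CT) training pairs from a dataset manifest
#'
#' For each case the acquisition is simulated from the activity map with
#' the PET-state anatomy's attenuation, and the non-attenuation-corrected
#' image (ACF = 1) is reconstructed; that PET_NAC image, paired with the
#' acquired CT, is a training sample.
#'
#' @param manifest manifest data.frame from [makeDataset()]/[readManifest()].
#' @param dir dataset directory (defaults to the manifest's `dir`
#'   attribute).
#' @param geom a [ProjectionGeometry-class].
#' @param params a [ReconParams-class] for the NAC reconstruction.
#' @param countScale acquisition count scale.
#' @param seed base seed; case i uses seed + i.
#' @return list of pairs \code{list(y = PET_NAC image, x = CT HU image,
#'   id, dose_MBq, weight_kg)}.
#' @export
prepareTrainingPairs <- function(manifest, dir = attr(manifest, "dir"), geom,
                                 params, countScale = 20, seed = 1L) {
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    act <- readImageNifti(file.path(dir, r$activity_path))
    ct <- readImageNifti(file.path(dir, r$ct_path))
    trueCt <- readImageNifti(file.path(dir, r$true_ct_path))
    sp <- attr(act, "spacing")
    mu <- huToMu(trueCt, sp)
    counts <- simulateAcquisition(act, mu, geom, countScale,
                                  seed = seed + i)
    nac <- mlemReconstruct(counts, "ones", params, sp,
                           countScale = countScale)
    list(y = nac, x = ct, id = r$id, dose_MBq = r$dose_MBq,
         weight_kg = r$weight_kg)
  })
}

#' Train the conditional GAN translator
#'
#' Alternating updates: per minibatch the discriminator takes one Adam step
#' on the negated adversarial loss, then the generator takes one step on
#' \code{lambda_adv * log(1 - D(x_hat, y)) + lambda_p * perceptual +
#' lambda_s * style + lambda_c * content}, where the perceptual and style
#' terms use the discriminator's strided-layer activations and the content
#' term uses the raw image channel. Training aborts with a diagnostic if a
#' loss goes non-finite. Runs are reproducible for a fixed seed on CPU.
#'
#' @param pairs list of training pairs (see [prepareTrainingPairs()]); raw
#'   intensities, normalization is applied internally.
#' @param generator a [CascadedGenerator-class].
#' @param discriminator a [PatchDiscriminator-class].
#' @param weights a [lossWeights()] list.
#' @param config a [trainConfig()] list.
#' @return list with `generator`, `discriminator` (trained) and `history`
#'   (data.frame, one row per epoch: adv, perceptual, style, content,
#'   loss_d, mae).
#' @export
trainTranslator <- function(pairs, generator, discriminator,
                            weights = lossWeights(), config = trainConfig()) {
  stopifnot(length(pairs) >= 1)
  norm <- generator@norm
  data <- lapply(pairs, function(p)
    list(y = normalizePet(p$y, norm), x = normalizeCt(p$x, norm)))
  stateG <- .adamInit(generator@params)
  stateD <- .adamInit(discriminator@params)
  histRows <- vector("list", config$epochs)
  set.seed(config$seed)

  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(data))
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    acc <- c(adv = 0, perceptual = 0, style = 0, content = 0,
             loss_d = 0, mae = 0)
    nseen <- 0
    for (b in batches) {
      batchData <- data[b]
      if (isTRUE(config$augment)) {
        flip <- runif(length(b)) < 0.5
        batchData <- lapply(seq_along(b), function(i) {
          s <- batchData[[i]]
          if (flip[i]) list(y = s$y[, ncol(s$y):1],
                            x = s$x[, ncol(s$x):1]) else s
        })
      }
      fwd <- lapply(batchData, function(s)
        generatorForward(generator, s$y, keepCache = TRUE))

      # discriminator step
      gD <- .zeroLike(discriminator@params)
      lossD <- 0
      for (i in seq_along(b)) {
        s <- batchData[[i]]
        dr <- discriminatorForward(discriminator, s$x, s$y, keepCache = TRUE)
        df <- discriminatorForward(discriminator, fwd[[i]]$y_hat, s$y,
                                   keepCache = TRUE)
        lossD <- lossD - adversarialLoss(dr$p, df$p)
        rR <- .discriminatorBackward(discriminator, dr$cache,
                                     gz = -(1 - dr$p))
        rF <- .discriminatorBackward(discriminator, df$cache, gz = df$p)
        gD <- .addGrads(gD, .addGrads(rR$grads, rF$grads))
      }
      gD <- .scaleGrads(gD, 1 / length(b))
      up <- .adamStep(discriminator@params, gD, stateD, config$lrD)
      discriminator@params <- up$params; stateD <- up$state

      # generator step (against the updated discriminator)
      gG <- .zeroLike(generator@params)
      for (i in seq_along(b)) {
        s <- batchData[[i]]
        yhat <- fwd[[i]]$y_hat
        df <- discriminatorForward(discriminator, yhat, s$y,
                                   keepCache = TRUE)
        dr <- discriminatorForward(discriminator, s$x, s$y)
        fF <- df$features; fR <- dr$features
        advG <- log(max(1 - df$p, 1e-7))
        perc <- perceptualLoss(fF[c("f1", "f2", "f3")],
                               fR[c("f1", "f2", "f3")])
        style <- styleContentLoss(fF[c("f1", "f2", "f3")],
                                  fR[c("f1", "f2", "f3")],
                                  contentWeights = rep(0, 3))
        content <- mean((fF$f0 - fR$f0)^2)
        total <- weights$adv * advG + weights$perceptual * perc +
                 weights$style * style + weights$content * content
        if (!is.finite(total))
          stop("training diverged (non-finite loss) at epoch ", ep)
        gfeats <- list(
          f0 = .gradFeatMSE(fF$f0, fR$f0, weights$content),
          f1 = .gradFeatMSE(fF$f1, fR$f1, weights$perceptual) +
               .gradStyle(fF$f1, fR$f1, weights$style),
          f2 = .gradFeatMSE(fF$f2, fR$f2, weights$perceptual) +
               .gradStyle(fF$f2, fR$f2, weights$style),
          f3 = .gradFeatMSE(fF$f3, fR$f3, weights$perceptual) +
               .gradStyle(fF$f3, fR$f3, weights$style))
        r <- .discriminatorBackward(discriminator, df$cache,
                                    gz = -weights$adv * df$p, gfeats)
        gG <- .addGrads(gG, .generatorBackward(generator, fwd[[i]]$caches,
                                               r$gct[, , 1L]))
        acc <- acc + c(adv = advG, perceptual = perc, style = style,
                       content = content, loss_d = lossD / length(b),
                       mae = mean(abs(yhat - s$x)))
        nseen <- nseen + 1
      }
      gG <- .scaleGrads(gG, 1 / length(b))
      up <- .adamStep(generator@params, gG, stateG, config$lrG)
      generator@params <- up$params; stateG <- up$state
    }
    histRows[[ep]] <- as.data.frame(c(list(epoch = ep),
                                      as.list(acc / nseen)))
    if (config$verbose)
      message(sprintf("epoch %d: mae=%.4f content=%.4f D=%.3f", ep,
                      acc["mae"] / nseen, acc["content"] / nseen,
                      acc["loss_d"] / nseen))
  }
  history <- do.call(rbind, histRows)
  if (!is.null(config$checkpointPath))
    saveTranslator(generator, config$checkpointPath)
  list(generator = generator, discriminator = discriminator,
       history = history)
}

#' Save / load a trained translator
#'
#' The checkpoint is an RDS of the generator's spec, weights and
#' normalization parameters, with a JSON sidecar (spec + normalization) for
#' inspection.
#'
#' @param gen a [CascadedGenerator-class].
#' @param path checkpoint path (.rds).
#' @return the path, invisibly.
#' @export
saveTranslator <- function(gen, path) {
  saveRDS(list(spec = gen@spec, params = gen@params, norm = gen@norm), path)
  jsonlite::write_json(list(spec = gen@spec, norm = gen@norm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveTranslator
#' @export
loadTranslator <- function(path) {
  x <- readRDS(path)
  new("CascadedGenerator", spec = x$spec, params = x$params, norm = x$norm)
}
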