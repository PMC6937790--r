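# Internal forward/backward engine.  Tensors are column-major R arrays
# (H, W, C, N); the convolution and pooling hot spots live in src/.

.CLASSES <- c("normal", "pathological")

.lrnForward <- function(a, alpha, beta, k, window) {
  lrn_forward(a, dim(a), alpha, beta, k, window)
}

.lrnBackward <- function(a, den, p, dy, alpha, beta, window) {
  lrn_backward(a, dim(a), dy, den, p, alpha, beta, window)
}

.softmax <- function(z) {
  m <- apply(z, 2, max)
  e <- exp(sweep(z, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# One full forward pass; returns every intermediate needed for backward.
.cnnForward <- function(params, cfg, x, train = FALSE, dropMask = NULL) {
  N <- dim(x)[4]
  z1 <- conv_forward(x, dim(x), params$Wc, dim(params$Wc), params$bc)
  a1 <- relu(z1)
  lr <- .lrnForward(a1, cfg@lrnAlpha, cfg@lrnBeta, cfg@lrnK, cfg@lrnWindow)
  pl <- pool_forward(lr$y, dim(lr$y))
  X1 <- matrix(pl$y, ncol = N)
  h <- params$W1 %*% X1 + params$b1
  hr <- pmax(h, 0)
  if (train) {
    if (is.null(dropMask))
      dropMask <- matrix(runif(length(hr)) >= cfg@dropoutP, nrow(hr))
    hd <- hr * dropMask / (1 - cfg@dropoutP)
  } else {
    dropMask <- NULL
    hd <- hr
  }
  z2 <- params$W2 %*% hd + params$b2
  prob <- .softmax(z2)
  list(z1 = z1, a1 = a1, den = lr$den, lrnP = lr$p, lrnY = lr$y,
       poolIdx = pl$idx, poolDim = dim(pl$y), X1 = X1, h = h, hd = hd,
       dropMask = dropMask, prob = prob)
}

.cnnLoss <- function(prob, yOneHot) {
  -mean(log(pmax(colSums(prob * yOneHot), 1e-300)))
}

.cnnBackward <- function(fw, params, cfg, x, yOneHot, train = TRUE) {
  N <- ncol(fw$prob)
  dz2 <- unname((fw$prob - yOneHot) / N)
  dW2 <- dz2 %*% t(fw$hd)
  db2 <- rowSums(dz2)
  dhd <- t(params$W2) %*% dz2
  dhr <- if (train && !is.null(fw$dropMask))
    dhd * fw$dropMask / (1 - cfg@dropoutP) else dhd
  dh <- dhr * (fw$h > 0)
  dW1 <- dh %*% t(fw$X1)
  db1 <- rowSums(dh)
  dX1 <- t(params$W1) %*% dh
  dpool <- pool_backward(as.numeric(dX1), fw$poolIdx, length(fw$lrnY))
  dim(dpool) <- dim(fw$lrnY)
  da1 <- .lrnBackward(fw$a1, fw$den, fw$lrnP, dpool, cfg@lrnAlpha,
                      cfg@lrnBeta, cfg@lrnWindow)
  dz1 <- da1 * (fw$z1 > 0)
  cb <- conv_backward(x, dim(x), params$Wc, dim(params$Wc), as.numeric(dz1))
  list(Wc = cb$dw, bc = cb$db, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# loss + gradients in one call (used by the finite-difference checks)
.cnnLossGrad <- function(params, cfg, x, yOneHot, train = FALSE,
                         dropMask = NULL) {
  fw <- .cnnForward(params, cfg, x, train = train, dropMask = dropMask)
  g <- .cnnBackward(fw, params, cfg, x, yOneHot, train = train)
  list(loss = .cnnLoss(fw$prob, yOneHot), grads = g, prob = fw$prob)
}

.padReflect <- function(x, p) {
  H <- dim(x)[1]; W <- dim(x)[2]
  ri <- c((p + 1):2, 1:H, (H - 1):(H - p))
  ci <- c((p + 1):2, 1:W, (W - 1):(W - p))
  x[ri, ci, , , drop = FALSE]
}

#' Augment images for training or evaluation
#'
#' Training mode pads each image reflectively by `cropPad` pixels and takes
#' a random crop back to the input resolution (offsets drawn from the
#' session RNG), then subtracts the training-set mean image. Evaluation mode
#' is deterministic: the centre path reproduces the original image, so only
#' the mean image is subtracted.
#'
#' @param images numeric array (R, R, 3, N) or a [TFImageSet-class].
#' @param meanImage training-set mean image (R, R, 3); `NULL` skips
#'   zero-centering.
#' @param mode `"train"` or `"eval"`.
#' @param cfg a [cnnConfig()] supplying `cropPad` and the expected
#'   resolution.
#' @return The augmented (R, R, 3, N) array.
#' @export
augment <- function(images, meanImage = NULL, mode = c("eval", "train"),
                    cfg = cnnConfig()) {
  mode <- match.arg(mode)
  x <- if (is(images, "TFImageSet")) imageArray(images) else images
  R <- dim(x)[1]
  if (R != cfg@inputResolution)
    stop(sprintf("augment: image resolution %d does not match config %d",
                 R, cfg@inputResolution))
  if (!is.null(meanImage) && !all(dim(meanImage) == dim(x)[1:3]))
    stop("augment: mean image shape mismatch")
  if (mode == "train" && cfg@cropPad > 0) {
    p <- cfg@cropPad
    xp <- .padReflect(x, p)
    N <- dim(x)[4]
    out <- x
    for (n in seq_len(N)) {
      oi <- sample.int(2 * p + 1, 1) - 1L
      oj <- sample.int(2 * p + 1, 1) - 1L
      out[, , , n] <- xp[oi + seq_len(R), oj + seq_len(R), , n]
    }
    x <- out
  }
  if (!is.null(meanImage)) x <- x - as.vector(meanImage)
  x
}

.oneHot <- function(labels) {
  y <- matrix(0, 2, length(labels), dimnames = list(.CLASSES, NULL))
  y[1, labels == "normal"] <- 1
  y[2, labels == "pathological"] <- 1
  y
}

.lrAt <- function(cfg, epoch) {
  cfg@initialLr * cfg@lrDropFactor^((epoch - 1) %/% cfg@lrDropPeriod)
}

#' Train the CNN with stochastic gradient descent
#'
#' Mini-batch SGD with momentum, an epoch-stepped learning-rate drop and L2
#' regularisation, minimising the cross-entropy of the softmax outputs.
#' Mini-batches are reshuffled every epoch from the seeded RNG and a short
#' final batch is kept. The training-set mean image is computed before
#' augmentation and stored in the model for zero-centering at prediction
#' time. Training is fully reproducible from `cfg@seed`.
#'
#' @param model an untrained [CNNModel-class] from [buildModel()].
#' @param images a [TFImageSet-class] with both classes present.
#' @param verbose print per-epoch loss/accuracy.
#' @return The trained model; `trainingHistory()` holds per-iteration loss
#'   and mini-batch accuracy.
#' @export
trainModel <- function(model, images, verbose = FALSE) {
  cfg <- model@config
  x <- imageArray(images)
  labels <- imageLabels(images)
  if (length(unique(labels)) < 2)
    stop("trainModel: need both classes in the training set")
  N <- dim(x)[4]
  if (cfg@miniBatch > N)
    stop("trainModel: mini-batch larger than the training set")
  if (dim(x)[1] != cfg@inputResolution)
    stop("trainModel: image resolution does not match the model config")
  set.seed(cfg@seed)
  params <- model@params
  vel <- lapply(params, function(p) p * 0)
  meanImage <- array(rowMeans(matrix(x, ncol = N)), dim(x)[1:3])
  y <- .oneHot(labels)
  hist <- list()
  it <- 0L
  for (epoch in seq_len(cfg@maxEpochs)) {
    lr <- .lrAt(cfg, epoch)
    ord <- sample.int(N)
    starts <- seq(1, N, by = cfg@miniBatch)
    epochLoss <- 0
    epochAcc <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg@miniBatch - 1, N)]
      xb <- augment(x[, , , idx, drop = FALSE], meanImage, "train", cfg)
      fw <- .cnnForward(params, cfg, xb, train = TRUE)
      loss <- .cnnLoss(fw$prob, y[, idx, drop = FALSE])
      if (!is.finite(loss))
        stop("trainModel: training diverged (non-finite loss) at epoch ",
             epoch)
      acc <- mean(apply(fw$prob, 2, which.max) ==
                    apply(y[, idx, drop = FALSE], 2, which.max))
      g <- .cnnBackward(fw, params, cfg, xb, y[, idx, drop = FALSE])
      for (p in names(params)) {
        vel[[p]] <- cfg@momentum * vel[[p]] -
          lr * (g[[p]] + cfg@l2Factor * params[[p]])
        params[[p]] <- params[[p]] + vel[[p]]
      }
      it <- it + 1L
      hist[[it]] <- data.frame(iteration = it, epoch = epoch, lr = lr,
                               loss = loss, accuracy = acc)
      epochLoss <- epochLoss + loss * length(idx)
      epochAcc <- epochAcc + acc * length(idx)
    }
    if (verbose)
      .msg("epoch %d/%d: lr %g, loss %.4f, acc %.3f", epoch, cfg@maxEpochs,
           lr, epochLoss / N, epochAcc / N)
  }
  model@params <- params
  model@meanImage <- meanImage
  model@history <- do.call(rbind, hist)
  model@trained <- TRUE
  model
}

#' Predict class probabilities for time-frequency images
#'
#' Deterministic evaluation-mode forward pass (no dropout, no random crop):
#' images are zero-centred with the training mean image and pushed through
#' the network. Probabilities are softmax outputs, so each row is
#' nonnegative and sums to one; the positive-class (normal) probability is
#' the ROC score.
#'
#' @param object a [CNNModel-class].
#' @param images a [TFImageSet-class] or an (R, R, 3, N) array at the
#'   model's input resolution.
#' @param batchSize internal batch size for the forward pass.
#' @return An N x 2 matrix with columns `normal` and `pathological`.
#' @export
setMethod("predict", "CNNModel", function(object, images, batchSize = 100) {
  cfg <- object@config
  x <- if (is(images, "TFImageSet")) imageArray(images) else images
  if (dim(x)[1] != cfg@inputResolution || dim(x)[3] != cfg@numChannels)
    stop(sprintf("predict: image shape %s does not match model input %dx%dx%d",
                 paste(dim(x)[1:3], collapse = "x"), cfg@inputResolution,
                 cfg@inputResolution, cfg@numChannels))
  N <- dim(x)[4]
  out <- matrix(0, N, 2, dimnames = list(NULL, .CLASSES))
  for (s in seq(1, N, by = batchSize)) {
    idx <- s:min(s + batchSize - 1, N)
    xb <- x[, , , idx, drop = FALSE]
    if (!is.null(object@meanImage)) xb <- xb - as.vector(object@meanImage)
    fw <- .cnnForward(object@params, cfg, xb, train = FALSE)
    out[idx, ] <- t(fw$prob)
  }
  out
})

#' Predicted class labels
#'
#' Argmax of [predict()][predict,CNNModel-method] probabilities.
#'
#' @param model a trained [CNNModel-class].
#' @param images images as in `predict`.
#' @return Character vector of `"normal"` / `"pathological"`.
#' @export
predictLabels <- function(model, images) {
  .CLASSES[max.col(predict(model, images), ties.method = "first")]
}
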