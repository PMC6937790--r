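#' Construct a CNN configuration
#'
#' Defaults are the optimum operating point of the pipeline: 5x5 kernels,
#' 15 filters, 20 epochs and mini-batch 50 on 64x64x3 images, trained with
#' stochastic gradient descent (momentum 0.9, initial learning rate 0.01
#' dropped by a factor of 0.1 every 10 epochs, L2 factor 1e-4), dropout 0.5,
#' and cross-channel normalisation with alpha 1e-3, beta 0.75, K 2 over a
#' 5-channel window. Convolution is valid (stride 1, no padding) and pooling
#' is 2x2 max pooling with stride 2, so the post-convolution width must tile
#' the pooling grid exactly -- the constructor validates this.
#'
#' @param inputResolution input image side length (pixels).
#' @param numChannels input channels.
#' @param kernelSize convolution kernel side length.
#' @param numFilters number of convolution filters.
#' @param maxEpochs number of training epochs.
#' @param miniBatch mini-batch size.
#' @param dropoutP dropout probability.
#' @param lrnAlpha,lrnBeta,lrnK,lrnWindow cross-channel normalisation
#'   parameters.
#' @param momentum SGD momentum.
#' @param initialLr initial learning rate.
#' @param lrDropFactor,lrDropPeriod learning-rate schedule.
#' @param l2Factor L2 regularisation factor (applied to weights and biases,
#'   whose per-layer multipliers are all 1).
#' @param fcWidth hidden fully-connected width.
#' @param init weight initialisation scheme: `"he"` (zero-mean Gaussian with
#'   per-layer standard deviation `sqrt(2 / fan-in)`, the standard choice
#'   for ReLU networks and the default here because it keeps the gradient
#'   signal alive through the wide flattening layer) or `"gaussian"` (fixed
#'   `initStd`).
#' @param initStd std. dev. used by the `"gaussian"` scheme.
#' @param cropPad reflect-padding width for random-crop augmentation.
#' @param seed RNG seed controlling initialisation, shuffling, crops and
#'   dropout.
#' @return A [CNNConfig-class].
#' @examples
#' cfg <- cnnConfig(inputResolution = 28)
#' cfg
#' @export
cnnConfig <- function(inputResolution = 64, numChannels = 3, kernelSize = 5,
                      numFilters = 15, maxEpochs = 20, miniBatch = 50,
                      dropoutP = 0.5, lrnAlpha = 1e-3, lrnBeta = 0.75,
                      lrnK = 2, lrnWindow = 5, momentum = 0.9,
                      initialLr = 0.01, lrDropFactor = 0.1,
                      lrDropPeriod = 10, l2Factor = 1e-4, fcWidth = 100,
                      init = c("he", "gaussian"), initStd = 0.01,
                      cropPad = 4, seed = 1) {
  init <- match.arg(init)
  new("CNNConfig", inputResolution = inputResolution,
      numChannels = numChannels, kernelSize = kernelSize,
      numFilters = numFilters, maxEpochs = maxEpochs, miniBatch = miniBatch,
      poolSize = 2, poolStride = 2, dropoutP = dropoutP,
      lrnAlpha = lrnAlpha, lrnBeta = lrnBeta, lrnK = lrnK,
      lrnWindow = lrnWindow, momentum = momentum, initialLr = initialLr,
      lrDropFactor = lrDropFactor, lrDropPeriod = lrDropPeriod,
      l2Factor = l2Factor, fcWidth = fcWidth, initScheme = init,
      initStd = initStd, cropPad = cropPad, seed = seed)
}

setMethod("show", "CNNConfig", function(object) {
  convOut <- object@inputResolution - object@kernelSize + 1
  cat(sprintf(paste0(
    "CNNConfig: input %dx%dx%d, conv %dx%d x%d -> %dx%dx%d, pool -> %dx%dx%d,\n",
    "  FC %d -> 2; epochs %d, batch %d, lr %g (x%g every %d epochs),\n",
    "  momentum %g, L2 %g, dropout %g, LRN(a=%g, b=%g, K=%g, w=%d), seed %d\n"),
    object@inputResolution, object@inputResolution, object@numChannels,
    object@kernelSize, object@kernelSize, object@numFilters,
    convOut, convOut, object@numFilters,
    convOut / 2, convOut / 2, object@numFilters,
    object@fcWidth, object@maxEpochs, object@miniBatch, object@initialLr,
    object@lrDropFactor, object@lrDropPeriod, object@momentum,
    object@l2Factor, object@dropoutP, object@lrnAlpha, object@lrnBeta,
    object@lrnK, object@lrnWindow, object@seed))
})

#' Build an untrained CNN
#'
#' Instantiates the eight-layer network (input with augmentation and
#' zero-centering, convolution, ReLU, cross-channel normalisation, 2x2 max
#' pooling, fully-connected, dropout, softmax classification). Weights are
#' drawn from a seeded zero-mean Gaussian (`initStd`), biases start at zero.
#'
#' @param cfg a [cnnConfig()].
#' @return An untrained [CNNModel-class].
#' @examples
#' m <- buildModel(cnnConfig(inputResolution = 28))
#' length(m@params$Wc)  # 5*5*3*15 kernel weights
#' @export
buildModel <- function(cfg = cnnConfig()) {
  validObject(cfg)
  set.seed(cfg@seed)
  k <- cfg@kernelSize
  FF <- cfg@numFilters
  C <- cfg@numChannels
  convOut <- cfg@inputResolution - k + 1
  d <- (convOut / 2)^2 * FF
  sdFor <- function(fanIn) {
    if (cfg@initScheme == "he") sqrt(2 / fanIn) else cfg@initStd
  }
  params <- list(
    Wc = array(rnorm(k * k * C * FF, 0, sdFor(k * k * C)), c(k, k, C, FF)),
    bc = numeric(FF),
    W1 = matrix(rnorm(cfg@fcWidth * d, 0, sdFor(d)), cfg@fcWidth, d),
    b1 = numeric(cfg@fcWidth),
    W2 = matrix(rnorm(2 * cfg@fcWidth, 0, sdFor(cfg@fcWidth)), 2, cfg@fcWidth),
    b2 = numeric(2))
  new("CNNModel", config = cfg, params = params, meanImage = NULL,
      history = data.frame(), trained = FALSE)
}

#' Cross-channel (local response) normalisation
#'
#' Normalises each activation by the summed squared activations of the
#' neighbouring channels:
#' `b_c = a_c / (K + alpha * sum_{c' in win(c)} a_{c'}^2 / W)^beta`,
#' where the window of nominal size `W` is centred on channel `c` and
#' truncated at the channel edges (the divisor stays `W`).
#'
#' @param a numeric array whose third dimension indexes channels
#'   (H, W, C) or (H, W, C, N).
#' @param alpha,beta,k,window normalisation parameters.
#' @return The normalised array, same shape as `a`.
#' @examples
#' a <- array(1, c(2, 2, 1))
#' crossChannelNormalize(a, alpha = 0, k = 1)  # identity
#' @export
crossChannelNormalize <- function(a, alpha = 1e-3, beta = 0.75, k = 2,
                                  window = 5) {
  if (k <= 0) stop("crossChannelNormalize: K must be positive")
  .lrnForward(a, alpha, beta, k, window)$y
}
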