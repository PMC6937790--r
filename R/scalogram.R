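.JET <- c("#00007F", "#0000FF", "#007FFF", "#00FFFF", "#7FFF7F",
          "#FFFF00", "#FF7F00", "#FF0000", "#7F0000")

.colormapFun <- function(name = "jet") {
  anchors <- switch(name,
    jet = .JET,
    gray = c("#000000", "#FFFFFF"),
    grey = c("#000000", "#FFFFFF"),
    stop("renderImage: unknown colormap '", name, "'"))
  ramp <- colorRamp(anchors, space = "rgb")
  function(v) ramp(v) / 255
}

# Separable bilinear resize of a matrix to nr x nc via interpolation weight
# matrices (pixel-centre alignment).  When downscaling, the triangle kernel
# is widened by the scale ratio (antialiased bilinear, as in the common
# image libraries): plain 2-tap interpolation would subsample a 4800-column
# scalogram almost at random.
.bilinearWeights <- function(nOut, nIn) {
  if (nIn == 1) return(matrix(1, nOut, 1))
  h <- max(1, nIn / nOut)                       # kernel half-width
  pos <- (seq_len(nOut) - 0.5) / nOut * nIn - 0.5  # 0-based input coords
  W <- matrix(0, nOut, nIn)
  for (i in seq_len(nOut)) {
    lo <- max(0, floor(pos[i] - h))
    hi <- min(nIn - 1, ceiling(pos[i] + h))
    j <- lo:hi
    w <- pmax(0, 1 - abs(j - pos[i]) / h)
    if (sum(w) == 0) w[which.min(abs(j - pos[i]))] <- 1
    W[i, j + 1] <- w / sum(w)
  }
  W
}

.resizeMatrix <- function(m, nr, nc) {
  A <- .bilinearWeights(nr, nrow(m))
  B <- .bilinearWeights(nc, ncol(m))
  A %*% m %*% t(B)
}

#' Render a scalogram as a fixed-resolution RGB image
#'
#' Coefficient magnitudes (optionally on a logarithmic scale, the field's
#' standard for time-frequency images) are min-max normalised per image,
#' mapped through a colormap (default `"jet"`) to RGB, and bilinearly
#' resized to a square `resolution x resolution` image with intensities in
#' `[0, 1]`. The normalisation range is computed outside the cone of
#' influence: with zero extension, the columns within one wavelet support
#' of the signal edge carry boundary artifacts proportional to the large
#' heart-rate baseline, and letting them set the range would crush the
#' interior dynamic range; those columns are clipped instead. A constant
#' coefficient matrix (degenerate normalisation) renders as the uniform
#' mid-colormap image.
#'
#' @param sc a [Scalogram-class].
#' @param resolution output side length in pixels (16, 28, 36 and 64 are
#'   the conventional settings).
#' @param colormap colormap name (`"jet"` or `"gray"`).
#' @param scaling `"linear"` (plain magnitudes) or `"log"`
#'   (`log10(|coef| + eps)` with `eps` 1e-3 of the in-range maximum, which
#'   keeps low-energy variability texture and high-energy transients
#'   visible together).
#' @param label class label to attach (defaults to `"unknown"`).
#' @return A [TFImage-class].
#' @export
renderImage <- function(sc, resolution = 64, colormap = "jet",
                        scaling = c("linear", "log"), label = "unknown") {
  scaling <- match.arg(scaling)
  a <- abs(coeffs(sc))
  if (!all(is.finite(a))) stop("renderImage: non-finite coefficients")
  waveletSupport <- 3  # order-2 Daubechies/symlet support in scale units
  coneWidth <- ceiling(waveletSupport * max(sc@scales)) + 1
  valid <- seq_len(max(1, ncol(a) - coneWidth))
  if (scaling == "log") {
    eps <- max(a[, valid, drop = FALSE]) * 1e-3
    if (eps == 0) eps <- 1
    a <- log10(a + eps)
  }
  rng <- range(a[, valid, drop = FALSE])
  v <- if (rng[2] > rng[1])
    pmin(pmax((a - rng[1]) / (rng[2] - rng[1]), 0), 1)
  else matrix(0.5, nrow(a), ncol(a))
  rgb <- .colormapFun(colormap)(as.vector(v))
  px <- array(0, c(resolution, resolution, 3))
  for (ch in 1:3) {
    chan <- matrix(rgb[, ch], nrow(v), ncol(v))
    px[, , ch] <- .resizeMatrix(chan, resolution, resolution)
  }
  px <- pmin(pmax(px, 0), 1)
  new("TFImage", pixels = px, label = label, sourceId = sc@sourceId,
      family = sc@family, exponent = sc@exponent)
}

#' Build the labelled time-frequency image dataset
#'
#' For every labelled clean signal, one image is rendered per combination of
#' mother wavelet family and scale exponent, so the dataset holds
#' `records x families x exponents` images (552 records with 2 families and
#' 3 exponents give 3312). Unlabelled records are skipped with a warning;
#' labels are copied from the records.
#'
#' @param signals list of [CleanSignal-class] objects carrying labels.
#' @param families character vector of wavelet families.
#' @param exponents integer vector of dyadic scale exponents.
#' @param resolution image side length in pixels.
#' @param colormap colormap name.
#' @param scaling magnitude scaling passed to [renderImage()].
#' @return A [TFImageSet-class].
#' @export
buildImageDataset <- function(signals, families = c("db2", "sym2"),
                              exponents = c(4, 5, 6), resolution = 64,
                              colormap = "jet", scaling = "linear") {
  labels <- vapply(signals, recordLabel, "")
  keep <- labels %in% c("normal", "pathological")
  if (any(!keep))
    warning(sprintf("buildImageDataset: skipping %d unlabelled record(s)",
                    sum(!keep)))
  signals <- signals[keep]
  nImg <- length(signals) * length(families) * length(exponents)
  images <- array(0, c(resolution, resolution, 3, nImg))
  lab <- character(nImg)
  meta <- data.frame(sourceId = character(nImg), family = character(nImg),
                     exponent = numeric(nImg), stringsAsFactors = FALSE)
  i <- 0L
  for (sg in signals) {
    for (fam in families) {
      for (J in exponents) {
        i <- i + 1L
        sc <- cwtCoefficients(sg, fam, J)
        img <- renderImage(sc, resolution, colormap, scaling,
                           label = recordLabel(sg))
        images[, , , i] <- pixels(img)
        lab[i] <- recordLabel(sg)
        meta$sourceId[i] <- recordId(sg)
        meta$family[i] <- fam
        meta$exponent[i] <- J
      }
    }
  }
  new("TFImageSet", images = images, labels = lab, meta = meta)
}

.subsetImageSet <- function(set, idx) {
  new("TFImageSet", images = set@images[, , , idx, drop = FALSE],
      labels = set@labels[idx], meta = set@meta[idx, , drop = FALSE])
}

#' Write a time-frequency image set as PNG files plus a manifest
#'
#' One PNG per image plus a tab-separated manifest (path, record id, label,
#' wavelet family, scale exponent, resolution). Requires the `png` package.
#'
#' @param set a [TFImageSet-class].
#' @param dir output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
writeImageSet <- function(set, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writeImageSet requires the 'png' package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(set@labels)
  paths <- character(n)
  for (i in seq_len(n)) {
    img <- set@images[, , , i]
    paths[i] <- file.path(dir, sprintf("%s_%s_J%d.png", set@meta$sourceId[i],
                                       set@meta$family[i],
                                       set@meta$exponent[i]))
    png::writePNG(aperm(img, c(1, 2, 3)), paths[i])
  }
  manifest <- data.frame(path = paths, sourceId = set@meta$sourceId,
                         label = set@labels, family = set@meta$family,
                         exponent = set@meta$exponent,
                         resolution = dim(set@images)[1])
  mf <- file.path(dir, "images.manifest")
  write.table(manifest, mf, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mf)
}
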