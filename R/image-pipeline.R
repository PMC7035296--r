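#' Maximum-entropy (Kapur) intensity threshold
#'
#' Returns the intensity level maximizing the sum of the Shannon
#' entropies of the foreground and background portions of the 256-bin
#' histogram (Kapur's criterion). Deterministic.
#'
#' @param image numeric or integer matrix; values in `[0, 1]` are scaled
#'   to the 8-bit range, anything else is clamped to `0..255` integers.
#' @return the threshold level on the `0..255` scale: pixels `<=`
#'   threshold form one class, pixels `>` the other.
#' @export
maxEntropyThreshold <- function(image) {
  v <- as.numeric(image)
  if (max(v) <= 1 && min(v) >= 0) v <- v * 255
  v <- pmin(pmax(round(v), 0), 255)
  if (length(unique(v)) < 2) stop("degenerate histogram: constant image")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  Pc <- cumsum(p)
  ent <- function(pp, tot) {
    pp <- pp[pp > 0] / tot
    -sum(pp * log(pp))
  }
  best <- -Inf; best_t <- 0L
  for (t in 0:254) {
    P1 <- Pc[t + 1L]
    if (P1 <= 0 || P1 >= 1) next
    H <- ent(p[1:(t + 1L)], P1) + ent(p[(t + 2L):256], 1 - P1)
    if (H > best) { best <- H; best_t <- t }
  }
  best_t
}

#' Binarize a grayscale panorama and clean the mask
#'
#' Maximum-entropy threshold (dark-object polarity by default: hyphae
#' appear dark on the bright transmitted-light background), optional
#' median despeckle beforehand, then a morphological opening and removal
#' of connected components smaller than `min_particle_px` (8-connected).
#' Cleaning never adds foreground pixels.
#'
#' @param image numeric matrix (grayscale) or [Panorama-class].
#' @param min_particle_px minimum connected-component size kept
#'   (default 50).
#' @param opening_radius disc radius of the opening, pixels (default 1;
#'   0 disables).
#' @param polarity `"dark"` (hyphae darker than background, default) or
#'   `"bright"`.
#' @param median_despeckle apply a radius-1 median filter first
#'   (default FALSE; synthetic input is already clean).
#' @return binary 0/1 integer matrix (hyphae = 1), or a [Panorama-class]
#'   when the input was one.
#' @export
binarizeAndClean <- function(image, min_particle_px = 50,
                             opening_radius = 1,
                             polarity = c("dark", "bright"),
                             median_despeckle = FALSE) {
  polarity <- match.arg(polarity)
  pan <- NULL
  if (is(image, "Panorama")) { pan <- image; image <- image@pixels }
  img <- image
  if (max(img) > 1) img <- img / 255
  if (median_despeckle)
    img <- EBImage::imageData(EBImage::medianFilter(EBImage::Image(img), 1))
  if (length(unique(as.numeric(img))) < 2) {
    mask <- matrix(0L, nrow(img), ncol(img))
  } else {
    thr <- maxEntropyThreshold(img) / 255
    mask <- if (polarity == "dark") img <= thr else img > thr
    mask <- matrix(as.integer(mask), nrow(img), ncol(img))
    if (opening_radius > 0) {
      brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
      mask <- EBImage::imageData(
        EBImage::opening(EBImage::Image(mask), brush))
      mask <- matrix(as.integer(mask > 0), nrow(img), ncol(img))
    }
    if (min_particle_px > 0 && any(mask > 0)) {
      lab <- .cc_label(mask == 1L, 8L)
      sizes <- tabulate(lab[lab > 0])
      drop <- which(sizes < min_particle_px)
      if (length(drop)) mask[lab %in% drop] <- 0L
    }
  }
  if (!is.null(pan)) initialize(pan, pixels = mask) else mask
}

#' Turn a binary panorama into a microscope-like grayscale image
#'
#' Renders hyphae dark on a bright background with optional Gaussian
#' noise, emulating transmitted-light contrast so that the full
#' thresholding pipeline can be exercised on synthetic data.
#'
#' @param pan a [Panorama-class] with a binary `pixels` matrix, or such a
#'   matrix.
#' @param fg,bg hypha and background gray levels, `0..255`
#'   (defaults 40 and 200).
#' @param noise_sd Gaussian noise standard deviation in gray levels
#'   (default 0).
#' @param seed seed used when `noise_sd > 0`.
#' @return grayscale matrix (`0..255`), or a [Panorama-class] when the
#'   input was one.
#' @export
asGrayscale <- function(pan, fg = 40, bg = 200, noise_sd = 0, seed = 1) {
  obj <- NULL
  if (is(pan, "Panorama")) { obj <- pan; pan <- pan@pixels }
  img <- ifelse(pan > 0, fg, bg)
  if (noise_sd > 0) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    img <- img + rnorm(length(img), 0, noise_sd)
  }
  img <- matrix(pmin(pmax(img, 0), 255), nrow(pan), ncol(pan))
  if (!is.null(obj)) initialize(obj, pixels = img) else img
}

#' Read a panorama image from disk
#'
#' @param path TIFF or PNG file.
#' @param time_h,pixel_scale,frame_index metadata to attach.
#' @return a [Panorama-class] (grayscale values on `0..255`).
#' @export
readPanorama <- function(path, time_h = NA_real_, pixel_scale = 3.516,
                         frame_index = NA_integer_) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  new("Panorama", pixels = matrix(img * 255, nrow(img), ncol(img)),
      time_h = time_h, pixel_scale = pixel_scale,
      frame_index = as.integer(frame_index))
}
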