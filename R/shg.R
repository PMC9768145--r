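## SHG image-stack quantification: Z-projections, imprint segmentation,
## full-width extents and relative damaged areas.

#' Construct an SHG image stack
#'
#' @param voxels 3D array (row, col, slice) of non-negative intensities;
#'   a 2D matrix is promoted to a single-slice stack
#' @param pixelSize lateral um per pixel (defaults to the 0.6 um of the
#'   confocal configuration emulated here)
#' @param voxelDepth um per slice
#' @param metadata acquisition metadata list
#' @return an [ImageStack-class]
#' @export
imageStack <- function(voxels, pixelSize = 0.6, voxelDepth = 1,
                       metadata = list()) {
  if (length(dim(voxels)) == 2) voxels <- array(voxels, c(dim(voxels), 1))
  new("ImageStack", voxels = voxels, pixelSize = pixelSize,
      voxelDepth = voxelDepth, metadata = metadata)
}

#' Read / write an SHG stack as multi-page TIFF
#'
#' Intensities are scaled to [0, 1] on write; analyses in this package
#' are invariant to that global scaling (background-relative thresholds).
#'
#' @param path TIFF file path
#' @param pixelSize,voxelDepth geometry in um
#' @return an [ImageStack-class]
#' @export
readShgStack <- function(path, pixelSize = 0.6, voxelDepth = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , i] <- p
  }
  imageStack(arr, pixelSize = pixelSize, voxelDepth = voxelDepth,
             metadata = list(source = path))
}

#' @rdname readShgStack
#' @param stack an [ImageStack-class]
#' @export
writeShgStack <- function(stack, path) {
  v <- stack@voxels
  mx <- max(v)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(v)[3]), function(i) v[, , i] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Z-projection of an image stack
#'
#' Per-pixel maximum or standard deviation across slices; the projections
#' used to delineate damage imprints in confocal SHG stacks.
#'
#' @param stack an [ImageStack-class] with >= 1 slice
#' @param mode "max" or "std"
#' @return a [ShgProjection-class]
#' @export
zProject <- function(stack, mode = c("max", "std")) {
  stopifnot(is(stack, "ImageStack"))
  mode <- match.arg(mode)
  v <- stack@voxels
  if (dim(v)[3] < 1) stop("empty stack")
  px <- switch(mode,
    max = apply(v, c(1, 2), max),
    std = if (dim(v)[3] == 1) matrix(0, dim(v)[1], dim(v)[2])
          else apply(v, c(1, 2), stats::sd))
  new("ShgProjection", pixels = px, pixelSize = stack@pixelSize,
      mode = mode)
}

## two-pass robust background: global median, exclude candidate dark
## pixels, median of the rest
.shgBackground <- function(pixels, dropThreshold) {
  med1 <- stats::median(pixels)
  cand <- pixels < (1 - dropThreshold) * med1
  stats::median(pixels[!cand])
}

#' Detect collagen damage imprints
#'
#' The projection is lightly Gaussian-smoothed (segmentation only; extent
#' measurements stay on the unsmoothed image), pixels darker than
#' (1 - dropThreshold) x the robust background are grouped into connected
#' components, and components smaller than `minArea` pixels are discarded.
#' Detection is invariant to global intensity scaling because the
#' threshold is background-relative.
#'
#' @param image a [ShgProjection-class]
#' @param dropThreshold fractional intensity drop defining damage
#'   (default 0.5)
#' @param minArea minimum component area in pixels
#' @param smoothSigma Gaussian smoothing sigma in pixels for segmentation
#'   (0 disables)
#' @return list of [DamageImprint-class] objects (empty if none found)
#' @export
detectImprints <- function(image, dropThreshold = 0.5, minArea = 50,
                           smoothSigma = 2) {
  stopifnot(is(image, "ShgProjection"))
  px <- image@pixels
  pxs <- if (smoothSigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(px),
                                      sigma = smoothSigma))
  else px
  bg <- .shgBackground(pxs, dropThreshold)
  binary <- pxs < (1 - dropThreshold) * bg
  if (!any(binary)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(binary * 1))
  lab <- EBImage::imageData(lab)
  out <- list()
  for (id in seq_len(max(lab))) {
    mask <- lab == id
    if (sum(mask) < minArea) next
    idx <- which(mask, arr.ind = TRUE)
    cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
    out[[length(out) + 1]] <- new("DamageImprint",
      center = c(x = (cx - 0.5) * image@pixelSize,
                 y = (cy - 0.5) * image@pixelSize),
      extentH = NA_real_, extentV = NA_real_,
      meanIntensityDrop = 1 - mean(px[mask]) / bg,
      mask = mask, pixelSize = image@pixelSize)
  }
  out
}

## crossing of a profile with a threshold, walking outward from `from`;
## recovery must be sustained over two samples so single noise spikes
## inside the dip do not truncate the width; linear sub-pixel
## interpolation at the crossing; errors when the profile never recovers
.profileCrossing <- function(vals, from, th, direction) {
  i <- from
  n <- length(vals)
  recovered <- function(j) {
    j2 <- j + direction
    vals[j] >= th && (j2 < 1 || j2 > n || vals[j2] >= th)
  }
  while (i >= 1 && i <= n && !recovered(i)) i <- i + direction
  if (i < 1 || i > n) stop("imprint touches border")
  prev <- i - direction
  if (prev < 1 || prev > n) return(i)
  # linear interpolation between the last below-threshold and first
  # recovered sample
  i - direction * (vals[i] - th) / (vals[i] - vals[prev])
}

#' Full-width extents of a damage imprint
#'
#' Takes horizontal and vertical intensity profiles through the imprint
#' center (averaged over a small band of rows/columns to suppress noise)
#' and measures the full width of the region below the
#' background-referenced threshold level
#' bg - dropThreshold x (bg - profile minimum), i.e. the full width at
#' half (by default) the dip depth, converted to um.
#'
#' @param image a [ShgProjection-class]
#' @param imprint a [DamageImprint-class] whose center lies inside the
#'   image
#' @param dropThreshold fraction of the dip depth defining the width level
#' @param band half-width in pixels of the averaging band around the
#'   profile line
#' @return the imprint with `extentH`/`extentV` filled in
#' @export
imprintExtents <- function(image, imprint, dropThreshold = 0.5, band = 3L) {
  stopifnot(is(image, "ShgProjection"), is(imprint, "DamageImprint"))
  px <- image@pixels
  ps <- image@pixelSize
  ci <- round(imprint@center[["y"]] / ps + 0.5)
  cj <- round(imprint@center[["x"]] / ps + 0.5)
  if (ci < 1 || ci > nrow(px) || cj < 1 || cj > ncol(px))
    stop("imprint center outside image")
  bg <- .shgBackground(px, 0.5)

  measure <- function(vals, at) {
    # light symmetric smoothing along the profile: suppresses noise
    # without biasing the half-level crossing position
    sm <- stats::filter(vals, rep(1 / 3, 3))
    sm[is.na(sm)] <- vals[is.na(sm)]
    vals <- as.numeric(sm)
    # pass 1: locate the dip against the global background
    depth <- bg - min(vals)
    th <- bg - dropThreshold * depth
    if (vals[at] >= th) return(NA_real_)
    left <- .profileCrossing(vals, at, th, -1L)
    right <- .profileCrossing(vals, at, th, +1L)
    # pass 2: re-reference to the local background flanking the dip
    # (fiber texture modulates the background along the profile)
    flankW <- max(5, ceiling((right - left) / 2))
    iL <- max(1, floor(left) - flankW):max(1, floor(left) - 2)
    iR <- min(length(vals), ceiling(right) + 2):
      min(length(vals), ceiling(right) + flankW)
    bgLoc <- stats::median(vals[unique(c(iL, iR))])
    inside <- vals[max(1, floor(left)):min(length(vals), ceiling(right))]
    th <- bgLoc - dropThreshold * (bgLoc - min(inside))
    if (vals[at] >= th) return(NA_real_)
    left <- .profileCrossing(vals, at, th, -1L)
    right <- .profileCrossing(vals, at, th, +1L)
    (right - left) * ps
  }
  rows <- max(1, ci - band):min(nrow(px), ci + band)
  cols <- max(1, cj - band):min(ncol(px), cj + band)
  imprint@extentH <- measure(colMeans(px[rows, , drop = FALSE]), cj)
  imprint@extentV <- measure(rowMeans(px[, cols, drop = FALSE]), ci)
  imprint
}

#' Relative damaged area
#'
#' 100 x (elliptical damage cross-section from the measured extents) over
#' the beam cross-section; with elliptical areas this reduces to the
#' product of the axis ratios, i.e. zeta_H x zeta_V in percent.
#'
#' @param imprint a measured [DamageImprint-class]
#' @param beam a [BeamSpec-class]
#' @return percent of the beam cross-sectional area
#' @export
relativeDamagedArea <- function(imprint, beam) {
  stopifnot(is(imprint, "DamageImprint"), is(beam, "BeamSpec"))
  if (is.na(imprint@extentH) || is.na(imprint@extentV))
    stop("imprint extents not measured; run imprintExtents() first")
  100 * (imprint@extentH * imprint@extentV) / (beam@widthH * beam@widthV)
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat("ImageStack: ", d[1], " x ", d[2], " px x ", d[3], " slices, ",
      object@pixelSize, " um/px, ", object@voxelDepth, " um/slice\n",
      sep = "")
})

setMethod("show", "DamageImprint", function(object) {
  cat("DamageImprint at (", signif(object@center[["x"]], 5), ", ",
      signif(object@center[["y"]], 5), ") um",
      if (!is.na(object@extentH))
        paste0(", extents ", signif(object@extentH, 4), " x ",
               signif(object@extentV, 4), " um"),
      ", drop ", signif(object@meanIntensityDrop, 3), "\n", sep = "")
})
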