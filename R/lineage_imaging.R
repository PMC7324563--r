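# Longitudinal quantification of multi-channel slice images.
#
# Images enter as numeric matrices in [0, 1] (one per channel). Tissue is
# segmented from brightfield; red/green lineage-reporter channels are
# thresholded within the tissue mask; yellow is the pixelwise intersection
# of red and green (the transient double-positive state marking new onset
# of insulin expression); all fractions are expressed relative to that
# timepoint's tissue area, so no cross-day registration is required.

as_ebimage <- function(img) {
  if (inherits(img, "Image")) img else EBImage::Image(img)
}

#' Segment tissue from a brightfield image
#'
#' Automatic (Otsu) thresholding followed by morphological closing and
#' selection of the largest connected component. Area is pixel count times
#' the squared pixel size.
#'
#' @param img Brightfield image, numeric matrix in \[0, 1\] (tissue brighter
#'   than background).
#' @param pixel_size Pixel size, micrometres per pixel.
#' @param closing_radius Radius (px) of the disc used for morphological
#'   closing.
#' @return List with `mask` (logical matrix) and `area_mm2`.
#' @export
segment_tissue <- function(img, pixel_size, closing_radius = 5) {
  img <- as.matrix(img)
  if (!length(img)) stop("empty image")
  if (pixel_size <= 0) stop("pixel size must be > 0")
  if (diff(range(img)) < 1e-8) stop("no tissue found (uniform image)")
  thr <- EBImage::otsu(as_ebimage(img))
  mask <- EBImage::Image(img > thr)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    mask <- EBImage::closing(mask, brush)
  }
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) stop("no tissue found (empty foreground)")
  sizes <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(sizes)
  m <- matrix(as.integer(lab) == keep, nrow = nrow(img))
  list(mask = m, area_mm2 = sum(m) * (pixel_size / 1000)^2)
}

#' Threshold a fluorescence channel within the tissue
#'
#' @param img Channel image, numeric matrix in \[0, 1\].
#' @param tissue_mask Logical tissue mask of the same shape.
#' @param method `"otsu"` for automatic thresholding over tissue pixels, or
#'   `"fixed"` with a threshold `t`.
#' @param t Fixed threshold (required when `method = "fixed"`); must lie
#'   within the representable intensity range \[0, 1\]. A threshold above
#'   every pixel yields an empty mask (e.g. an unexpressed channel).
#' @return Logical mask restricted to the tissue.
#' @export
channel_mask <- function(img, tissue_mask, method = c("otsu", "fixed"),
                         t = NULL) {
  method <- match.arg(method)
  img <- as.matrix(img)
  stopifnot(all(dim(img) == dim(tissue_mask)))
  if (method == "fixed") {
    if (is.null(t)) stop("fixed thresholding needs t")
    if (t < 0 || t > 1) stop("fixed threshold outside intensity range")
    return(img > t & tissue_mask)
  }
  vals <- img[tissue_mask]
  if (diff(range(vals)) < 1e-8) return(img > max(vals) & tissue_mask)
  # threshold computed over tissue pixels only
  thr <- EBImage::otsu(as_ebimage(matrix(vals, ncol = 1)),
                       range = range(vals))
  img > thr & tissue_mask
}

#' Red/green/yellow area fractions
#'
#' Yellow is defined as the pixelwise intersection of the red and green
#' masks (co-localisation), not a hue classifier. Each fraction is percent
#' of tissue area.
#'
#' @param red_mask,green_mask,tissue_mask Logical matrices of equal shape.
#' @return Named numeric vector `red_pct`, `green_pct`, `yellow_pct`.
#' @export
area_fractions <- function(red_mask, green_mask, tissue_mask) {
  stopifnot(all(dim(red_mask) == dim(tissue_mask)),
            all(dim(green_mask) == dim(tissue_mask)))
  n_t <- sum(tissue_mask)
  if (n_t == 0) stop("empty tissue mask")
  c(red_pct = 100 * sum(red_mask & tissue_mask) / n_t,
    green_pct = 100 * sum(green_mask & tissue_mask) / n_t,
    yellow_pct = 100 * sum(red_mask & green_mask & tissue_mask) / n_t)
}

#' Area-based viability
#'
#' Percent of stained area in the live channel:
#' `100 * |live| / (|live| + |dead|)`.
#'
#' @param live_mask,dead_mask Logical masks from the live (calcein) and
#'   dead (ethidium/PI) channels.
#' @return Viable percentage in \[0, 100\].
#' @export
viability <- function(live_mask, dead_mask) {
  n_live <- sum(live_mask); n_dead <- sum(dead_mask)
  if (n_live + n_dead == 0) stop("both masks empty")
  100 * n_live / (n_live + n_dead)
}

#' Count nuclei in a DAPI image
#'
#' Gaussian smoothing followed by local-maximum detection with minimum
#' distance suppression: a pixel is a nucleus centre if it is the maximum
#' of its `min_distance` neighbourhood, exceeds the intensity threshold,
#' and lies in the tissue. Two nuclei closer than `min_distance` merge into
#' one detection.
#'
#' @param img DAPI image, numeric matrix in \[0, 1\].
#' @param tissue_mask Logical tissue mask.
#' @param sigma Gaussian smoothing scale, px.
#' @param min_distance Minimum separation between detections, px.
#' @param threshold Intensity threshold on the smoothed image (fraction of
#'   its maximum).
#' @return List with `count` and `centers` (two-column matrix of row/col
#'   indices).
#' @export
count_nuclei <- function(img, tissue_mask, sigma = 2, min_distance = 5,
                         threshold = 0.2) {
  img <- as.matrix(img)
  stopifnot(all(dim(img) == dim(tissue_mask)))
  if (!any(tissue_mask)) stop("empty tissue mask")
  sm <- as.matrix(EBImage::gblur(as_ebimage(img), sigma = sigma))
  if (max(sm) <= 0)
    return(list(count = 0L, centers = matrix(numeric(0), ncol = 2)))
  brush <- EBImage::makeBrush(2 * min_distance + 1, shape = "disc")
  dil <- as.matrix(EBImage::dilate(as_ebimage(sm), brush))
  is_peak <- sm >= dil - 1e-12 & sm > threshold * max(sm) & tissue_mask
  centers <- which(is_peak, arr.ind = TRUE)
  # Suppress residual plateau duplicates within min_distance.
  if (nrow(centers) > 1) {
    keep <- rep(TRUE, nrow(centers))
    for (i in seq_len(nrow(centers) - 1)) {
      if (!keep[i]) next
      d <- sqrt((centers[, 1] - centers[i, 1])^2 +
                (centers[, 2] - centers[i, 2])^2)
      keep[d < min_distance & seq_along(d) > i] <- FALSE
    }
    centers <- centers[keep, , drop = FALSE]
  }
  list(count = nrow(centers), centers = centers)
}

#' Mean fluorescence intensity per cell
#'
#' Mean intensity over the tissue divided by the number of DAPI-positive
#' cells, the per-cell uptake measure used e.g. for 2-NBDG quantification.
#'
#' @param img Intensity image.
#' @param tissue_mask Logical tissue mask.
#' @param n_cells Number of cells (> 0).
#' @return MFI per cell, a.u.
#' @export
mfi_per_cell <- function(img, tissue_mask, n_cells) {
  if (n_cells <= 0) stop("n_cells must be > 0")
  mean(as.matrix(img)[tissue_mask]) / n_cells
}

#' Fold change between two group means
#'
#' @param a,b Group means; the ratio `a / b` is returned.
#' @return Fold change.
#' @export
fold_change <- function(a, b) {
  if (any(b == 0)) stop("denominator group mean is zero")
  a / b
}

#' Marker-positive nuclei
#'
#' A nucleus is marker-positive when the mean marker intensity in a disc
#' neighbourhood of its centre exceeds the threshold. Fractions over
#' several markers need not sum to one.
#'
#' @param img Marker channel image.
#' @param centers Two-column matrix of nucleus centres (row, col).
#' @param threshold Intensity threshold on the neighbourhood mean.
#' @param radius Neighbourhood radius, px.
#' @return List with `count`, `fraction`, and the per-nucleus logical
#'   `positive` vector.
#' @export
marker_positive_count <- function(img, centers, threshold, radius = 3) {
  img <- as.matrix(img)
  if (!nrow(centers)) return(list(count = 0L, fraction = NA_real_,
                                  positive = logical(0)))
  nr <- nrow(img); nc <- ncol(img)
  positive <- vapply(seq_len(nrow(centers)), function(i) {
    r0 <- max(1, centers[i, 1] - radius); r1 <- min(nr, centers[i, 1] + radius)
    c0 <- max(1, centers[i, 2] - radius); c1 <- min(nc, centers[i, 2] + radius)
    mean(img[r0:r1, c0:c1]) > threshold
  }, TRUE)
  list(count = sum(positive), fraction = sum(positive) / length(positive),
       positive = positive)
}

#' Longitudinal area report for an image series
#'
#' Applies tissue segmentation, channel thresholding and area-fraction
#' quantification to every timepoint of a slice image series. Fractions are
#' normalised to each day's own tissue area.
#'
#' @param series A slice image series: list with `days` (numeric vector),
#'   `pixel_size` (um/px), and `images` (one list per day of named channel
#'   matrices; roles `brightfield`, `red`, `green` are used, `live`/`dead`
#'   when present).
#' @param method Channel thresholding method, `"otsu"` or `"fixed"`.
#' @param t Fixed threshold when `method = "fixed"`.
#' @return Tidy tibble keyed by `day`, with `slice_area_mm2`, `red_pct`,
#'   `green_pct`, `yellow_pct` and `viable_pct` (NA when viability channels
#'   are absent).
#' @export
longitudinal_report <- function(series, method = "otsu", t = NULL) {
  stopifnot(length(series$days) >= 1,
            length(series$images) == length(series$days))
  rows <- lapply(seq_along(series$days), function(i) {
    ch <- series$images[[i]]
    seg <- segment_tissue(ch$brightfield, series$pixel_size)
    red <- channel_mask(ch$red, seg$mask, method, t)
    green <- channel_mask(ch$green, seg$mask, method, t)
    fr <- area_fractions(red, green, seg$mask)
    viab <- if (!is.null(ch$live) && !is.null(ch$dead)) {
      viability(channel_mask(ch$live, seg$mask, method, t),
                channel_mask(ch$dead, seg$mask, method, t))
    } else NA_real_
    tibble::tibble(day = series$days[i], slice_area_mm2 = seg$area_mm2,
                   red_pct = fr[["red_pct"]], green_pct = fr[["green_pct"]],
                   yellow_pct = fr[["yellow_pct"]], viable_pct = viab)
  })
  do.call(rbind, rows)
}
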