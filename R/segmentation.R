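#' Coarse binarization of a pathology intensity image
#'
#' First step of center-proliferation segmentation (CPS): threshold the
#' intensity image so that nuclei (the dark, hematoxylin-stained regions)
#' become foreground. With `threshold = "auto"` the cut is chosen by Otsu's
#' method on the image histogram.
#'
#' @param image Single-channel numeric matrix (use [read_image()] for RGB).
#' @param threshold `"auto"` (Otsu) or a numeric cut in the intensity range.
#' @param dark_foreground If `TRUE` (default) pixels strictly below the
#'   threshold are foreground, matching hematoxylin-dark nuclei on a bright
#'   background.
#' @return Binary mask. An empty foreground raises a warning, not an error.
#' @export
binarize <- function(image, threshold = "auto", dark_foreground = TRUE) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a single-channel numeric matrix")
  if (identical(threshold, "auto")) {
    rng <- range(image)
    if (diff(rng) < .Machine$double.eps^0.5) {
      warning("constant image: empty foreground")
      return(matrix(FALSE, nrow(image), ncol(image)))
    }
    threshold <- EBImage::otsu(EBImage::Image(image), range = rng)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L)
      stop("'threshold' must be \"auto\" or a single number")
    if (threshold < min(image) || threshold > max(image))
      stop("threshold ", threshold, " outside the intensity range [",
           min(image), ", ", max(image), "]")
  }
  mask <- if (dark_foreground) image < threshold else image > threshold
  if (!any(mask)) warning("binarization produced an empty foreground")
  mask
}

#' Circularity of a region
#'
#' `4*pi*area / perimeter^2`, with the perimeter estimated by chain-code
#' tracing of the region contour (axial steps 1, diagonal steps sqrt(2)).
#' Equals ~1 for a disk and decreases for elongated or irregular regions;
#' CPS keeps regions above 0.85. A single pixel (zero traced perimeter) is
#' defined to have circularity 1.
#'
#' @param region A binary mask containing one region, or a one-row
#'   data frame from [region_props()].
#' @return Scalar circularity.
#' @export
circularity <- function(region) {
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    return(region$circularity)
  }
  props <- region_props(as_mask(region))
  if (nrow(props) == 0L) stop("region is empty")
  if (nrow(props) > 1L)
    stop("mask contains ", nrow(props), " components; expected one region")
  props$circularity
}

#' Filter regions by circularity
#'
#' Keeps exactly the regions whose circularity is strictly greater than
#' `min_circularity`, preserving input order (CPS region selection step).
#'
#' @param regions Data frame from [region_props()].
#' @param min_circularity Threshold in `[0, 1]`, default 0.85.
#' @return The surviving rows of `regions`.
#' @export
filter_regions <- function(regions, min_circularity = 0.85) {
  stopifnot(is.data.frame(regions),
            min_circularity >= 0, min_circularity <= 1)
  regions[regions$circularity > min_circularity, , drop = FALSE]
}

#' Extract fixed-size nucleus patches around centers
#'
#' Crops an `n x n` window around each center (rows
#' `c - floor(n/2) ... c - floor(n/2) + n - 1`, likewise for columns;
#' windows reaching past the image border are padded with background) and
#' resizes it to `patch_size x patch_size`. Binary input is resized
#' nearest-neighbour, preserving binarity, and reduced to the single
#' connected component at (or nearest to) the patch center; intensity
#' input is resized bilinearly.
#'
#' @param image Intensity matrix or binary mask.
#' @param centers Matrix or data frame of centers, columns `(row, col)`.
#' @param n Pre-resize window side (pixels), `n >= 3`.
#' @param patch_size Output side length, default 100.
#' @return List of `nucleus_patch` objects carrying the patch `mask` (or
#'   `intensity`), the `source_center`, and label `"unknown"`.
#' @export
extract_patches <- function(image, centers, n, patch_size = 100) {
  stopifnot(n >= 3)
  if (is.data.frame(centers)) {
    cn <- intersect(c("centroid_row", "row", "center_row"), names(centers))
    rn <- intersect(c("centroid_col", "col", "center_col"), names(centers))
    centers <- cbind(centers[[cn[1L]]], centers[[rn[1L]]])
  }
  centers <- matrix(as.numeric(centers), ncol = 2L)
  is_mask <- is.logical(image)
  nr <- nrow(image); nc <- ncol(image)
  lapply(seq_len(nrow(centers)), function(i) {
    cr <- round(centers[i, 1L]); cc <- round(centers[i, 2L])
    if (cr < 1 || cr > nr || cc < 1 || cc > nc)
      stop(sprintf("center (%s, %s) lies outside the %dx%d image",
                   centers[i, 1L], centers[i, 2L], nr, nc))
    r0 <- cr - n %/% 2; c0 <- cc - n %/% 2
    rows <- r0:(r0 + n - 1L); cols <- c0:(c0 + n - 1L)
    win <- matrix(if (is_mask) FALSE else 0, n, n)
    rok <- rows >= 1 & rows <= nr; cok <- cols >= 1 & cols <= nc
    win[rok, cok] <- image[rows[rok], cols[cok]]
    if (is_mask) {
      out <- EBImage::imageData(EBImage::resize(
        EBImage::Image(win * 1), w = patch_size, h = patch_size,
        filter = "none")) > 0.5
      out <- keep_center_component(out)
      nucleus_patch(out, source_center = c(centers[i, 1L], centers[i, 2L]))
    } else {
      out <- EBImage::imageData(EBImage::resize(
        EBImage::Image(win), w = patch_size, h = patch_size,
        filter = "bilinear"))
      nucleus_patch(mask = NULL, source_center = c(centers[i, 1L], centers[i, 2L]),
                    intensity = out)
    }
  })
}

# keep only the connected component at the patch center (or, if the center
# pixel is background, the component closest to it)
keep_center_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) <= 1L) return(mask)
  ctr <- round(dim(mask) / 2 + 0.5)
  keep <- lab[ctr[1L], ctr[2L]]
  if (keep == 0L) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    d2 <- (idx[, 1L] - ctr[1L])^2 + (idx[, 2L] - ctr[2L])^2
    keep <- lab[idx[which.min(d2), , drop = FALSE]]
  }
  lab == keep
}

#' Center-proliferation segmentation (CPS)
#'
#' The full seed-center nucleus extraction procedure: coarse binarization,
#' 8-connected component labelling, circularity filtering (keeps round,
#' isolated nuclei), nucleus-center localisation at the region centroids,
#' and fixed-size patch extraction around each center.
#'
#' @param image Intensity matrix (nuclei dark).
#' @param threshold Passed to [binarize()].
#' @param min_circularity Circularity cut, default 0.85.
#' @param min_area Regions smaller than this many pixels are discarded as
#'   noise before the circularity test (default 30).
#' @param n Pre-resize patch window side, default 50.
#' @param patch_size Output patch side, default 100.
#' @return List with `patches` (list of `nucleus_patch`), `centers`
#'   (data frame `row`, `col`), and `regions` (the surviving
#'   [region_props()] rows).
#' @export
cps_segment <- function(image, threshold = "auto", min_circularity = 0.85,
                        min_area = 30, n = 50, patch_size = 100) {
  mask <- binarize(image, threshold)
  props <- region_props(mask)
  props <- props[props$area >= min_area, , drop = FALSE]
  props <- filter_regions(props, min_circularity)
  centers <- data.frame(row = props$centroid_row, col = props$centroid_col)
  patches <- if (nrow(centers) > 0L) {
    lab <- label_components(mask)
    sel <- lab %in% props$label
    extract_patches(matrix(sel, nrow(mask), ncol(mask)),
                    centers, n = n, patch_size = patch_size)
  } else list()
  list(patches = patches, centers = centers, regions = props)
}
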