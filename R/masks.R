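#' @importFrom stats runif rnorm sd setNames
#' @importFrom utils combn read.csv write.csv
NULL

#' Coerce to a binary nucleus mask
#'
#' Masks are plain logical matrices throughout the package: rows are image
#' rows (y, increasing downwards), columns are image columns (x). Anything
#' numeric is thresholded at 0.5, which also converts 0/255 PNG masks.
#'
#' @param x A logical or numeric matrix, an [EBImage::Image], or a
#'   `nucleus_patch` as returned by [extract_patches()].
#' @return A logical matrix.
#' @export
as_mask <- function(x) {
  if (inherits(x, "nucleus_patch")) return(x$mask)
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (is.logical(x) && is.matrix(x)) return(x)
  if (is.numeric(x) && is.matrix(x)) return(x > 0.5)
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a binary mask")
}

mask_area <- function(mask) sum(mask)

#' Foreground centroid of a mask
#'
#' @param mask Binary mask.
#' @return Named numeric vector `c(x, y)` in 1-based pixel-center
#'   coordinates (x = column, y = row).
#' @export
mask_centroid <- function(mask) {
  mask <- as_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  c(x = mean(idx[, 2L]), y = mean(idx[, 1L]))
}

#' Geometric center of a patch
#'
#' The pixel-center of the patch midpoint, `((ncol+1)/2, (nrow+1)/2)` in
#' 1-based coordinates; half-integral for even side lengths.
#'
#' @param dim Integer vector `c(nrow, ncol)` or a mask.
#' @return Named numeric vector `c(x, y)`.
#' @export
patch_center <- function(dim) {
  if (is.matrix(dim)) dim <- base::dim(dim)
  c(x = (dim[2L] + 1) / 2, y = (dim[1L] + 1) / 2)
}

#' Label connected foreground components
#'
#' Wraps [EBImage::bwlabel()] (4-connected) and, for the default
#' 8-connectivity, merges labels that touch diagonally so that thin tilted
#' structures are not split.
#'
#' @param mask Binary mask.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels, 0 = background, components numbered
#'   consecutively from 1 in first-appearance (column-major) order.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- as_mask(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  if (connectivity == 4 || max(lab) <= 1L) return(relabel(lab))
  if (connectivity != 8) stop("connectivity must be 4 or 8")
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal label adjacencies (both diagonal directions)
  p1 <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))
  p2 <- cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
  pairs <- rbind(p1, p2)
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    parent <- seq_len(max(lab))
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_along(parent), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  relabel(lab)
}

# renumber positive labels consecutively, preserving first appearance
relabel <- function(lab) {
  u <- unique(lab[lab > 0L])
  if (length(u) == 0L) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

# chain-code perimeter of each labelled object: the traced outer contour
# with axial steps counted 1 and diagonal steps sqrt(2)
contour_perimeter <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(numeric(0))
  oc <- EBImage::ocontour(lab)
  vapply(seq_len(n), function(i) {
    p <- oc[[i]]
    m <- nrow(p)
    if (is.null(m) || m < 2L) return(0)
    sum(sqrt(rowSums((p - p[c(2:m, 1L), , drop = FALSE])^2)))
  }, numeric(1))
}

#' Measure labelled regions
#'
#' Computes per-component area, chain-code perimeter, centroid, bounding
#' box and circularity (`4*pi*area/perimeter^2`; defined as 1 for a single
#' pixel whose traced perimeter is zero).
#'
#' @param x A binary mask (labelled with [label_components()]) or an
#'   integer label matrix.
#' @param connectivity Passed to [label_components()] when `x` is a mask.
#' @return A data frame with one row per region: `label`, `area`,
#'   `perimeter`, `centroid_row`, `centroid_col`, `circularity`, and the
#'   bounding box `rmin`, `rmax`, `cmin`, `cmax`.
#' @export
region_props <- function(x, connectivity = 8) {
  lab <- if (is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1))))
    label_components(x, connectivity) else x
  n <- max(lab)
  empty <- data.frame(label = integer(0), area = integer(0),
                      perimeter = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), circularity = numeric(0),
                      rmin = integer(0), rmax = integer(0),
                      cmin = integer(0), cmax = integer(0))
  if (n == 0L) return(empty)
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  area <- tabulate(l, n)
  crow <- rowsum(as.numeric(idx[, 1L]), l)[, 1L] / area
  ccol <- rowsum(as.numeric(idx[, 2L]), l)[, 1L] / area
  rmin <- vapply(split(idx[, 1L], l), min, numeric(1))
  rmax <- vapply(split(idx[, 1L], l), max, numeric(1))
  cmin <- vapply(split(idx[, 2L], l), min, numeric(1))
  cmax <- vapply(split(idx[, 2L], l), max, numeric(1))
  per <- contour_perimeter(lab)
  circ <- ifelse(per > 0, 4 * pi * area / per^2, 1.0)
  data.frame(label = seq_len(n), area = area, perimeter = per,
             centroid_row = crow, centroid_col = ccol, circularity = circ,
             rmin = rmin, rmax = rmax, cmin = cmin, cmax = cmax,
             row.names = NULL)
}

#' Read an image file as an intensity matrix
#'
#' PNG (and TIFF, if the tiff package is installed) input; RGB images are
#' converted to intensity with the BT.601 luma weights
#' 0.299 R + 0.587 G + 0.114 B. Values are in `[0, 1]`.
#'
#' @param path File path ending in .png, .tif or .tiff.
#' @return Numeric matrix (rows = image rows).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image extension: ", ext))
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3L]
    img <- if (ch >= 3L)
      0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    else img[, , 1L]
  }
  img
}

#' Read and write binary mask PNGs
#'
#' Masks are stored as 8-bit grayscale PNGs with foreground 255 and
#' background 0, the interchange format shared by the segmentation and
#' synthetic-data modules.
#'
#' @param mask Binary mask.
#' @param path Output (or input) PNG path.
#' @return `write_mask` returns `path` invisibly; `read_mask` a logical
#'   matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) png::readPNG(path) > 0.5

#' Write patches and their manifest
#'
#' Saves each patch mask as a PNG under `dir` and writes a CSV manifest
#' with columns `patch_path, source_image, center_row, center_col, label`,
#' the on-disk interface shared by segmentation and the synthetic
#' generator.
#'
#' @param patches List of `nucleus_patch` objects (or bare masks).
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param source_image Character recorded in the manifest.
#' @return The manifest data frame, invisibly; written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_patches <- function(patches, dir, prefix = "patch",
                          source_image = NA_character_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    if (!inherits(p, "nucleus_patch"))
      p <- nucleus_patch(as_mask(p), c(NA_real_, NA_real_))
    fn <- sprintf("%s_%04d.png", prefix, i)
    write_mask(p$mask, file.path(dir, fn))
    data.frame(patch_path = fn, source_image = source_image,
               center_row = p$source_center[1L],
               center_col = p$source_center[2L],
               label = p$label, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_patches
#' @param manifest_path Path to a manifest CSV written by [write_patches()].
#' @return `read_patches` returns a list of `nucleus_patch` objects.
#' @export
read_patches <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i)
    nucleus_patch(read_mask(file.path(dir, man$patch_path[i])),
                  c(man$center_row[i], man$center_col[i]),
                  label = man$label[i]))
}

nucleus_patch <- function(mask, source_center, label = "unknown",
                          intensity = NULL) {
  structure(list(mask = mask, source_center = source_center,
                 label = label, intensity = intensity),
            class = "nucleus_patch")
}

#' @export
print.nucleus_patch <- function(x, ...) {
  cat(sprintf("<nucleus_patch %dx%d, area %d px, label %s>\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$label))
  invisible(x)
}

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
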