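#' Translation that centers a nucleus in its patch
#'
#' The vector from the foreground centroid to the geometric patch center,
#' `(dx, dy) = (x_c - x_i, y_c - y_i)`, in 1-based pixel-center
#' coordinates (x = column, y = row).
#'
#' @param mask Nonempty binary mask.
#' @return Named numeric vector `c(dx, dy)`.
#' @export
centroid_translation <- function(mask) {
  mask <- as_mask(mask)
  ctr <- patch_center(dim(mask))
  cen <- mask_centroid(mask)
  c(dx = unname(ctr["x"] - cen["x"]), dy = unname(ctr["y"] - cen["y"]))
}

#' Scale factor bringing a nucleus to the standard area
#'
#' `sigma = sqrt(target_area / area)`, so that the scaled nucleus covers
#' approximately `target_area` pixels (1000 by default, the standard-space
#' area).
#'
#' @param mask Nonempty binary mask.
#' @param target_area Target foreground area in pixels.
#' @return Scalar scale factor (> 0).
#' @export
scale_factor <- function(mask, target_area = 1000) {
  a <- mask_area(as_mask(mask))
  if (a == 0L) stop("mask is empty")
  sqrt(target_area / a)
}

# second central moments of the foreground in (x, y) coordinates
central_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2L] - mean(idx[, 2L])
  y <- idx[, 1L] - mean(idx[, 1L])
  c(mu20 = mean(x * x), mu02 = mean(y * y), mu11 = mean(x * y))
}

#' Orientation of the principal axis
#'
#' Angle between the major principal axis (from second central moments of
#' the foreground) and the positive horizontal axis, canonicalized to
#' `(-pi/2, pi/2]`. The axis is defined modulo pi; the remaining
#' 180-degree ambiguity is inherent to second moments. A (near-)isotropic
#' mask has no preferred axis: the angle is returned as 0 with a warning.
#'
#' @param mask Binary mask with at least 2 foreground pixels.
#' @return Angle in radians.
#' @export
principal_angle <- function(mask) {
  mask <- as_mask(mask)
  if (mask_area(mask) < 2L) stop("mask needs at least 2 foreground pixels")
  mu <- central_moments(mask)
  aniso <- sqrt((mu["mu20"] - mu["mu02"])^2 + 4 * mu["mu11"]^2) /
    (mu["mu20"] + mu["mu02"])
  if (aniso < 1e-3) {
    warning("mask is isotropic; principal angle undefined, returning 0")
    return(0)
  }
  theta <- 0.5 * atan2(2 * mu["mu11"], mu["mu20"] - mu["mu02"])
  canonical_angle(unname(theta))
}

canonical_angle <- function(theta) {
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  if (theta <= -pi / 2 + 1e-15) theta <- theta + pi
  theta
}

#' Alignment transform into the uniform standard space
#'
#' An `alignment_transform` records the similarity map `a' = sigma R a + T`
#' taking original-mask coordinates into the standard space: `translation`
#' is the centroid-to-patch-center vector (the Eq-3 style offset), `scale`
#' the area-normalising factor and `angle` the principal-axis angle that
#' the rotation removes. [transform_points()] and [invert_points()] apply
#' the map and its inverse to continuous `(x, y)` coordinates.
#'
#' @param points Numeric matrix with columns `(x, y)`.
#' @param transform An `alignment_transform`.
#' @return Transformed coordinate matrix.
#' @name alignment_transform
NULL

new_transform <- function(translation, scale, angle, centroid) {
  structure(list(translation = translation, scale = scale, angle = angle,
                 centroid = centroid,
                 rotation = rotation_matrix(-angle)),
            class = "alignment_transform")
}

rotation_matrix <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)

#' @rdname alignment_transform
#' @export
transform_points <- function(points, transform) {
  stopifnot(inherits(transform, "alignment_transform"))
  p <- sweep(as.matrix(points), 2L, transform$centroid)
  q <- transform$scale * (p %*% t(transform$rotation))
  sweep(q, 2L, transform$centroid + transform$translation, `+`)
}

#' @rdname alignment_transform
#' @export
invert_points <- function(points, transform) {
  stopifnot(inherits(transform, "alignment_transform"))
  q <- sweep(as.matrix(points), 2L,
             transform$centroid + transform$translation)
  p <- (q %*% transform$rotation) / transform$scale
  sweep(p, 2L, transform$centroid, `+`)
}

#' @export
print.alignment_transform <- function(x, ...) {
  cat(sprintf(
    "<alignment_transform dx=%.2f dy=%.2f scale=%.3f angle=%.3f rad>\n",
    x$translation[1L], x$translation[2L], x$scale, x$angle))
  invisible(x)
}

#' Align a nucleus mask into the uniform standard space
#'
#' Maps a mask into the canonical frame shared by all nuclei: centroid at
#' the patch center, foreground area approximately `target_area` pixels,
#' and major principal axis horizontal. Rasterization samples the original
#' mask through the inverse similarity map (nearest neighbour), which
#' avoids the holes of forward mapping; a few corrective passes absorb the
#' residual rasterization drift in area, angle and centroid, always
#' resampling from the original mask so that resampling error does not
#' compound.
#'
#' @param mask Nonempty binary mask.
#' @param target_area Standard-space area (pixels); `NA` or `scale = FALSE`
#'   skips area normalisation (used for boundary features, which keep the
#'   original axis lengths).
#' @param rotate Rotate the principal axis to horizontal (default `TRUE`).
#' @param scale Normalise the area (default `TRUE`).
#' @param patch_size Output canvas side; defaults to the input size.
#' @param max_iter Maximum corrective passes (default 8).
#' @return List with `mask` (aligned binary mask) and `transform` (the
#'   composite [alignment_transform]).
#' @export
align_mask <- function(mask, target_area = 1000, rotate = TRUE, scale = TRUE,
                       patch_size = NULL, max_iter = 8) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("mask is empty")
  if (is.null(patch_size)) patch_size <- max(dim(mask))
  if (is.na(target_area)) scale <- FALSE

  centroid <- mask_centroid(mask)
  sigma <- if (scale) scale_factor(mask, target_area) else 1
  theta <- if (rotate && mask_area(mask) >= 2L)
    suppressWarnings(principal_angle(mask)) else 0
  dst <- patch_center(c(patch_size, patch_size))

  # nucleus must fit the output canvas after scaling
  idx <- which(mask, arr.ind = TRUE)
  rmax <- sqrt(max((idx[, 2L] - centroid["x"])^2 +
                   (idx[, 1L] - centroid["y"])^2))
  if (2 * sigma * rmax + 2 > patch_size * sqrt(2))
    stop("nucleus cannot fit the ", patch_size, "px canvas after scaling")

  dst_adj <- dst
  out <- NULL
  damp <- 1
  prev_resid <- NA_real_
  for (iter in seq_len(max_iter)) {
    out <- resample_mask(mask, centroid, sigma, theta, dst_adj, patch_size)
    if (!any(out)) stop("alignment produced an empty mask")
    a <- mask_area(out)
    cen <- mask_centroid(out)
    resid <- if (rotate && a >= 2L)
      suppressWarnings(principal_angle(out)) else 0
    ok_area <- !scale || abs(a - target_area) / target_area <= 0.02
    ok_ang <- !rotate || abs(resid) <= 0.01
    ok_cen <- max(abs(cen - dst)) <= 0.3
    if (ok_area && ok_ang && ok_cen) break
    if (scale) sigma <- sigma * sqrt(target_area / a)
    # damped update: the rasterized angle estimate is noisy and a
    # full-step update can cycle around the fixed point; halve the step
    # whenever the residual changes sign
    if (rotate) {
      if (!is.na(prev_resid) && sign(resid) != sign(prev_resid))
        damp <- damp / 2
      theta <- canonical_angle(theta + damp * resid)
      prev_resid <- resid
    }
    dst_adj <- dst_adj + (dst - cen)
  }
  tf <- new_transform(translation = dst - centroid[c("x", "y")],
                      scale = sigma, angle = theta, centroid = centroid)
  list(mask = out, transform = tf)
}

# inverse-map rasterization: each output pixel is sampled at a 2x2
# subpixel grid pulled back through the similarity (nearest neighbour at
# each sample) and re-binarized at coverage 0.5; the supersampling
# suppresses the boundary quantization noise that plain pixel-center
# sampling leaves in the second moments
resample_mask <- function(mask, centroid, sigma, theta, dst, patch_size) {
  g <- seq_len(patch_size)
  xo <- rep(g, each = patch_size)   # column index, x slow
  yo <- rep(g, times = patch_size)  # row index, y fast
  Rt <- rotation_matrix(theta)      # inverse of rotation_matrix(-theta)
  cover <- numeric(patch_size^2)
  for (ox in c(-0.25, 0.25)) for (oy in c(-0.25, 0.25)) {
    dx <- (xo + ox - dst["x"]) / sigma
    dy <- (yo + oy - dst["y"]) / sigma
    xs <- round(Rt[1L, 1L] * dx + Rt[1L, 2L] * dy + centroid["x"])
    ys <- round(Rt[2L, 1L] * dx + Rt[2L, 2L] * dy + centroid["y"])
    ok <- xs >= 1 & xs <= ncol(mask) & ys >= 1 & ys <= nrow(mask)
    hit <- numeric(length(xo))
    hit[ok] <- mask[cbind(ys[ok], xs[ok])]
    cover <- cover + hit
  }
  matrix(cover >= 2, nrow = patch_size, ncol = patch_size)
}
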