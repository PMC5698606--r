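#' Extract the closed outer boundary of a nucleus
#'
#' Holes are filled first, so only the outer contour remains. The default
#' backend is the morphological inner gradient `mask & !erode(mask)`,
#' which is deterministic, parameter-free and exactly one pixel wide. A
#' Canny-style backend (Gaussian smoothing, Sobel gradients, non-maximum
#' suppression, hysteresis) is available for users who prefer classic
#' edge detection; on a binary mask both localise the same contour, but
#' Canny introduces smoothing and hysteresis parameters.
#'
#' The mask is expected to be pose-aligned (same center and direction,
#' via the translation and rotation of the standard space) before its
#' boundary enters the landmark pipeline.
#'
#' @param mask Nonempty binary mask with a single foreground component.
#' @param method `"gradient"` (default) or `"canny"`.
#' @param sigma,low,high Canny parameters: Gaussian sigma and the
#'   hysteresis thresholds as fractions of the maximum gradient.
#' @return Logical matrix marking boundary pixels.
#' @export
extract_boundary <- function(mask, method = c("gradient", "canny"),
                             sigma = 1, low = 0.1, high = 0.3) {
  method <- match.arg(method)
  mask <- as_mask(mask)
  if (!any(mask)) stop("mask is empty")
  mask <- EBImage::imageData(EBImage::fillHull(mask * 1)) > 0.5
  ncomp <- max(label_components(mask))
  if (ncomp > 1L)
    stop("mask has ", ncomp, " components; expected a single nucleus")
  if (method == "gradient") {
    er <- EBImage::imageData(
      EBImage::erode(mask * 1, EBImage::makeBrush(3, "box"))) > 0.5
    mask & !er
  } else {
    canny_edges(mask * 1, sigma = sigma, low = low, high = high)
  }
}

# minimal Canny on a (binary) image: blur, Sobel, NMS, hysteresis
canny_edges <- function(img, sigma = 1, low = 0.1, high = 0.3) {
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)        # d/dcol
  gx <- EBImage::imageData(EBImage::filter2(EBImage::Image(sm), kx))
  gy <- EBImage::imageData(EBImage::filter2(EBImage::Image(sm), t(kx)))
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  sector <- (floor(ang / (pi / 4) + 0.5) %% 4) + 1  # 1:E-W 2:NE-SW 3:N-S 4:NW-SE
  nr <- nrow(img); nc <- ncol(img)
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))  # (drow, dcol) per sector
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  keep <- matrix(FALSE, nr, nc)
  for (s in 1:4) {
    d <- off[[s]]
    n1 <- shift(mag, d[1L], d[2L]); n2 <- shift(mag, -d[1L], -d[2L])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  nms <- mag * keep
  m <- max(nms)
  if (m == 0) return(matrix(FALSE, nr, nc))
  strong <- nms >= high * m
  cand <- nms >= low * m
  lab <- label_components(cand)
  good <- unique(lab[strong & lab > 0L])
  lab > 0L & lab %in% good
}

#' Ellipse template of a nucleus
#'
#' Fits the moment-equivalent ellipse of a direction-aligned nucleus and
#' places `k` ordered template points on it at equal polar-angle
#' intervals `2*pi/k` (pi/6 for the default k = 12), anticlockwise from
#' the initial angle on the positive horizontal axis:
#' `x = a cos(theta), y = b sin(theta)` relative to the centroid, where
#' `a >= b` are the semi-major and semi-minor axis lengths derived from
#' the second central moments (`a = 2 sqrt(lambda_max)`).
#'
#' @param mask Nonempty, direction-aligned binary mask.
#' @param k Number of template points, default 12.
#' @param initial_angle Polar angle of the first point (radians),
#'   default 0.
#' @return An `ellipse_template`: list with `a`, `b`, `center` (x, y),
#'   `angles` and `points` (k x 2 matrix of absolute x, y coordinates).
#' @export
ellipse_template <- function(mask, k = 12, initial_angle = 0) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("mask is empty")
  stopifnot(k >= 3)
  mu <- central_moments(mask)
  tr <- mu["mu20"] + mu["mu02"]
  det <- mu["mu20"] * mu["mu02"] - mu["mu11"]^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  if (b < 0.5) stop("degenerate mask: minor axis ~ 0")
  cen <- mask_centroid(mask)
  angles <- initial_angle + (seq_len(k) - 1L) * 2 * pi / k
  pts <- cbind(x = cen["x"] + a * cos(angles),
               y = cen["y"] + b * sin(angles))
  rownames(pts) <- NULL
  structure(list(a = unname(a), b = unname(b), center = cen,
                 angles = angles, points = pts),
            class = "ellipse_template")
}

#' @export
print.ellipse_template <- function(x, ...) {
  cat(sprintf("<ellipse_template a=%.2f b=%.2f, %d points>\n",
              x$a, x$b, nrow(x$points)))
  invisible(x)
}

#' Boundary feature points (landmarks)
#'
#' For each of the `k` template points on the fitted ellipse, selects the
#' nucleus boundary pixel at minimum Euclidean distance. Ties are broken
#' by the smallest (row, col) in lexicographic order, making the
#' selection deterministic. Landmarks inherit the template-point
#' ordering.
#'
#' @param boundary Logical boundary matrix from [extract_boundary()], or
#'   a two-column (x, y) coordinate matrix of boundary pixels.
#' @param template An [ellipse_template()].
#' @return A `landmark_set`: list with `points` (k x 2 matrix of x, y
#'   pixel coordinates) and `template`.
#' @export
boundary_feature_points <- function(boundary, template) {
  stopifnot(inherits(template, "ellipse_template"))
  if (is.logical(boundary)) {
    idx <- which(boundary, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("boundary is empty")
    bx <- idx[, 2L]; by <- idx[, 1L]
  } else {
    boundary <- as.matrix(boundary)
    if (nrow(boundary) == 0L) stop("boundary is empty")
    bx <- boundary[, 1L]; by <- boundary[, 2L]
  }
  ord <- order(by, bx)  # lexicographic (row, col) tie-break
  bx <- bx[ord]; by <- by[ord]
  tp <- template$points
  pts <- t(vapply(seq_len(nrow(tp)), function(j) {
    d2 <- (bx - tp[j, 1L])^2 + (by - tp[j, 2L])^2
    i <- which.min(d2)  # first minimum = smallest (row, col)
    c(x = bx[i], y = by[i])
  }, numeric(2)))
  structure(list(points = pts, template = template), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: %d boundary feature points>\n",
              nrow(x$points)))
  invisible(x)
}

#' Triangle-angle boundary-similarity features
#'
#' Enumerates all `choose(k, 3)` triangles over the ordered landmarks, in
#' lexicographic order of the vertex triple (i, j, k), and encodes each
#' triangle by interior-angle cosines computed with the law of cosines on
#' the squared side lengths (arguments clamped to `[-1, 1]` against
#' rounding). Angles are scale-free, so the features are invariant to
#' uniform scaling.
#'
#' `mode = "paper"` (default) stores one value per triangle — the cosine
#' of the angle at the middle vertex j — giving 220 dimensions for
#' k = 12 (and 56 for the 8-landmark optimal set). `mode = "full"`
#' stores both the angle at j and the angle at k (440 dimensions for
#' k = 12); the third angle is redundant since the three interior angles
#' sum to pi.
#'
#' Degenerate triples (coincident or collinear landmarks, which arise
#' when a template point maps to a repeated boundary pixel) take the
#' limiting cosine values; their count is recorded in the `"degenerate"`
#' attribute.
#'
#' @param landmarks A [boundary_feature_points()] landmark set, or a
#'   k x 2 coordinate matrix.
#' @param mode `"paper"` or `"full"`.
#' @return Named numeric vector; names `BF.i.j.k` (and `.j`/`.k` suffixes
#'   for `mode = "full"`), attribute `degenerate` = number of degenerate
#'   triangles.
#' @export
triangle_features <- function(landmarks, mode = c("paper", "full")) {
  mode <- match.arg(mode)
  pts <- if (inherits(landmarks, "landmark_set")) landmarks$points
         else as.matrix(landmarks)
  k <- nrow(pts)
  if (k < 3L) stop("need at least 3 landmarks")
  tri <- combn(k, 3L)  # lexicographic (i, j, k) triples
  x <- pts[, 1L]; y <- pts[, 2L]
  d2 <- function(u, v) (x[u] - x[v])^2 + (y[u] - y[v])^2
  i <- tri[1L, ]; j <- tri[2L, ]; kk <- tri[3L, ]
  dij <- d2(i, j); djk <- d2(j, kk); dik <- d2(i, kk)
  cross <- (x[j] - x[i]) * (y[kk] - y[i]) - (x[kk] - x[i]) * (y[j] - y[i])
  degen <- dij == 0 | djk == 0 | dik == 0 | cross == 0
  # law of cosines: angle at j between sides j-i and j-k, angle at k
  # between sides k-i and k-j
  safe <- function(num, den) {
    out <- ifelse(den > 0, num / den, 1)
    pmin(1, pmax(-1, out))
  }
  cos_j <- safe(dij + djk - dik, 2 * sqrt(dij * djk))
  cos_k <- safe(dik + djk - dij, 2 * sqrt(dik * djk))
  nm <- sprintf("BF.%02d.%02d.%02d", i, j, kk)
  out <- if (mode == "paper") {
    stats::setNames(cos_j, nm)
  } else {
    v <- as.vector(rbind(cos_j, cos_k))
    stats::setNames(v, as.vector(rbind(paste0(nm, ".j"), paste0(nm, ".k"))))
  }
  attr(out, "degenerate") <- sum(degen)
  out
}

#' Boundary-similarity features of a nucleus mask
#'
#' Convenience wrapper running the full boundary pipeline on one mask:
#' pose alignment (center + direction only — axis lengths stay those of
#' the original segmented nucleus, so no area scaling is applied),
#' boundary extraction, ellipse-template landmark selection, and triangle
#' features.
#'
#' @param mask Nonempty binary mask.
#' @param k Number of landmarks, default 12.
#' @param mode Passed to [triangle_features()].
#' @param method Passed to [extract_boundary()].
#' @param initial_angle Passed to [ellipse_template()].
#' @return Named numeric feature vector (`choose(k, 3)` values for
#'   `mode = "paper"`).
#' @export
boundary_features <- function(mask, k = 12, mode = c("paper", "full"),
                              method = c("gradient", "canny"),
                              initial_angle = 0) {
  al <- align_mask(mask, target_area = NA, scale = FALSE)
  bd <- extract_boundary(al$mask, method = method)
  tpl <- ellipse_template(al$mask, k = k, initial_angle = initial_angle)
  lm <- boundary_feature_points(bd, tpl)
  triangle_features(lm, mode = mode)
}
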