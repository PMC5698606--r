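#' Parametric nucleus shape model
#'
#' A synthetic nucleus is a radially perturbed ellipse: in polar
#' coordinates about the center, the boundary radius is
#' `r(t) = r_ellipse(t - phi) * (1 + sum_h eps_h cos(h (t - phi) + psi_h))`,
#' where `r_ellipse` is the polar radius of the `(a, b)` ellipse, the
#' harmonics `h` and total perturbation amplitude `eps` control boundary
#' roughness, and `phi` is the orientation. The perturbation rides in the
#' nucleus frame (`t - phi`), so changing `phi` rotates the shape
#' rigidly. The region is star-shaped by construction, hence a single
#' connected component for any `eps < 0.5`.
#'
#' @param label Class label, `"normal"` or `"HCC"`.
#' @param a,b Semi-major and semi-minor axes (pixels), `a >= b > 0`.
#' @param eps Total radial perturbation amplitude as a fraction of the
#'   local radius, `0 <= eps < 0.5`.
#' @param harmonics Integer harmonics carrying the perturbation
#'   (default 2:5; harmonic 1 is excluded, it mostly shifts the
#'   centroid).
#' @param phi Orientation (radians).
#' @return A `nucleus_model` list.
#' @export
nucleus_model <- function(label = c("normal", "HCC"), a, b, eps = 0,
                          harmonics = 2:5, phi = 0) {
  label <- match.arg(label)
  stopifnot(a >= b, b > 0, eps >= 0, eps < 0.5)
  structure(list(label = label, a = a, b = b, eps = eps,
                 harmonics = as.integer(harmonics), phi = phi),
            class = "nucleus_model")
}

# boundary radius r(t) for angles t (absolute frame)
model_radius <- function(model, t, amp, psi) {
  u <- t - model$phi
  re <- model$a * model$b /
    sqrt((model$b * cos(u))^2 + (model$a * sin(u))^2)
  pert <- rep(0, length(t))
  for (ih in seq_along(model$harmonics))
    pert <- pert + amp[ih] * cos(model$harmonics[ih] * u + psi[ih])
  re * (1 + pert)
}

draw_perturbation <- function(model) {
  nh <- length(model$harmonics)
  if (model$eps == 0)
    return(list(amp = rep(0, nh), psi = rep(0, nh)))
  w <- runif(nh)
  list(amp = model$eps * w / sum(w), psi = runif(nh, 0, 2 * pi))
}

#' Rasterize a synthetic nucleus mask
#'
#' Draws the perturbation phases and per-harmonic amplitudes under
#' `seed`, then fills the star-shaped region `radius <= r(t)` on a
#' `patch_size` square canvas centered on the patch center. Bit-identical
#' for identical model and seed.
#'
#' @param model A [nucleus_model()].
#' @param patch_size Canvas side, default 100.
#' @param seed Integer seed.
#' @return A `nucleus_patch` whose mask holds one connected nucleus.
#' @export
generate_mask <- function(model, patch_size = 100, seed = 1) {
  stopifnot(inherits(model, "nucleus_model"))
  pert <- with_seed(seed, draw_perturbation(model))
  rmax <- model$a * (1 + model$eps)
  if (2 * rmax + 4 > patch_size)
    stop("nucleus (max radius ", round(rmax, 1), " px) exceeds the ",
         patch_size, "px patch")
  ctr <- patch_center(c(patch_size, patch_size))
  g <- seq_len(patch_size)
  dx <- rep(g, each = patch_size) - ctr["x"]   # column offset, x slow
  dy <- rep(g, times = patch_size) - ctr["y"]  # row offset, y fast
  t <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  inside <- r <= model_radius(model, t, pert$amp, pert$psi)
  mask <- matrix(inside, patch_size, patch_size)
  nucleus_patch(mask, source_center = unname(ctr[c("y", "x")]),
                label = model$label)
}

default_class_params <- function() {
  list(normal = list(aspect = c(1.0, 1.4), eps = c(0.0, 0.05),
                     area = c(600, 1200)),
       HCC = list(aspect = c(1.0, 2.2), eps = c(0.10, 0.30),
                  area = c(800, 2600)))
}

# draw class parameters; joint draws whose maximum radius cannot fit the
# patch (extreme area x aspect x roughness corner) are rejected and redrawn
draw_model <- function(label, params, patch_size = 100) {
  for (try in 1:100) {
    aspect <- runif(1, params$aspect[1L], params$aspect[2L])
    area <- runif(1, params$area[1L], params$area[2L])
    eps <- runif(1, params$eps[1L], params$eps[2L])
    b <- sqrt(area / (pi * aspect))
    if (2 * aspect * b * (1 + eps) + 4 <= patch_size) break
    if (try == 100L)
      stop("class parameters cannot produce a nucleus that fits the patch")
  }
  phi <- runif(1, -pi / 2, pi / 2)
  nucleus_model(label, a = aspect * b, b = b, eps = eps, phi = phi)
}

#' Generate a balanced two-class synthetic mask dataset
#'
#' Emulates the balanced one-nucleus-per-patch regime: `n_per_class`
#' masks per class, with per-nucleus shape parameters drawn from the
#' class archetypes. Defaults encode the qualitative pathology contrast —
#' normal nuclei are near-elliptical and regular (aspect 1.0-1.4,
#' roughness up to 0.05, area 600-1200 px), HCC nuclei are enlarged and
#' irregular (aspect up to 2.2, roughness 0.10-0.30, area 800-2600 px).
#' One global seed fans out to per-nucleus substreams, so datasets are
#' reproducible and extensible.
#'
#' @param n_per_class Masks per class.
#' @param patch_size Patch side, default 100.
#' @param seed Global seed.
#' @param class_params List with `normal` and `HCC` parameter ranges
#'   (`aspect`, `eps`, `area`); see Details for the defaults.
#' @return List with `masks` (named list of logical masks), `labels`
#'   (factor) and `manifest` (per-nucleus parameters and substream
#'   seeds).
#' @export
generate_dataset <- function(n_per_class, patch_size = 100, seed = 1,
                             class_params = default_class_params()) {
  stopifnot(n_per_class >= 1)
  n <- 2L * n_per_class
  labels <- rep(c("normal", "HCC"), each = n_per_class)
  info <- with_seed(seed, {
    sub <- sample.int(.Machine$integer.max - 1L, n)
    models <- lapply(seq_len(n), function(i)
      draw_model(labels[i], class_params[[labels[i]]], patch_size))
    list(sub = sub, models = models)
  })
  masks <- lapply(seq_len(n), function(i)
    generate_mask(info$models[[i]], patch_size, seed = info$sub[i])$mask)
  ids <- sprintf("%s%04d", ifelse(labels == "normal", "n", "h"),
                 seq_len(n))
  names(masks) <- ids
  manifest <- data.frame(
    id = ids, label = labels,
    a = vapply(info$models, `[[`, numeric(1), "a"),
    b = vapply(info$models, `[[`, numeric(1), "b"),
    eps = vapply(info$models, `[[`, numeric(1), "eps"),
    phi = vapply(info$models, `[[`, numeric(1), "phi"),
    seed = info$sub, stringsAsFactors = FALSE)
  list(masks = masks, labels = factor(labels, c("normal", "HCC")),
       manifest = manifest)
}

#' Generate a composite multi-nucleus intensity image
#'
#' A test bed for center-proliferation segmentation: dark, round-ish
#' nuclei placed without overlap (rejection sampling) on a bright noisy
#' background, returned together with the ground-truth centers and label
#' image. Nuclei here follow the regular archetype (aspect up to 1.3,
#' mild roughness), matching the round isolated seeds the CPS
#' circularity gate is designed to keep.
#'
#' @param n_nuclei Number of nuclei to place (0 gives background only).
#' @param image_size Square image side, default 512.
#' @param seed Integer seed.
#' @param fg,bg Mean nucleus and background intensities.
#' @param noise_sd Gaussian pixel noise, default 0.03.
#' @param min_gap Minimum boundary gap between nuclei (pixels).
#' @param max_retries Placement attempts per nucleus before giving up.
#' @return List with `image` (intensity matrix in `[0, 1]`), `centers`
#'   (data frame `row`, `col`), and `truth` (integer label image of the
#'   planted nuclei).
#' @export
generate_pathology_image <- function(n_nuclei, image_size = 512, seed = 1,
                                     fg = 0.30, bg = 0.85,
                                     noise_sd = 0.03, min_gap = 4,
                                     max_retries = 2000) {
  params <- list(aspect = c(1.0, 1.3), eps = c(0.0, 0.04),
                 area = c(500, 1100))
  with_seed(seed, {
    truth <- matrix(0L, image_size, image_size)
    centers <- matrix(numeric(0), 0L, 2L)
    radii <- numeric(0)
    placed <- 0L
    while (placed < n_nuclei) {
      model <- draw_model("normal", params)
      pert <- draw_perturbation(model)
      rmax <- model$a * (1 + model$eps)
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cr <- runif(1, rmax + 2, image_size - rmax - 1)
        cc <- runif(1, rmax + 2, image_size - rmax - 1)
        if (placed == 0L ||
            all(sqrt((centers[, 1L] - cr)^2 + (centers[, 2L] - cc)^2) >
                radii + rmax + min_gap)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place nucleus ", placed + 1L, " after ",
             max_retries, " tries; reduce n_nuclei or enlarge the image")
      placed <- placed + 1L
      centers <- rbind(centers, c(cr, cc))
      radii <- c(radii, rmax)
      # rasterize locally around the center
      rows <- max(1, floor(cr - rmax - 1)):min(image_size, ceiling(cr + rmax + 1))
      cols <- max(1, floor(cc - rmax - 1)):min(image_size, ceiling(cc + rmax + 1))
      dx <- rep(cols, each = length(rows)) - cc
      dy <- rep(rows, times = length(cols)) - cr
      t <- atan2(dy, dx)
      inside <- sqrt(dx^2 + dy^2) <=
        model_radius(model, t, pert$amp, pert$psi)
      loc <- matrix(inside, length(rows), length(cols))
      truth[rows, cols][loc] <- placed
    }
    img <- matrix(rnorm(image_size^2, bg, noise_sd),
                  image_size, image_size)
    if (placed > 0L)
      img[truth > 0L] <- rnorm(sum(truth > 0L), fg, noise_sd)
    img[] <- pmin(1, pmax(0, img))
    list(image = img,
         centers = data.frame(row = centers[, 1L], col = centers[, 2L]),
         truth = truth)
  })
}
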