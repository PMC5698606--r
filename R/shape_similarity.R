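#' Overlap scores between two masks
#'
#' The four set-cardinality similarity coefficients evaluated exactly on
#' the foreground pixel sets of a query region SR and a reference region
#' TR:
#' Dice `2|SR & TR| / (|SR| + |TR|)`, Jaccard `|SR & TR| / |SR | TR|`,
#' precision `|SR & TR| / |SR|` and recall `|SR & TR| / |TR|`.
#' By construction `dice = 2*jaccard / (1 + jaccard)` and Dice is the
#' harmonic mean of precision and recall. An empty SR yields precision 0
#' by convention (its other three scores are 0 already).
#'
#' @param sr Query mask (may be empty).
#' @param tr Reference mask (must be nonempty, same dimensions).
#' @return Named numeric vector of class `overlap_scores` with elements
#'   `dice`, `jaccard`, `precision`, `recall`, all in `[0, 1]`.
#' @export
overlap_metrics <- function(sr, tr) {
  sr <- as_mask(sr); tr <- as_mask(tr)
  if (!identical(dim(sr), dim(tr)))
    stop("masks differ in shape: ", paste(dim(sr), collapse = "x"),
         " vs ", paste(dim(tr), collapse = "x"))
  ns <- sum(sr); nt <- sum(tr)
  if (nt == 0L) stop("reference mask (TR) is empty")
  ni <- sum(sr & tr)
  structure(c(dice = 2 * ni / (ns + nt),
              jaccard = ni / (ns + nt - ni),
              precision = if (ns > 0L) ni / ns else 0,
              recall = ni / nt),
            class = "overlap_scores")
}

#' @export
print.overlap_scores <- function(x, ...) {
  cat(sprintf("dice %.4f  jaccard %.4f  precision %.4f  recall %.4f\n",
              x["dice"], x["jaccard"], x["precision"], x["recall"]))
  invisible(x)
}

#' Build the nucleus shape library
#'
#' Selects `n_per_class` masks per class (default 80 normal + 80 HCC, a
#' 160-entry library) and aligns each into the uniform standard space.
#' The entry order is fixed and persisted: downstream feature columns are
#' named after it. Selection is either an explicit id list (standing in
#' for manual curation) or a seeded uniform draw without replacement,
#' which in practice influences the final classification little.
#'
#' @param masks List of binary masks.
#' @param labels Class labels, values `"normal"` or `"HCC"`.
#' @param n_per_class Entries per class, default 80.
#' @param selection `"random"` (seeded draw) or `"manual"` (use `ids`).
#' @param ids For `selection = "manual"`: indices or names of the chosen
#'   masks, used verbatim in the given order.
#' @param seed Seed for the random draw.
#' @param target_area Standard-space area the entries are aligned to.
#' @param patch_size Canvas side of the aligned entries, default 100.
#' @return A `shape_library`: list with `masks` (aligned), `label`
#'   (factor, levels normal/HCC), `id`, `target_area`, `patch_size`, and
#'   a pixel-by-entry logical matrix `mat` used for fast feature
#'   computation.
#' @export
build_shape_library <- function(masks, labels, n_per_class = 80,
                                selection = c("random", "manual"),
                                ids = NULL, seed = 1,
                                target_area = 1000, patch_size = 100) {
  selection <- match.arg(selection)
  labels <- as.character(labels)
  stopifnot(length(masks) == length(labels))
  if (is.null(names(masks)))
    names(masks) <- sprintf("m%04d", seq_along(masks))
  if (selection == "manual") {
    if (is.null(ids)) stop("selection = \"manual\" requires 'ids'")
    pick <- if (is.character(ids)) match(ids, names(masks)) else as.integer(ids)
    if (anyNA(pick)) stop("unknown ids in manual selection")
  } else {
    pick <- with_seed(seed, {
      unlist(lapply(c("normal", "HCC"), function(cl) {
        cand <- which(labels == cl)
        if (length(cand) < n_per_class)
          stop("class ", cl, " has only ", length(cand),
               " masks; need ", n_per_class)
        sort(sample(cand, n_per_class))
      }))
    })
  }
  aligned <- lapply(masks[pick], function(m)
    align_mask(as_mask(m), target_area = target_area,
               patch_size = patch_size)$mask)
  lib <- structure(list(
    masks = aligned,
    label = factor(labels[pick], levels = c("normal", "HCC")),
    id = names(masks)[pick],
    target_area = target_area,
    patch_size = patch_size,
    mat = vapply(aligned, as.vector, logical(patch_size^2))),
    class = "shape_library")
  colnames(lib$mat) <- lib$id
  lib
}

#' @export
print.shape_library <- function(x, ...) {
  cat(sprintf("<shape_library: %d entries (%s), target area %d px>\n",
              length(x$masks),
              paste(sprintf("%d %s", table(x$label), levels(x$label)),
                    collapse = " + "),
              x$target_area))
  invisible(x)
}

#' @export
length.shape_library <- function(x) length(x$masks)

#' Shape-similarity feature vectors against the library
#'
#' Scores each aligned query mask (SR) against every library entry (TR)
#' with the requested overlap metrics, in library order. With all four
#' metrics and a 160-entry library this yields the full 640-dimensional
#' shape-similarity block (160 per metric); the Jaccard block alone is
#' the 160-dimensional JI feature.
#'
#' @param masks A single aligned mask or a list of them. Masks must be in
#'   the standard space of `library` (area within 5% of its target);
#'   unaligned input is refused.
#' @param library A [build_shape_library()] object.
#' @param metrics Subset of `c("DI", "JI", "P", "R")`; default all four.
#' @return Numeric matrix, one row per query, columns named
#'   `metric.libraryid` grouped by metric in library order.
#' @export
shape_features <- function(masks, library,
                           metrics = c("DI", "JI", "P", "R")) {
  stopifnot(inherits(library, "shape_library"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.list(masks)) masks <- list(masks)
  masks <- lapply(masks, as_mask)
  areas <- vapply(masks, sum, numeric(1))
  bad <- abs(areas - library$target_area) / library$target_area > 0.05
  if (any(bad))
    stop(sum(bad), " query mask(s) are not in the standard space ",
         "(area outside 5% of ", library$target_area,
         " px); run align_mask() first")
  Q <- vapply(masks, as.vector, logical(library$patch_size^2))
  ns <- colSums(Q)                       # |SR| per query
  nt <- colSums(library$mat)             # |TR| per entry
  I <- crossprod(Q * 1, library$mat * 1) # query x entry intersections
  out <- lapply(metrics, function(m) {
    v <- switch(m,
      DI = 2 * I / outer(ns, nt, `+`),
      JI = I / (outer(ns, nt, `+`) - I),
      P  = I / ns,
      R  = sweep(I, 2L, nt, `/`))
    colnames(v) <- paste(m, library$id, sep = ".")
    v
  })
  do.call(cbind, out)
}
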