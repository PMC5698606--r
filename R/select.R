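#' Cross-validated accuracy of single feature columns
#'
#' Shared engine of the two ranking procedures: one stratified fold
#' assignment (so columns are compared on identical folds), then a
#' per-column forest trained on that single column and scored by
#' cross-validated accuracy.
#'
#' @param table Feature table with `label`.
#' @param cols Character vector of columns to score; default all feature
#'   columns.
#' @param folds,n_trees,seed Cross-validation controls. Column ranking
#'   uses a lighter forest (default 100 trees) than the final model: a
#'   single-feature tree is a thresholded stump ensemble and stabilises
#'   with few trees.
#' @return Data frame `id`, `acc` in input column order.
#' @export
single_column_acc <- function(table, cols = NULL, folds = 10,
                              n_trees = 100, seed = 1) {
  table <- check_feature_table(table)
  if (is.null(cols)) cols <- setdiff(names(table), "label")
  fold_id <- stratified_folds(table$label, folds, seed)
  acc <- vapply(seq_along(cols), function(ci) {
    sub <- table[, c(cols[ci], "label")]
    correct <- 0L
    for (f in seq_len(folds)) {
      fit <- train_classifier(sub[fold_id != f, ], n_trees = n_trees,
                              mtry = 1L, seed = seed + 7919L * f + ci)
      pred <- predict(fit, sub[fold_id == f, , drop = FALSE])
      correct <- correct + sum(pred == sub$label[fold_id == f])
    }
    correct / nrow(sub)
  }, numeric(1))
  data.frame(id = cols, acc = acc, stringsAsFactors = FALSE)
}

#' Rank shape-library nuclei by single-feature accuracy
#'
#' Tests the discriminative performance of each library nucleus
#' separately: the feature table must hold one column per library entry
#' (e.g. the JI block), each scored by cross-validated accuracy on that
#' single column, then sorted from high to low. Ties keep the original
#' library order.
#'
#' @param table Feature table whose non-label columns are per-library-
#'   nucleus features.
#' @param folds,n_trees,seed Passed to [single_column_acc()].
#' @return Data frame `id`, `acc`, `rank`, ordered by decreasing
#'   accuracy.
#' @export
rank_library_nuclei <- function(table, folds = 10, n_trees = 100,
                                seed = 1) {
  res <- single_column_acc(table, folds = folds, n_trees = n_trees,
                           seed = seed)
  ord <- order(-res$acc, seq_len(nrow(res)))
  out <- res[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Grow the library subset along the ranking
#'
#' Starting from the top `start` ranked library nuclei, adds `step`
#' nuclei at a time and cross-validates the forest on each growing
#' column subset. Returns the full accuracy curve and the subset size
#' maximising mean accuracy (ties resolved toward the smaller, cheaper
#' subset).
#'
#' @param ranking Data frame from [rank_library_nuclei()].
#' @param table The feature table the ranking came from.
#' @param start First subset size, default 30.
#' @param step Increment, default 10.
#' @param folds,n_trees,seed Cross-validation controls.
#' @return List with `best_size` (argmax of mean accuracy, ties resolved
#'   to the smaller size), `best_size_1se` (smallest size within one
#'   standard error of the maximum — the parsimonious pick, robust on
#'   accuracy plateaus), `best_ids`, and `curve` (data frame `size`,
#'   `acc`, `se`).
#' @export
grow_library_subset <- function(ranking, table, start = 30, step = 10,
                                folds = 10, n_trees = 500, seed = 1) {
  ids <- ranking$id
  if (start > length(ids))
    stop("start (", start, ") exceeds the number of ranked ids (",
         length(ids), ")")
  sizes <- seq(start, length(ids), by = step)
  res <- vapply(sizes, function(s) {
    sub <- table[, c(ids[seq_len(s)], "label")]
    cv <- cross_validate(sub, folds = folds, n_trees = n_trees,
                         seed = seed)
    c(cv_mean_acc(cv), sd(cv$folds$ACC) / sqrt(nrow(cv$folds)))
  }, numeric(2))
  acc <- res[1L, ]; se <- res[2L, ]
  imax <- which.max(acc)  # first max = smallest size on ties
  best <- sizes[imax]
  best_1se <- sizes[min(which(acc >= acc[imax] - se[imax]))]
  list(best_size = best, best_size_1se = best_1se,
       best_ids = ids[seq_len(best)],
       curve = data.frame(size = sizes, acc = acc, se = se))
}

parse_triangle_cols <- function(cols) {
  m <- regmatches(cols, regexec("^BF\\.(\\d+)\\.(\\d+)\\.(\\d+)", cols))
  ok <- lengths(m) == 4L
  if (!any(ok)) stop("no triangle feature columns (BF.i.j.k) found")
  tri <- t(vapply(m[ok], function(g) as.integer(g[2:4]), integer(3)))
  list(cols = cols[ok], tri = tri)
}

#' Rank boundary landmarks by triangle occurrence
#'
#' Scores every triangle feature column separately by single-column
#' cross-validated accuracy, keeps the top fraction of triangles, and
#' counts how often each of the `k` landmarks occurs as a vertex among
#' them. Landmarks are ranked from high to low occurrence (ties keep
#' index order).
#'
#' @param table Feature table containing `BF.i.j.k` triangle columns.
#' @param k Number of landmarks, default 12.
#' @param folds,n_trees,seed Passed to [single_column_acc()].
#' @param top_frac Fraction of triangles (by accuracy) whose vertices are
#'   counted, default 0.5.
#' @return List with `landmarks` (data frame `point`, `count`, `rank`)
#'   and `triangles` (per-triangle accuracies).
#' @export
rank_boundary_points <- function(table, k = 12, folds = 10, n_trees = 100,
                                 seed = 1, top_frac = 0.5) {
  pc <- parse_triangle_cols(setdiff(names(table), "label"))
  res <- single_column_acc(table, cols = pc$cols, folds = folds,
                           n_trees = n_trees, seed = seed)
  m <- ceiling(top_frac * nrow(res))
  top <- order(-res$acc, seq_len(nrow(res)))[seq_len(m)]
  counts <- tabulate(as.vector(pc$tri[top, , drop = FALSE]), nbins = k)
  ord <- order(-counts, seq_len(k))
  landmarks <- data.frame(point = ord, count = counts[ord],
                          rank = seq_len(k))
  list(landmarks = landmarks, triangles = res)
}

#' Select triangle features spanned by the top landmarks
#'
#' Keeps exactly the triangle columns whose three vertices all lie among
#' the `p` best-ranked landmarks — `choose(p, 3)` columns, e.g. 56 for
#' the 8-landmark optimal set.
#'
#' @param ranking Result of [rank_boundary_points()] (or a data frame
#'   with a `point` column in rank order).
#' @param p Number of landmarks to keep, `p >= 3`.
#' @param feature_names Available feature column names.
#' @return Character vector of retained column names.
#' @export
select_top_landmarks <- function(ranking, p, feature_names) {
  if (p < 3L) stop("p must be at least 3")
  lm <- if (is.data.frame(ranking)) ranking else ranking$landmarks
  keep <- lm$point[seq_len(p)]
  pc <- parse_triangle_cols(feature_names)
  sel <- apply(pc$tri, 1L, function(v) all(v %in% keep))
  pc$cols[sel]
}
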