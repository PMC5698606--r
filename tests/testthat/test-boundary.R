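test_that("boundary extraction gives the closed outer contour", {
  sq <- matrix(FALSE, 7, 7); sq[3:5, 3:5] <- TRUE
  b <- extract_boundary(sq)
  expect_equal(sum(b), 8L)  # all square pixels except the center

  # holes are filled: the inner rim does not appear
  holed <- rect_mask(9, 9, 15); holed[8, 8] <- FALSE
  bh <- extract_boundary(holed)
  filled <- rect_mask(9, 9, 15)
  expect_identical(bh, extract_boundary(filled))

  d <- disk_mask(15)
  nb <- sum(extract_boundary(d))
  expect_gte(nb, 2 * pi * 15 * 0.8)
  expect_lte(nb, 2 * pi * 15 * 1.3)

  two <- matrix(FALSE, 30, 30); two[3:7, 3:7] <- TRUE; two[20:24, 20:24] <- TRUE
  expect_error(extract_boundary(two), "components")
})

test_that("canny backend localises the same contour as the gradient", {
  d <- disk_mask(15)
  nc <- sum(extract_boundary(d, method = "canny"))
  expect_gte(nc, 2 * pi * 15 * 0.7)
  expect_lte(nc, 2 * pi * 15 * 1.5)
})

test_that("ellipse template places k points by x = a cos, y = b sin", {
  m <- ellipse_mask(20, 10)
  tpl <- ellipse_template(m, k = 12)
  expect_equal(tpl$a, 20, tolerance = 0.03)
  expect_equal(tpl$b, 10, tolerance = 0.05)
  expect_true(tpl$a >= tpl$b)
  rel <- sweep(tpl$points, 2, c(tpl$center["x"], tpl$center["y"]))
  # angle 0 -> (a, 0); angle pi/2 -> (0, b); angle pi/6 -> (a cos30, b/2)
  expect_equal(unname(rel[1, ]), c(tpl$a, 0), tolerance = 1e-12)
  expect_equal(unname(rel[4, ]), c(0, tpl$b), tolerance = 1e-9)
  expect_equal(unname(rel[2, ]),
               c(tpl$a * cos(pi / 6), tpl$b * sin(pi / 6)),
               tolerance = 1e-12)
  expect_equal(nrow(tpl$points), 12L)
  expect_equal(diff(tpl$angles)[1], pi / 6)

  expect_error(ellipse_template(rect_mask(1, 30)), "degenerate")
})

test_that("landmarks are the nearest boundary pixels to template points", {
  m <- ellipse_mask(20, 10)
  tpl <- ellipse_template(m, k = 12)
  # boundary sampled densely on the template ellipse itself: fixed point
  t <- seq(0, 2 * pi, length.out = 720)
  bnd <- cbind(tpl$center["x"] + tpl$a * cos(t),
               tpl$center["y"] + tpl$b * sin(t))
  lm <- boundary_feature_points(bnd, tpl)
  expect_lt(max(sqrt(rowSums((lm$points - tpl$points)^2))), 1)

  # single-pixel boundary: every landmark collapses onto it
  one <- matrix(FALSE, 50, 50); one[20, 30] <- TRUE
  lm1 <- boundary_feature_points(one, tpl)
  expect_true(all(lm1$points[, 1] == 30 & lm1$points[, 2] == 20))
})

test_that("landmark selection equals exhaustive nearest-neighbour search", {
  for (s in 1:5) {
    rb <- random_blob(s, eps = c(0.05, 0.2), harmonics = 2:5)
    al <- align_mask(rb$mask, target_area = NA, scale = FALSE)
    bd <- extract_boundary(al$mask)
    tpl <- ellipse_template(al$mask, k = 12)
    lm <- boundary_feature_points(bd, tpl)
    idx <- which(bd, arr.ind = TRUE)
    for (j in 1:12) {
      d2 <- (idx[, 2] - tpl$points[j, 1])^2 + (idx[, 1] - tpl$points[j, 2])^2
      best <- which(d2 == min(d2))
      # tie rule: smallest (row, col)
      best <- best[order(idx[best, 1], idx[best, 2])][1]
      expect_equal(unname(lm$points[j, ]),
                   unname(c(idx[best, 2], idx[best, 1])))
    }
  }
})

test_that("triangle counts equal choose(k, 3) for k = 5..12", {
  for (k in 5:12) {
    set.seed(k)
    pts <- cbind(runif(k, 0, 50), runif(k, 0, 50))
    expect_length(triangle_features(pts), choose(k, 3))
    expect_length(triangle_features(pts, mode = "full"), 2 * choose(k, 3))
  }
})

test_that("triangle cosines match hand-computed triangles", {
  eq <- cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))  # equilateral
  tf <- triangle_features(eq, mode = "full")
  expect_equal(as.vector(tf), c(0.5, 0.5), tolerance = 1e-12)

  tri345 <- cbind(c(0, 4, 4), c(0, 0, 3))  # right angle at j, cos at k = 3/5
  tf2 <- triangle_features(tri345, mode = "full")
  expect_equal(as.vector(tf2), c(0, 3 / 5), tolerance = 1e-12)
  expect_identical(names(tf2), c("BF.01.02.03.j", "BF.01.02.03.k"))

  expect_equal(attr(triangle_features(cbind(c(0, 1, 2), c(0, 1, 2))),
                    "degenerate"), 1L)
})

test_that("interior angles sum to pi and match a dot-product oracle", {
  set.seed(31)
  for (rep in 1:100) {
    k <- sample(5:12, 1)
    pts <- cbind(runif(k, 0, 60), runif(k, 0, 60))
    tf <- triangle_features(pts, mode = "full")
    tri <- combn(k, 3)
    for (tcol in seq_len(ncol(tri))) {
      v <- tri[, tcol]
      P <- pts[v, ]
      ang <- function(at, o1, o2) {
        u <- P[o1, ] - P[at, ]; w <- P[o2, ] - P[at, ]
        acos(pmin(1, pmax(-1, sum(u * w) / sqrt(sum(u^2) * sum(w^2)))))
      }
      a_i <- ang(1, 2, 3); a_j <- ang(2, 1, 3); a_k <- ang(3, 1, 2)
      expect_lt(abs(a_i + a_j + a_k - pi), 1e-9)
      expect_lt(abs(cos(a_j) - tf[2 * tcol - 1]), 1e-9)
      expect_lt(abs(cos(a_k) - tf[2 * tcol]), 1e-9)
    }
  }
})

test_that("triangle features are invariant to uniform scaling", {
  set.seed(8)
  pts <- cbind(runif(12, 0, 40), runif(12, 0, 40))
  f1 <- triangle_features(pts)
  f2 <- triangle_features(pts * 3.7)
  expect_lt(max(abs(f1 - f2)), 1e-6)

  # and nearly so after rasterization of a scaled mask
  mod <- nucleus_model("normal", a = 20, b = 14, eps = 0.1,
                       harmonics = c(2, 3), phi = 0.4)
  mod2 <- nucleus_model("normal", a = 30, b = 21, eps = 0.1,
                        harmonics = c(2, 3), phi = 0.4)
  b1 <- boundary_features(generate_mask(mod, seed = 5)$mask)
  b2 <- boundary_features(generate_mask(mod2, seed = 5)$mask)
  expect_lt(mean(abs(b1 - b2)), 0.05)
})

test_that("boundary_features returns the documented dimensions", {
  m <- random_blob(2)$mask
  expect_length(boundary_features(m), 220L)
  expect_length(boundary_features(m, k = 8), 56L)
  expect_length(boundary_features(m, mode = "full"), 440L)
})
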