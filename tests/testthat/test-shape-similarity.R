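test_that("overlap metrics reproduce the set-cardinality formulas", {
  a <- disk_mask(8, 30)
  expect_equal(unclass(overlap_metrics(a, a)),
               c(dice = 1, jaccard = 1, precision = 1, recall = 1))

  b <- shift_mask(a, 0, 18)  # disjoint
  expect_equal(unname(unclass(overlap_metrics(b, a))), rep(0, 4))

  # |SR| = 100, |TR| = 100, |SR & TR| = 50
  sr <- matrix(FALSE, 20, 20); sr[1:10, 1:10] <- TRUE
  tr <- matrix(FALSE, 20, 20); tr[6:15, 1:10] <- TRUE
  om <- overlap_metrics(sr, tr)
  expect_equal(unname(om["dice"]), 0.5)
  expect_equal(unname(om["jaccard"]), 1 / 3)
  expect_equal(unname(om["precision"]), 0.5)
  expect_equal(unname(om["recall"]), 0.5)

  expect_error(overlap_metrics(sr, matrix(FALSE, 20, 20)), "empty")
  expect_error(overlap_metrics(sr, matrix(TRUE, 10, 10)), "shape")
})

test_that("overlap identities hold over random mask pairs", {
  set.seed(99)
  for (i in 1:200) {
    a <- matrix(runif(400) < 0.4, 20, 20)
    b <- matrix(runif(400) < 0.4, 20, 20)
    if (!any(b)) b[1, 1] <- TRUE
    om <- overlap_metrics(a, b)
    J <- om["jaccard"]
    expect_equal(unname(om["dice"]), unname(2 * J / (1 + J)),
                 tolerance = 1e-12)
    expect_true(J <= om["dice"] + 1e-15)
    if (om["precision"] + om["recall"] > 0)
      expect_equal(unname(om["dice"]),
                   unname(2 * om["precision"] * om["recall"] /
                          (om["precision"] + om["recall"])),
                   tolerance = 1e-12)
  }
})

test_that("overlap counts agree with a brute-force pixel double loop", {
  set.seed(5)
  for (rep in 1:20) {
    a <- matrix(runif(400) < 0.35, 20, 20)
    b <- matrix(runif(400) < 0.35, 20, 20)
    if (!any(b)) b[1, 1] <- TRUE
    ni <- 0L; nu <- 0L
    for (r in 1:20) for (cc in 1:20) {
      if (a[r, cc] && b[r, cc]) ni <- ni + 1L
      if (a[r, cc] || b[r, cc]) nu <- nu + 1L
    }
    om <- overlap_metrics(a, b)
    expect_equal(unname(om["jaccard"]), ni / nu)
    expect_equal(unname(om["dice"]), 2 * ni / (sum(a) + sum(b)))
  }
})

test_that("build_shape_library is balanced, seeded and deterministic", {
  dd <- generate_dataset(12, seed = 4)
  lib <- build_shape_library(dd$masks, dd$labels, n_per_class = 8, seed = 7)
  expect_length(lib, 16L)
  expect_equal(as.vector(table(lib$label)), c(8L, 8L))
  lib2 <- build_shape_library(dd$masks, dd$labels, n_per_class = 8, seed = 7)
  expect_identical(lib$id, lib2$id)

  # manual selection uses the given ids verbatim
  ids <- c(names(dd$masks)[3:4], names(dd$masks)[15:16])
  libm <- build_shape_library(dd$masks, dd$labels, selection = "manual",
                              ids = ids)
  expect_identical(libm$id, ids)

  expect_error(
    build_shape_library(dd$masks, dd$labels, n_per_class = 50, seed = 1),
    "only")
})

test_that("feature vectors follow library order and metric blocks", {
  dd <- generate_dataset(6, seed = 2)
  lib <- build_shape_library(dd$masks, dd$labels, n_per_class = 5, seed = 3)
  q <- align_mask(dd$masks[[1]])$mask
  sf <- shape_features(q, lib)
  expect_equal(ncol(sf), 4L * 10L)
  expect_identical(colnames(sf)[1:10], paste("DI", lib$id, sep = "."))
  sf_ji <- shape_features(q, lib, metrics = "JI")
  expect_equal(ncol(sf_ji), 10L)
  expect_equal(unname(sf[, paste("JI", lib$id, sep = ".")]),
               unname(sf_ji[1, ]))
  expect_true(all(sf >= 0 & sf <= 1))

  # a library entry scored against the library hits JI = 1 on itself
  self <- shape_features(lib$masks[[4]], lib, metrics = "JI")
  expect_equal(unname(self[1, 4]), 1.0)
  expect_true(all(self <= 1))

  # unaligned input is refused
  expect_error(shape_features(dd$masks[[1]], lib, metrics = "JI"),
               "align")
})

test_that("reordering the library permutes feature columns identically", {
  dd <- generate_dataset(6, seed = 8)
  ids <- c(names(dd$masks)[1:4], names(dd$masks)[7:10])
  lib <- build_shape_library(dd$masks, dd$labels, selection = "manual",
                             ids = ids)
  libr <- build_shape_library(dd$masks, dd$labels, selection = "manual",
                              ids = rev(ids))
  q <- align_mask(dd$masks[[5]])$mask
  f1 <- shape_features(q, lib, metrics = "JI")
  f2 <- shape_features(q, libr, metrics = "JI")
  expect_equal(unname(f1[1, ]), unname(rev(f2[1, ])))
})

test_that("JI features are stable under rigid + scale transforms", {
  dd <- generate_dataset(6, seed = 13)
  lib <- build_shape_library(dd$masks, dd$labels, n_per_class = 5, seed = 5)
  for (s in 1:10) {
    rb <- random_blob(s)
    f1 <- shape_features(align_mask(rb$mask)$mask, lib, metrics = "JI")
    set.seed(s + 77)
    sc <- runif(1, 0.8, 1.25)
    mod2 <- nucleus_model("normal", a = rb$model$a * sc, b = rb$model$b * sc,
                          eps = rb$model$eps, harmonics = rb$model$harmonics,
                          phi = canonical_angle_t(rb$model$phi + runif(1, 0, 2 * pi)))
    m2 <- shift_mask(generate_mask(mod2, seed = s + 1000)$mask,
                     round(runif(1, -6, 6)), round(runif(1, -6, 6)))
    f2 <- shape_features(align_mask(m2)$mask, lib, metrics = "JI")
    expect_lte(max(abs(f1 - f2)), 0.1)
  }
})
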