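sep_table <- function(n = 40, seed = 1, gap = 4) {
  set.seed(seed)
  lab <- rep(c("normal", "HCC"), each = n)
  data.frame(label = factor(lab, c("normal", "HCC")),
             f1 = rnorm(2 * n, ifelse(lab == "HCC", gap, 0)),
             f2 = rnorm(2 * n))
}

test_that("confusion metrics follow the ACC/SEN/SPE definitions", {
  pred <- c(rep("HCC", 90), rep("normal", 10), rep("normal", 80), rep("HCC", 20))
  truth <- c(rep("HCC", 100), rep("normal", 100))
  m <- evaluate_predictions(pred, truth)
  expect_equal(list(m$TP, m$FN, m$TN, m$FP), list(90L, 10L, 80L, 20L))
  expect_equal(m$ACC, 0.85)
  expect_equal(m$SEN, 0.90)
  expect_equal(m$SPE, 0.80)
  expect_false(m$undefined)

  all_right <- evaluate_predictions(truth, truth)
  expect_equal(c(all_right$ACC, all_right$SEN, all_right$SPE), c(1, 1, 1))

  # a one-class truth leaves the absent-class rate undefined, flagged
  one <- evaluate_predictions(rep("HCC", 5), rep("HCC", 5))
  expect_true(one$undefined)
  expect_true(is.na(one$SPE))

  expect_error(evaluate_predictions(character(0), character(0)), "empty")
  expect_error(evaluate_predictions("HCC", c("HCC", "normal")), "length")
})

test_that("a separable problem is learnt perfectly and deterministically", {
  tab <- sep_table()
  fit <- train_classifier(tab, n_trees = 100, seed = 3)
  expect_equal(mean(predict(fit, tab) == tab$label), 1.0)

  new <- sep_table(seed = 9)
  fit2 <- train_classifier(tab, n_trees = 100, seed = 3)
  expect_identical(predict(fit, new), predict(fit2, new))

  bad <- tab[tab$label == "HCC", ]
  expect_error(train_classifier(bad, n_trees = 10), "single class")
})

test_that("the ensemble prediction is the majority vote over trees", {
  tab <- sep_table(n = 30, gap = 1.2)
  fit <- train_classifier(tab, n_trees = 51, seed = 2)
  new <- sep_table(n = 25, seed = 4, gap = 1.2)
  trees <- predict(fit, new, type = "trees")
  expect_equal(dim(trees), c(50L, 51L))
  manual <- apply(trees, 1, function(r) {
    tal <- c(normal = sum(r == "normal"), HCC = sum(r == "HCC"))
    names(tal)[which.max(tal)]  # ties (impossible at 51 trees) to first
  })
  expect_identical(as.character(predict(fit, new)), unname(manual))
  votes <- predict(fit, new, type = "votes")
  expect_true(all(rowSums(votes) == 51))
})

test_that("cross-validation is stratified, seeded and sane", {
  tab <- sep_table(n = 30)
  cv <- cross_validate(tab, folds = 5, n_trees = 60, seed = 11)
  expect_gte(cv$summary$mean[cv$summary$metric == "ACC"], 0.99)
  cv2 <- cross_validate(tab, folds = 5, n_trees = 60, seed = 11)
  expect_identical(cv$assignments, cv2$assignments)
  expect_equal(cv$summary, cv2$summary)
  # each fold carries both classes (stratification)
  for (f in 1:5)
    expect_equal(length(unique(tab$label[cv$assignments == f])), 2L)

  expect_error(cross_validate(tab[1:3, ], folds = 5), "fewer|single")
})

test_that("shuffled labels drop accuracy to chance", {
  tab <- sep_table(n = 50)
  set.seed(21)
  tab$label <- sample(tab$label)
  cv <- cross_validate(tab, folds = 5, n_trees = 80, seed = 2)
  acc <- cv$summary$mean[cv$summary$metric == "ACC"]
  expect_gte(acc, 0.3); expect_lte(acc, 0.7)
})

test_that("make_split reproduces exact per-class counts", {
  lab <- rep(c("normal", "HCC"), each = 60)
  sp <- make_split(lab, n_train_per_class = 30, n_test_per_class = 25,
                   seed = 5)
  expect_length(sp$train, 60L)
  expect_length(sp$test, 50L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_equal(as.vector(table(lab[sp$train])), c(30L, 30L))
  expect_equal(as.vector(table(lab[sp$test])), c(25L, 25L))
  sp2 <- make_split(lab, 30, 25, seed = 5)
  expect_identical(sp, sp2)
  expect_error(make_split(lab, 50, 25, seed = 1), "need")
})
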