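test_that("multi-label metrics reproduce the hand-derived worked example", {
  truth <- rbind(c(1, 1, 0, 0, 0), c(0, 0, 1, 0, 0))
  pred <- rbind(c(1, 0, 0, 0, 0), c(0, 0, 1, 1, 0))
  r <- multilabel_metrics(truth, pred)
  expect_equal(r$precision, 0.75)
  expect_equal(r$coverage, 0.75)
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$absolute_true, 0)
  expect_equal(r$absolute_false, 0.2)
})

test_that("perfect and complementary predictions hit the metric extremes", {
  set.seed(3)
  truth <- random_bits(50L)
  perfect <- multilabel_metrics(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$coverage, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$absolute_true, 1)
  expect_equal(perfect$absolute_false, 0)
  comp <- multilabel_metrics(truth, 1L - truth)
  expect_equal(comp$absolute_true, 0)
  expect_equal(comp$accuracy, 0)
})

test_that("metrics agree with the set-arithmetic oracle on random data", {
  set.seed(17)
  for (r in 1:40) {
    truth <- random_bits(25L, p = runif(1, 0.1, 0.7))
    pred <- random_bits(25L, p = runif(1, 0.1, 0.7))
    got <- multilabel_metrics(truth, pred)
    want <- oracle_multilabel(truth, pred)
    expect_equal(got$precision, unname(want["precision"]), tolerance = 1e-13)
    expect_equal(got$coverage, unname(want["coverage"]), tolerance = 1e-13)
    expect_equal(got$accuracy, unname(want["accuracy"]), tolerance = 1e-13)
    expect_equal(got$absolute_true, unname(want["absolute_true"]))
    expect_equal(got$absolute_false, unname(want["absolute_false"]),
                 tolerance = 1e-13)
  }
})

test_that("the metric ordering invariants hold on random instances", {
  set.seed(23)
  for (r in 1:200) {
    truth <- random_bits(10L, p = runif(1, 0, 1))
    pred <- random_bits(10L, p = runif(1, 0, 1))
    m <- multilabel_metrics(truth, pred)
    expect_lte(m$absolute_true, m$accuracy + 1e-12)
    expect_lte(m$accuracy, min(m$precision, m$coverage) + 1e-12)
    expect_identical(m$absolute_false == 0, m$absolute_true == 1)
  }
})

test_that("binary metrics match their closed forms and conventions", {
  # balanced single-count confusion: MCC 0, ACC 0.5
  truth <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.1, 0.8, 0.2)  # TP, FN, FP, TN at 0.5
  b <- binary_metrics(truth, scores)
  expect_equal(unname(b$confusion), c(1L, 1L, 1L, 1L))
  expect_equal(b$mcc, 0)
  expect_equal(b$accuracy, 0.5)
  expect_equal(b$sensitivity, 0.5)
  expect_equal(b$specificity, 0.5)
  # perfect separation
  sep <- binary_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(sep$auc, 1)
  expect_equal(sep$mcc, 1)
  # all-tied scores give AUC 0.5 by mid-ranks
  expect_equal(rank_auc(c(1, 0, 1, 0), rep(0.4, 4L)), 0.5)
  # single-class truth: AUC undefined with warning
  expect_warning(u <- rank_auc(c(1, 1), c(0.2, 0.9)), "one class")
  expect_true(is.na(u))
})

test_that("AUC is invariant under strictly monotone score transforms and
           agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (r in 1:10) {
    truth <- c(rep(1L, 12L), rep(0L, 18L))
    scores <- rnorm(30L)
    a <- rank_auc(truth, scores)
    expect_equal(rank_auc(truth, plogis(3 * scores)), a)
    expect_equal(rank_auc(truth, rank(scores)), a)
    ref <- suppressMessages(as.numeric(pROC::auc(truth, scores,
                                                 direction = "<")))
    expect_equal(a, ref, tolerance = 1e-12)
  }
})

test_that("per-label confusion matrices conserve counts and prevalences", {
  set.seed(41)
  truth <- random_bits(30L)
  pred <- random_bits(30L)
  cms <- per_label_confusions(truth, pred)
  expect_named(cms, label_space())
  for (j in seq_len(5L)) {
    expect_equal(sum(cms[[j]]), 30L)
    expect_equal(sum(cms[[j]]["1", ]), sum(truth[, j]))
    expect_equal(sum(cms[[j]][, "1"]), sum(pred[, j]))
  }
  # perfect prediction: zero off-diagonals
  cmp <- per_label_confusions(truth, truth)
  for (j in 1:5) expect_equal(cmp[[j]]["1", "0"] + cmp[[j]]["0", "1"], 0L)
  # hand-enumerated single sample
  one <- per_label_confusions(matrix(c(1, 0, 0, 0, 0), 1L),
                              matrix(0L, 1L, 5L))
  expect_equal(unname(one$AMP["1", "0"]), 1L)
  for (j in 2:5) expect_equal(unname(one[[j]]["0", "0"]), 1L)
})
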