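test_that("confusion counts partition the examples at any cutoff", {
  scores <- c(0.9, 0.1)
  labels <- c(1, 0)
  cc <- confusion(scores, labels, 0.5)
  expect_equal(cc, list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  expect_equal(confusion(scores, labels, 0)$tp +
                 confusion(scores, labels, 0)$fp, 2L)
  cc_hi <- confusion(scores, labels, 0.95)
  expect_equal(cc_hi$tn + cc_hi$fn, 2L)
  expect_error(confusion(numeric(0), numeric(0), 0.5), "empty")
})

test_that("MCC follows the closed formula, its symmetry and its range", {
  expect_equal(mcc(list(tp = 75, tn = 75, fp = 0, fn = 0)), 1.0)
  expect_equal(mcc(list(tp = 50, tn = 40, fp = 10, fn = 20)), 0.5071,
               tolerance = 1e-4)
  expect_equal(mcc(list(tp = 50, tn = 40, fp = 10, fn = 20)),
               mcc(list(tp = 40, tn = 50, fp = 20, fn = 10)))
  expect_equal(mcc(list(tp = 10, tn = 0, fp = 0, fn = 0)), 0)
  set.seed(1)
  for (i in 1:50) {
    counts <- as.list(stats::setNames(sample(0:30, 4), c("tp", "fp", "tn", "fn")))
    expect_true(abs(mcc(counts)) <= 1)
    expect_true(accuracy(counts) >= 0 && accuracy(counts) <= 100 ||
                  sum(unlist(counts)) == 0)
  }
})

test_that("accuracy is reported as a percentage", {
  expect_equal(accuracy(list(tp = 5, tn = 5, fp = 0, fn = 0)), 100)
  expect_equal(accuracy(list(tp = 0, tn = 0, fp = 5, fn = 5)), 0)
  expect_equal(accuracy(list(tp = 25, tn = 25, fp = 25, fn = 25)), 50)
})

test_that("ROC area matches hand-counts, ties-half, and the pair oracle", {
  expect_equal(roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$area, 1.0)
  expect_equal(roc(c(0.8, 0.2, 0.6, 0.4), c(1, 1, 0, 0))$area, 0.5)
  expect_equal(roc(rep(0.3, 10), rep(c(0, 1), 5))$area, 0.5)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:500, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n, mean = labels), 1)  # coarse: forces ties
    r <- roc(scores, labels)
    expect_equal(r$area, brute_auroc(scores, labels), tolerance = 1e-12)
    expect_equal(auroc(scores, labels), r$area, tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
    expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
    # invariance under strictly increasing transforms
    expect_equal(auroc(exp(3 * scores), labels), r$area)
  }
})

test_that("the MCC sweep equals exhaustive enumeration", {
  expect_equal(max_mcc_sweep(c(0.9, 0.6, 0.4, 0.1), c(1, 1, 0, 0)),
               list(cutoff = 0.6, mcc = 1.0))
  inv <- max_mcc_sweep(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_lte(inv$mcc, 0)
  tied <- max_mcc_sweep(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(tied$mcc, 0)
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)
    expect_equal(max_mcc_sweep(scores, labels),
                 brute_best_cutoff(scores, labels))
  }
})

test_that("DeLong paired test agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(42)
  n <- 150
  labels <- rep(c(1, 0), each = n)
  truth_signal <- rnorm(2 * n, mean = labels)
  a <- truth_signal + rnorm(2 * n, sd = 0.8)
  b <- 0.4 * truth_signal + rnorm(2 * n, sd = 1)
  res <- delta_aroc_test(a, b, labels)
  ra <- pROC::roc(labels, a, direction = "<", levels = c(0, 1), quiet = TRUE)
  rb <- pROC::roc(labels, b, direction = "<", levels = c(0, 1), quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(res$auc_a, as.numeric(ra$auc), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(res$delta, as.numeric(ra$auc) - as.numeric(rb$auc),
               tolerance = 1e-12)
})

test_that("DeLong test is antisymmetric and null on identical scores", {
  set.seed(9)
  labels <- rep(c(1, 0), each = 40)
  a <- rnorm(80, labels)
  b <- rnorm(80, 0.5 * labels)
  same <- delta_aroc_test(a, a, labels)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  ab <- delta_aroc_test(a, b, labels)
  ba <- delta_aroc_test(b, a, labels)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(delta_aroc_test(a, b[-1], labels), "length")
  expect_error(delta_aroc_test(a, b, rep(1, 80)), "both classes")
})

test_that("the analytic DeLong variance is consistent with a bootstrap", {
  set.seed(7)
  n <- 100
  labels <- rep(c(1, 0), each = n)
  sig <- rnorm(2 * n, labels)
  a <- sig + rnorm(2 * n, sd = 1)
  b <- 0.5 * sig + rnorm(2 * n, sd = 1)
  res <- delta_aroc_test(a, b, labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  deltas <- replicate(400, {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auroc(a[idx], labels[idx]) - auroc(b[idx], labels[idx])
  })
  expect_gt(res$se / sd(deltas), 0.6)
  expect_lt(res$se / sd(deltas), 1.6)
})
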