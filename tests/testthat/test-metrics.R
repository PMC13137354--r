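# Image-quality and classification metrics against closed forms and
# independent oracles.

test_that("PSNR matches its closed form and is symmetric", {
  a <- matrix(0L, 8, 8); b <- matrix(16L, 8, 8)
  expect_equal(psnr(a, b), 10 * log10(255^2 / 256))
  expect_equal(psnr(a, b), psnr(b, a))
  expect_equal(psnr(a, a), Inf)
  expect_error(psnr(a, matrix(0L, 4, 4)), "shape")
})

test_that("SSIM is 1 on identical images, low on inversions, and matches
           the single-window closed form", {
  ph <- fixture_phantom(noise = 8)
  expect_equal(ssim(ph, ph), 1)
  inv <- 255L - ph$pixels
  expect_lt(ssim(ph, inv), 0.5)
  expect_equal(ssim(ph, inv), ssim(inv, ph))

  # constant vs constant+1: mu_a=100, mu_b=101, variances and covariance 0
  a <- matrix(100, 7, 7); b <- matrix(101, 7, 7)
  C1 <- (0.01 * 255)^2
  closed <- (2 * 100 * 101 + C1) / (100^2 + 101^2 + C1)
  expect_equal(ssim(a, b), closed, tolerance = 1e-12)
  expect_error(ssim(a, matrix(0, 3, 3)), "shape")
})

test_that("RMS contrast and relative change follow the stated conventions", {
  expect_equal(rms_contrast(matrix(7, 5, 5)), 0)
  img <- matrix(c(50, 150), 10, 10)
  expect_equal(rms_contrast(img), sd(img / mean(img)))
  expect_equal(relative_contrast_change(1.5, 1.5), 0)
  expect_equal(round(relative_contrast_change(1.1426, 1.1204), 4), -0.0194)
  expect_error(rms_contrast(matrix(0, 2, 2)), "zero-mean")
  expect_error(relative_contrast_change(0, 1), "zero")
})

test_that("confusion-count metrics match hand arithmetic and degenerate
           rules", {
  perfect <- classification_metrics(list(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1))
  m <- classification_metrics(list(tp = 2, tn = 5, fp = 1, fn = 2))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 4 / 7)
  expect_equal(m$accuracy, 0.7)
  expect_warning(
    z <- classification_metrics(list(tp = 0, tn = 3, fp = 0, fn = 1)),
    "precision")
  expect_equal(z$precision, 0)
  expect_error(classification_metrics(list(tp = -1, tn = 0, fp = 0, fn = 0)),
               ">= 0")
  # f1 is the harmonic mean of the returned precision/recall
  set.seed(3)
  for (i in 1:25) {
    cts <- as.list(setNames(sample(0:30, 4, replace = TRUE),
                            c("tp", "tn", "fp", "fn")))
    m <- suppressWarnings(classification_metrics(cts))
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall))
  }
})

test_that("ROC/AUC agree with pair-counting, and the curves are sane", {
  r <- roc_points(c(.9, .8, .4, .2), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(tail(r$points$tpr, 1), 1)

  set.seed(10)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    scores <- round(runif(n), 2)          # rounded scores force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_points(scores, labels)$auc,
                 oracle_auc(scores, labels), tolerance = 1e-12)
  }
  # null case: labels independent of scores
  set.seed(11)
  scores <- runif(4000); labels <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_points(scores, labels)$auc - 0.5), 0.05)
  expect_error(roc_points(1:3, c(1, 1, 1)), "positive and one negative")

  pr <- pr_points(c(.9, .8, .4, .2), c(1, 0, 1, 0))
  expect_equal(pr$precision[1], 1)
  expect_equal(tail(pr$recall, 1), 1)
  expect_true(all(diff(pr$recall) >= 0))
})

test_that("ROC matches an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- round(runif(80), 2); labels <- rbinom(80, 1, 0.4)
  expect_equal(roc_points(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("confusion matrices are truth x prediction with conserved
           marginals", {
  truth <- c("a", "a", "b", "b", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "a")
  cm <- confusion_matrix(pred, truth, c("a", "b", "c"))
  expect_equal(sum(cm), 6L)
  expect_equal(cm["a", "b"], 1L)
  expect_equal(cm["c", "a"], 1L)
  expect_equal(diag(cm), c(a = 1L, b = 2L, c = 1L))
  ident <- confusion_matrix(truth, truth, c("a", "b", "c"))
  expect_true(all(ident[upper.tri(ident) | lower.tri(ident)] == 0L))
  expect_error(confusion_matrix(c("a", "x"), c("a", "a"), c("a", "b")), "x")

  mm <- multiclass_metrics(pred, truth, c("a", "b", "c"))
  expect_equal(nrow(mm), 4L)
  expect_equal(mm$class[4], "macro")
  expect_equal(mm$recall[mm$class == "b"], 1)
})
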