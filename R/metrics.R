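# Image-quality metrics (PSNR, SSIM, RMS contrast) and classification
# metric suites (confusion counts, accuracy/precision/recall/F1, ROC/AUC,
# precision-recall curves).

#' Peak signal-to-noise ratio
#'
#' `10 * log10((L-1)^2 / MSE)` in dB; identical images (MSE 0) return the
#' `Inf` sentinel. Symmetric in its arguments.
#'
#' @param reference,test Same-shape intensity matrices (or phantoms).
#' @param L Number of levels.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, L = 256L) {
  a <- as_pixels(reference); b <- as_pixels(test)
  if (!all(dim(a) == dim(b))) stop("psnr: image shapes differ")
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) return(Inf)
  10 * log10((L - 1)^2 / mse)
}

# Sliding-window local sums via an integral image ("valid" positions only).
.local_sums <- function(x, w) {
  H <- nrow(x); W <- ncol(x)
  S <- apply(apply(x, 2, cumsum), 1, cumsum)    # transposed cumsum2d
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  i <- seq_len(H - w + 1L); j <- seq_len(W - w + 1L)
  S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]
}

#' Structural similarity index (mean over windows)
#'
#' Standard windowed SSIM with a uniform window (default 7) and
#' stabilizers `C1 = (k1 (L-1))^2`, `C2 = (k2 (L-1))^2` with
#' `k1 = 0.01`, `k2 = 0.03`. Returns 1 for identical images; symmetric.
#'
#' @param reference,test Same-shape intensity matrices (or phantoms).
#' @param window Odd window side length.
#' @param k1,k2 Stabilizer constants.
#' @param L Number of levels.
#' @return Mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(reference, test, window = 7L, k1 = 0.01, k2 = 0.03,
                 L = 256L) {
  a <- as_pixels(reference); b <- as_pixels(test)
  if (!all(dim(a) == dim(b))) stop("ssim: image shapes differ")
  if (window %% 2L == 0L) stop("ssim: window must be odd")
  w <- min(window, nrow(a), ncol(a))
  if (w %% 2L == 0L) w <- w - 1L
  n <- w * w
  a <- matrix(as.numeric(a), nrow(a)); b <- matrix(as.numeric(b), nrow(b))
  mu_a <- .local_sums(a, w) / n
  mu_b <- .local_sums(b, w) / n
  var_a <- .local_sums(a^2, w) / n - mu_a^2
  var_b <- .local_sums(b^2, w) / n - mu_b^2
  cov_ab <- .local_sums(a * b, w) / n - mu_a * mu_b
  C1 <- (k1 * (L - 1))^2; C2 <- (k2 * (L - 1))^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  mean(s)
}

#' RMS contrast
#'
#' Standard deviation of mean-normalized intensities `v / mean(v)`; 0 for a
#' constant image, error for a zero-mean one.
#'
#' @param image Intensity matrix (or phantom).
#' @return Non-negative contrast value.
#' @export
rms_contrast <- function(image) {
  v <- as.numeric(as_pixels(image))
  if (length(v) == 0L) stop("rms_contrast: empty image")
  m <- mean(v)
  if (m == 0) stop("rms_contrast: zero-mean image is degenerate")
  stats::sd(v / m)
}

#' Relative contrast change
#' @param before,after RMS contrasts before and after enhancement.
#' @return `(after - before) / before`.
#' @export
relative_contrast_change <- function(before, after) {
  if (before == 0) stop("relative_contrast_change: zero baseline contrast")
  (after - before) / before
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' `accuracy = (TP+TN)/total`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `f1 = harmonic mean`. Zero denominators yield 0
#' with a warning.
#'
#' @param counts Named list or vector with `tp`, `tn`, `fp`, `fn`.
#' @return Named list of the four metrics.
#' @export
classification_metrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be >= 0")
  total <- tp + tn + fp + fn
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0",
              call. = FALSE)
      0
    } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = safe(tp + tn, total, "accuracy"),
       precision = precision, recall = recall, f1 = f1)
}

#' ROC curve and AUC by threshold sweep
#'
#' Thresholds sweep the unique scores (ties grouped, predictions positive
#' at `score >= threshold`); AUC by the trapezoid rule.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return List with `points` (threshold, fpr, tpr ordered from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("roc_points requires at least one positive and one negative")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / P, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / N, 0)
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Precision-recall curve by threshold sweep
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return data.frame with `threshold`, `recall`, `precision` (ties
#'   grouped).
#' @export
pr_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1L)
  if (P == 0L) stop("pr_points requires at least one positive")
  thr <- sort(unique(scores), decreasing = TRUE)
  rec <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / P, 0)
  prec <- vapply(thr, function(t) {
    np <- sum(scores >= t)
    if (np == 0L) 1 else sum(scores >= t & labels == 1L) / np
  }, 0)
  data.frame(threshold = thr, recall = rec, precision = prec)
}

#' Confusion matrix (rows = truth, columns = prediction)
#'
#' @param predictions,truths Equal-length label vectors.
#' @param class_order Character vector fixing row/column order; every label
#'   must appear in it.
#' @return Integer matrix whose entries sum to `length(truths)`.
#' @export
confusion_matrix <- function(predictions, truths, class_order) {
  predictions <- as.character(predictions); truths <- as.character(truths)
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  unknown <- setdiff(unique(c(predictions, truths)), class_order)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  m <- table(factor(truths, class_order), factor(predictions, class_order))
  mat <- matrix(as.integer(m), nrow = length(class_order),
                dimnames = list(truth = class_order,
                                prediction = class_order))
  mat
}

#' Per-class one-vs-rest metrics plus macro average
#'
#' @param predictions,truths Label vectors.
#' @param classes Class order.
#' @param scores Optional matrix of class scores (columns named by class)
#'   for per-class one-vs-rest AUC.
#' @return data.frame with one row per class and a final `macro` row.
#' @export
multiclass_metrics <- function(predictions, truths, classes,
                               scores = NULL) {
  cm <- confusion_matrix(predictions, truths, classes)
  n <- sum(cm)
  rows <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    tn <- n - tp - fp - fn
    m <- suppressWarnings(
      classification_metrics(list(tp = tp, tn = tn, fp = fp, fn = fn)))
    auc <- if (!is.null(scores) && cl %in% colnames(scores) &&
               length(unique(truths == cl)) == 2L)
      roc_points(scores[, cl], truths == cl)$auc else NA_real_
    data.frame(class = cl, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1, auc = auc,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  macro <- data.frame(class = "macro", accuracy = mean(df$accuracy),
                      precision = mean(df$precision),
                      recall = mean(df$recall), f1 = mean(df$f1),
                      auc = mean(df$auc, na.rm = TRUE),
                      stringsAsFactors = FALSE)
  rbind(df, macro)
}
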