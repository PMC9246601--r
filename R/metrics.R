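# Evaluation metrics: multiclass accuracy, one-vs-rest AUC (rank statistic,
# ties at 0.5), Cohen's kappa (unweighted and quadratic-weighted), and a
# stratified k-fold splitter preserving the class-wise distribution.

#' Confusion matrix from true and predicted labels
#'
#' @param true,pred integer class labels in `0..n_classes-1`.
#' @param n_classes number of classes (defaults to the range observed).
#' @return square count matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true, pred, n_classes = max(true, pred) + 1L) {
  stopifnot(length(true) == length(pred))
  lv <- 0:(n_classes - 1L)
  table(factor(true, levels = lv), factor(pred, levels = lv))
}

#' Accuracy from a confusion matrix
#'
#' Multiclass accuracy: correctly classified samples over total samples,
#' i.e. the trace over the grand sum.
#'
#' @param cm square count matrix (rows = true, columns = predicted).
#' @return accuracy in `[0, 1]`.
#' @export
accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  tot <- sum(cm)
  if (tot <= 0) stop("confusion matrix is empty")
  sum(diag(cm)) / tot
}

#' One-vs-rest AUC
#'
#' Per-class area under the ROC curve, each class in turn treated as
#' positive against the rest, computed by the rank (Mann-Whitney) statistic
#' with ties counted 0.5. The macro AUC is the unweighted mean over classes
#' that have both positives and negatives; degenerate classes are skipped
#' with a warning.
#'
#' @param scores numeric matrix, rows = samples, columns = class scores.
#' @param labels integer class labels in `0..ncol(scores)-1`.
#' @return list with `macro` and `per_class` (NA for skipped classes).
#' @export
auc_ovr <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  stopifnot(nrow(scores) == length(labels))
  K <- ncol(scores)
  per <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    pos <- labels == (k - 1L)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) {
      warning(sprintf("class %d has no %s; skipped from macro AUC",
                      k - 1L, if (n1 == 0L) "positives" else "negatives"))
      next
    }
    r <- rank(scores[, k])           # midranks handle ties at 0.5
    per[k] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(macro = mean(per, na.rm = TRUE), per_class = per)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with `po` the observed
#' agreement (trace over total) and `pe` the expected agreement under
#' marginal independence. The `"quadratic"` option uses quadratic
#' disagreement weights `((i - j) / (K - 1))^2`, the convention of the
#' APTOS grading competition.
#'
#' @param cm square count matrix (rows = true, columns = predicted).
#' @param weighting `"none"` (default) or `"quadratic"`.
#' @return kappa in `[-1, 1]`; `NA` with a warning when the expected
#'   agreement is 1 (degenerate single-cell marginals).
#' @export
cohen_kappa <- function(cm, weighting = c("none", "quadratic")) {
  weighting <- match.arg(weighting)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  tot <- sum(cm)
  if (tot <= 0) stop("confusion matrix is empty")
  K <- nrow(cm)
  p <- cm / tot
  expected <- outer(rowSums(p), colSums(p))
  if (weighting == "none") {
    po <- sum(diag(p))
    pe <- sum(diag(expected))
    if (abs(1 - pe) < 1e-15) {
      warning("expected agreement is 1; kappa undefined")
      return(NA_real_)
    }
    (po - pe) / (1 - pe)
  } else {
    if (K == 1L) {
      warning("expected agreement is 1; kappa undefined")
      return(NA_real_)
    }
    w <- outer(seq_len(K), seq_len(K), function(i, j) ((i - j) / (K - 1))^2)
    den <- sum(w * expected)
    if (den < 1e-15) {
      warning("expected disagreement is 0; weighted kappa undefined")
      return(NA_real_)
    }
    1 - sum(w * p) / den
  }
}

#' Stratified k-fold split
#'
#' Partitions sample indices into `k` folds so that per-class counts per
#' fold differ from the stratified ideal by at most one. Deterministic
#' given `seed`.
#'
#' @param labels class label vector.
#' @param k number of folds.
#' @param seed optional integer seed.
#' @return list of `k` integer index vectors (disjoint, covering).
#' @export
stratified_kfold <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  cls <- unique(labels)
  folds <- vector("list", k)
  for (ci in seq_along(cls)) {
    idx <- which(labels == cls[ci])
    if (length(idx) < k) {
      stop(sprintf("class %s has %d < k = %d members", as.character(cls[ci]),
                   length(idx), k))
    }
    idx <- idx[sample.int(length(idx))]
    # rotate the starting fold per class so extras spread over folds
    assign_f <- ((seq_along(idx) - 1L + (ci - 1L)) %% k) + 1L
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_f == f])
    }
  }
  lapply(folds, sort)
}
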