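#' Confusion matrix
#'
#' Counts of (true class, predicted class) pairs, true classes on rows.
#' Row normalisation divides each row by its total, i.e. by the number of
#' observations belonging to that class.
#'
#' @param truth,pred Equal-length label vectors; every label must belong to
#'   \code{classes}.
#' @param classes Class vocabulary fixing row/column order.
#' @param normalize Return row-normalised proportions instead of counts.
#' @return A K x K matrix of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(truth, pred, classes = sort(unique(truth)),
                             normalize = FALSE) {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad)) stop("label(s) outside the class set: ",
                        paste(bad, collapse = ", "))
  cm <- table(factor(truth, classes), factor(pred, classes))
  cm <- matrix(as.numeric(cm), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  if (normalize) {
    rs <- rowSums(cm)
    cm <- cm / ifelse(rs == 0, 1, rs)
  }
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class classification metrics
#'
#' For each class c, treated one-vs-rest: precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2PR/(P+R), accuracy = (TP+TN)/N, and the
#' misclassification rate 100 x (1 - recall) — the share of class-c
#' observations assigned elsewhere. All values are percentages. A zero
#' denominator yields 0 with a warning.
#'
#' @param cm A count \code{\link{confusion_matrix}}.
#' @return Data frame with one row per class: \code{class}, \code{f1},
#'   \code{accuracy}, \code{misclassification} (all in %), plus
#'   \code{precision} and \code{recall}.
#' @export
class_metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  N <- sum(cm)
  out <- lapply(seq_along(classes), function(k) {
    TP <- cm[k, k]
    FP <- sum(cm[-k, k])
    FN <- sum(cm[k, -k])
    TN <- N - TP - FP - FN
    P <- .safe_div(TP, TP + FP)
    R <- .safe_div(TP, TP + FN)
    F1 <- .safe_div(2 * P * R, P + R)
    data.frame(class = classes[k],
               f1 = 100 * F1,
               accuracy = 100 * (TP + TN) / N,
               misclassification = 100 * (1 - R),
               precision = 100 * P,
               recall = 100 * R,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.safe_div <- function(num, den) {
  if (den == 0) {
    warning("zero denominator in metric; reported as 0")
    return(0)
  }
  num / den
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of the per-class F1 scores (percent).
#'
#' @param truth,pred Label vectors.
#' @param classes Class vocabulary.
#' @return Macro-F1 in percent.
#' @export
macro_f1 <- function(truth, pred, classes = sort(unique(truth))) {
  mean(class_metrics(confusion_matrix(truth, pred, classes))$f1)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Compares two paired vectors of per-subject F1 scores: zero differences
#' are dropped, the exact signed-rank distribution is used for n <= 25
#' (without ties), and the normal approximation with continuity correction
#' otherwise; the difference is called significant when the two-sided p
#' falls below \code{alpha}. When every difference is zero the test is
#' degenerate: p = 1, not significant.
#'
#' @param a,b Equal-length paired score vectors.
#' @param alpha Significance threshold (default 0.05).
#' @return List with \code{statistic} (V, sum of positive-difference ranks),
#'   \code{p_value}, \code{significant}, \code{n_effective}.
#' @export
wilcoxon_compare <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = 1, significant = FALSE,
                n_effective = 0L))
  }
  exact <- n <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       significant = wt$p.value < alpha,
       n_effective = n)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}
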