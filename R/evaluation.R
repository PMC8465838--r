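#' ROC curve of a pairwise score matrix against a truth adjacency
#'
#' Sweeps a threshold over all distinct score values from highest to
#' lowest; at each, every off-diagonal ordered pair with score above the
#' threshold is predicted a link. `NA`/`NaN` scores are ranked below every
#' finite score (absence of evidence never creates a positive). The area
#' under the curve is the trapezoidal integral, identical to the
#' Mann-Whitney concordance probability with ties counted one half.
#'
#' @param scores numeric matrix (diagonal ignored), or vector
#' @param truth logical/0-1 matrix of the same shape, or vector
#' @return object of class `roc_summary`: `fpr`, `tpr`, `thresholds`,
#'   `auc`, plus the Youden point (`youden_j`, `sensitivity_at_j`,
#'   `specificity_at_j`, `threshold_at_j`)
#' @export
roc_curve <- function(scores, truth) {
  if (is.matrix(scores)) {
    off <- row(scores) != col(scores)
    s <- scores[off]
    y <- truth[off]
  } else {
    s <- as.numeric(scores)
    y <- truth
  }
  y <- as.logical(y)
  if (length(s) != length(y)) stop("scores and truth differ in length")
  P <- sum(y); N <- sum(!y)
  if (P == 0 || N == 0)
    stop("ROC undefined: truth must contain positives and negatives")
  s[!is.finite(s)] <- -Inf
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  # collapse ties: one curve point per distinct threshold
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  # ties on J broken toward higher specificity (lower FPR)
  best <- order(-j, fpr)[1]
  thresholds <- c(Inf, s[last])
  structure(list(fpr = fpr, tpr = tpr, thresholds = thresholds, auc = auc,
                 youden_j = j[best], sensitivity_at_j = tpr[best],
                 specificity_at_j = 1 - fpr[best],
                 threshold_at_j = thresholds[best]),
            class = "roc_summary")
}

#' Youden operating point of an ROC curve
#'
#' @param roc a `roc_summary`
#' @return list with `j = max(TPR - FPR)`, `sensitivity`, `specificity`
#'   and the score `threshold` attaining it
#' @export
youden <- function(roc) {
  list(j = roc$youden_j, sensitivity = roc$sensitivity_at_j,
       specificity = roc$specificity_at_j, threshold = roc$threshold_at_j)
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("roc_summary: AUC %.3f, J %.3f (sens %.3f, spec %.3f)\n",
              x$auc, x$youden_j, x$sensitivity_at_j, x$specificity_at_j))
  invisible(x)
}

#' Score one TE component against ground truth across an ROI sweep
#'
#' For each ROI level of a [te_matrix()] sweep, builds the ROC of the
#' requested component against the class truth and reports the level whose
#' AUC is highest. Selection by ground-truth AUC mirrors best-ROI
#' reporting in benchmark studies and is deliberately non-blind: on real
#' data, fix the ROI threshold a priori instead (see `roi_level`).
#'
#' @param te a `local_te_result` (ROI sweep)
#' @param truth logical adjacency for the component (see [truth_matrix()])
#' @param component `"E"`, `"I"` or `"total"`
#' @param roi_level fix a specific level instead of selecting the best
#' @return list: `roc` (at the chosen level), `roi_level`, `auc_by_level`
#' @export
score_component <- function(te, truth, component = c("E", "I", "total"),
                            roi_level = NULL) {
  component <- match.arg(component)
  arr <- switch(component, E = te$te_E, I = te$te_I, total = te$te_total)
  L <- dim(arr)[3]
  if (is.null(roi_level)) {
    aucs <- vapply(seq_len(L), function(l) {
      sc <- arr[, , l]
      if (all(!is.finite(sc[row(sc) != col(sc)]))) return(NA_real_)
      roc_curve(sc, truth)$auc
    }, numeric(1))
    roi_level <- which.max(aucs)
  } else {
    aucs <- rep(NA_real_, L)
    aucs[roi_level] <- roc_curve(arr[, , roi_level], truth)$auc
  }
  list(roc = roc_curve(arr[, , roi_level], truth), roi_level = roi_level,
       auc_by_level = aucs)
}

#' Aggregate one benchmark condition over model realizations
#'
#' For each realization, selects the ROI threshold maximizing the
#' component's AUC, records AUC and the Youden point, then averages across
#' realizations.
#'
#' @param te_results list (one per realization) of `local_te_result` sweeps
#' @param truths list (one per realization) of logical truth matrices
#' @param component `"E"` or `"I"`
#' @return object of class `condition_result`: per-realization data.frame
#'   `per_realization` and named vectors `mean` / `sd` over `auc`, `j`,
#'   `sensitivity`, `specificity`
#' @export
evaluate_condition <- function(te_results, truths, component = c("E", "I")) {
  component <- match.arg(component)
  if (length(te_results) == 0) stop("need at least one realization")
  if (length(truths) != length(te_results))
    stop("one truth matrix per realization required")
  rows <- lapply(seq_along(te_results), function(r) {
    sc <- score_component(te_results[[r]], truths[[r]], component)
    data.frame(realization = r, roi_level = sc$roi_level,
               auc = sc$roc$auc, j = sc$roc$youden_j,
               sensitivity = sc$roc$sensitivity_at_j,
               specificity = sc$roc$specificity_at_j)
  })
  per <- do.call(rbind, rows)
  metrics <- c("auc", "j", "sensitivity", "specificity")
  structure(list(component = component, per_realization = per,
                 mean = vapply(per[metrics], mean, numeric(1)),
                 sd = vapply(per[metrics],
                             function(v) if (length(v) < 2) 0 else sd(v),
                             numeric(1))),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat("condition_result [", x$component, "]:",
      nrow(x$per_realization), "realization(s)\n")
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 3))
  invisible(x)
}
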