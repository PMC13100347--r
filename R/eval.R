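#' Classifier performance report
#'
#' AUC is computed by the rank (Mann-Whitney) formulation, giving 0.5
#' credit to ties; F1, positive predictive value, recall and negative
#' predictive value are computed at \code{score >= threshold}.
#' Undefined ratios (empty denominator) are reported as 0.
#'
#' @param scores Probability scores in \code{[0, 1]}.
#' @param labels Binary 0/1 labels (both classes required).
#' @param threshold Classification threshold.
#' @return Object of class \code{eval_report}: list with \code{auc},
#'   \code{f1}, \code{ppv}, \code{recall}, \code{npv}.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores)  # average ranks -> 0.5 credit for ties
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  npv <- if (tn + fn > 0) tn / (tn + fn) else 0
  f1 <- if (ppv + rec > 0) 2 * ppv * rec / (ppv + rec) else 0
  structure(list(auc = auc, f1 = f1, ppv = ppv, recall = rec, npv = npv),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUC %.3f | F1 %.3f | PPV %.3f | recall %.3f | NPV %.3f\n",
              x$auc, x$f1, x$ppv, x$recall, x$npv))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same
#' samples using the asymptotic normal statistic built from
#' placement-value covariances. Identical scores (or zero variance of
#' the AUC difference) give p = 1 with a warning.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary labels (both classes required).
#' @return List with \code{z} (signed statistic, positive when a's AUC
#'   exceeds b's) and two-sided \code{p}.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (length(unique(labels)) < 2L) stop("both classes required")
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b)))) {
    warning("identical score vectors; AUC difference has zero variance")
    return(list(z = 0, p = 1))
  }
  ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<")
  tst <- suppressWarnings(pROC::roc.test(ra, rb, method = "delong",
                                         paired = TRUE))
  z <- unname(tst$statistic)
  p <- tst$p.value
  if (!is.finite(z) || !is.finite(p)) {
    warning("zero variance of the AUC difference; returning p = 1")
    return(list(z = 0, p = 1))
  }
  list(z = z, p = p)
}

#' Univariate group-difference tests with BH-FDR correction
#'
#' Continuous/ordinal features are compared between groups by the
#' Mann-Whitney U test (normal approximation with tie correction);
#' categorical features by the chi-square test (for 2x2 tables the
#' continuity correction is applied only when an expected count is
#' below 5). Constant features get p = 1. P values are adjusted by the
#' Benjamini-Hochberg step-up procedure.
#'
#' @param features Data frame or matrix of feature columns.
#' @param labels Binary group labels (at least 2 samples per group).
#' @param categorical Optional character vector of column names to
#'   treat as categorical; by default columns with at most 2 distinct
#'   values.
#' @return Data frame with \code{feature}, \code{test}, \code{p_raw},
#'   \code{p_adj}.
#' @export
univariate_tests <- function(features, labels, categorical = NULL) {
  features <- as.data.frame(features)
  labels <- as.factor(labels)
  stopifnot(min(table(labels)) >= 2L)
  if (is.null(categorical)) {
    categorical <- names(features)[vapply(features, function(x)
      length(unique(x)) <= 2L, logical(1))]
  }
  res <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    if (length(unique(x)) <= 1L) {
      return(data.frame(feature = nm, test = "constant", p_raw = 1))
    }
    if (nm %in% categorical) {
      tab <- table(x, labels)
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      corr <- all(dim(tab) == c(2L, 2L)) && any(expd < 5)
      p <- suppressWarnings(stats::chisq.test(tab, correct = corr)$p.value)
      data.frame(feature = nm, test = "chisq", p_raw = p)
    } else {
      p <- suppressWarnings(stats::wilcox.test(x ~ labels,
                                               exact = FALSE)$p.value)
      data.frame(feature = nm, test = "mann_whitney", p_raw = p)
    }
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Spearman correlation of a feature with residual infiltration size
#'
#' Rank correlation with average ranks on ties; two-sided p value from
#' the t approximation. A constant input leaves rho undefined and is
#' flagged.
#'
#' @param feature_values Numeric feature vector (at least 4 pairs).
#' @param ris_values Residual infiltration sizes, same length.
#' @return List with \code{rho}, \code{p} and \code{constant}.
#' @export
spearman_with_ris <- function(feature_values, ris_values) {
  stopifnot(length(feature_values) == length(ris_values),
            length(feature_values) >= 4L)
  if (length(unique(feature_values)) <= 1L ||
      length(unique(ris_values)) <= 1L) {
    return(list(rho = NA_real_, p = NA_real_, constant = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(feature_values, ris_values,
                                         method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, constant = FALSE)
}

#' Descriptive class proportions
#'
#' Per-level counts and percentages of a categorical/binary variable —
#' the descriptive summary used in cohort characteristics tables.
#'
#' @param labels Vector of group labels.
#' @return Data frame with \code{level}, \code{n}, \code{percent}.
#' @export
class_proportions <- function(labels) {
  tab <- table(labels)
  data.frame(level = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(labels),
             row.names = NULL)
}
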