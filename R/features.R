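#' Fit min-max normalization constants
#'
#' Records the minimum and maximum of a training-set feature column (e.g.
#' IC50 in nM, or the TAP transport score). Constants are fitted on the
#' training split only and persisted with the model so that inference uses
#' the same scale.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return A `neoimm_minmax` object with fields `x_min`, `x_max`.
#' @export
fit_minmax <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || min(values) == max(values)) {
    stop("degenerate range: need at least two distinct finite values",
         call. = FALSE)
  }
  structure(list(x_min = min(values), x_max = max(values)),
            class = "neoimm_minmax")
}

#' Apply min-max normalization
#'
#' Computes `(x - x_min) / (x_max - x_min)`. Values outside the fitted range
#' (possible at inference time) are clamped to \[0, 1\].
#'
#' @param x Numeric vector.
#' @param constants A `neoimm_minmax` object from [fit_minmax()].
#' @return Numeric vector in \[0, 1\].
#' @export
apply_minmax <- function(x, constants) {
  stopifnot(inherits(constants, "neoimm_minmax"))
  y <- (x - constants$x_min) / (constants$x_max - constants$x_min)
  pmin(1, pmax(0, y))
}

#' Class weights for imbalanced binary training
#'
#' For class c with S_c instances out of T total training instances, the
#' weight is w_c = (1 / S_c) * (T / 2), so that the total weighted mass of
#' each class is T/2 and w_pos * S_pos + w_neg * S_neg = T exactly.
#'
#' @param s_pos,s_neg Positive / negative instance counts (both > 0).
#' @return A list with `w_pos`, `w_neg`, `s_pos`, `s_neg`, `t_total`.
#' @examples
#' class_weights(25, 75)  # w_pos = 2, w_neg = 2/3
#' @export
class_weights <- function(s_pos, s_neg) {
  if (s_pos <= 0L || s_neg <= 0L) {
    stop("empty class: both classes must have at least one instance",
         call. = FALSE)
  }
  t_total <- s_pos + s_neg
  list(w_pos = (1 / s_pos) * (t_total / 2),
       w_neg = (1 / s_neg) * (t_total / 2),
       s_pos = s_pos, s_neg = s_neg, t_total = t_total)
}

#' Accuracy, precision and recall of binary predictions
#'
#' @param predicted_positive Logical vector of predicted classes.
#' @param actual Logical vector of true classes, same length.
#' @return Named list `accuracy`, `precision`, `recall`; precision is `NA`
#'   when nothing is predicted positive, recall is `NA` when there are no
#'   actual positives.
#' @export
binary_metrics <- function(predicted_positive, actual) {
  if (length(predicted_positive) != length(actual)) {
    stop("prediction and truth vectors differ in length", call. = FALSE)
  }
  if (length(actual) == 0L) stop("empty input", call. = FALSE)
  predicted_positive <- as.logical(predicted_positive)
  actual <- as.logical(actual)
  tp <- sum(predicted_positive & actual)
  fp <- sum(predicted_positive & !actual)
  fn <- sum(!predicted_positive & actual)
  tn <- sum(!predicted_positive & !actual)
  list(
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank handling of score ties.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary truth (0/1 or logical).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC needs both classes present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Threshold-based binding call
#'
#' A peptide-MHC pair is called a binder when its predicted IC50 is below
#' 500 nM and its rank percentile is below 1% (both strict inequalities).
#'
#' @param ic50 Predicted IC50 in nM (nonnegative).
#' @param percentile Rank percentile (0--100 scale).
#' @return Logical vector.
#' @export
threshold_binding <- function(ic50, percentile) {
  ic50 < 500 & percentile < 1
}

#' Compare a feature's distribution between two groups
#'
#' Two-sided Wilcoxon rank-sum test (robust on the heavily skewed nM scale of
#' IC50), plus the conventional significance-star annotation:
#' `****` for p < 1e-4, `***` < 1e-3, `**` < 0.01, `*` < 0.05, `ns` otherwise.
#'
#' @param group_a,group_b Numeric vectors, each with >= 2 values.
#' @return List with `statistic` (rank-sum W), `p_value`, `annotation`.
#' @export
compare_distributions <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  ht <- stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       annotation = signif_stars(ht$p.value))
}

signif_stars <- function(p) {
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Pearson correlation between two features
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r` and `p_value` (two-sided).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p_value = ht$p.value)
}

#' Read a per-peptide feature table
#'
#' TSV/CSV with mandatory columns `peptide`, `allele`, `ic50_nm`, `tap` and
#' optionally `tpm`; extra columns are preserved.
#'
#' @param path Path to the table.
#' @return A `data.table`.
#' @export
read_feature_table <- function(path) {
  dt <- data.table::fread(path, sep = "auto", na.strings = c("", "NA"))
  need <- c("peptide", "allele", "ic50_nm", "tap")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L) {
    stop("feature table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("ic50_nm", "tap", "tpm")) {
    if (col %in% names(dt) && !is.numeric(dt[[col]])) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
  }
  dt$allele <- normalize_allele_name(dt$allele)
  dt
}
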