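#' ROC analysis of a responder biomarker
#'
#' Treats higher scores as responder-positive. The AUC is the normalised
#' Mann-Whitney U statistic (ties counted one half); significance comes
#' from permutation of the labels: exact enumeration of all label
#' assignments when their number is feasible, otherwise seeded Monte-Carlo
#' resampling, two-sided on `|AUC - 0.5|`. The operating point maximises
#' Youden's J = sensitivity + specificity - 1, ties resolved toward higher
#' specificity. A Mann-Whitney normal-approximation p-value is reported
#' alongside for comparison.
#'
#' @param scores per-patient biomarker values (e.g. connectivity change)
#' @param labels logical (or 0/1) responder flags; both classes required
#' @param p_method `"auto"` (exact when the number of label assignments is
#'   at most `exact_limit`, else Monte-Carlo), `"exact"`, `"mc"`, or
#'   `"none"` to skip the permutation p entirely
#' @param mc_resamples Monte-Carlo resamples (default 10000)
#' @param seed seed for Monte-Carlo resampling (default 1)
#' @param exact_limit feasibility bound on `choose(n, n1)` (default 1e6)
#' @return list of class `RocResult` with `auc`, `p_value`, `p_method`,
#'   `p_wilcox`, `sensitivity`, `specificity`, `threshold`, `youden_j`,
#'   and `curve` (data.frame of `threshold`, `fpr`, `tpr` from (0,0) to
#'   (1,1))
#' @export
rocAuc <- function(scores, labels,
                   p_method = c("auto", "exact", "mc", "none"),
                   mc_resamples = 10000, seed = 1, exact_limit = 1e6) {
  p_method <- match.arg(p_method)
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    .fcStop("fcTarget_bad_input", "scores and labels must match, no NA")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    .fcStop("fcTarget_single_class", "both classes must be present")
  n <- n1 + n0
  r <- rank(scores)
  aucOf <- function(pos) (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  auc <- aucOf(labels)

  if (p_method == "auto")
    p_method <- if (choose(n, n1) <= exact_limit) "exact" else "mc"
  p <- NA_real_
  if (p_method == "exact") {
    cmb <- utils::combn(n, n1)
    ranksum <- colSums(matrix(r[cmb], nrow = n1))
    aucs <- (ranksum - n1 * (n1 + 1) / 2) / (n1 * n0)
    p <- mean(abs(aucs - 0.5) >= abs(auc - 0.5) - 1e-12)
  } else if (p_method == "mc") {
    p <- .withSeed(seed, {
      hits <- sum(vapply(seq_len(mc_resamples), function(i) {
        abs(aucOf(sample(n, n1)) - 0.5) >= abs(auc - 0.5) - 1e-12
      }, logical(1)))
      (1 + hits) / (1 + mc_resamples)
    })
  }
  pw <- suppressWarnings(stats::wilcox.test(scores[labels], scores[!labels],
                                            exact = FALSE)$p.value)

  # ROC curve over thresholds "predict positive if score >= t"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  curve <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  jj <- tpr - fpr
  best <- order(-jj, fpr)[1] # max J; ties -> lower fpr = higher specificity
  out <- list(auc = auc, p_value = p, p_method = p_method, p_wilcox = pw,
              sensitivity = 100 * tpr[best], specificity = 100 * (1 - fpr[best]),
              threshold = thr[best], youden_j = jj[best], curve = curve,
              n_pos = n1, n_neg = n0)
  class(out) <- "RocResult"
  out
}

#' Two-sample t-test of a biomarker between responders and non-responders
#'
#' @param scores per-patient biomarker values
#' @param labels logical (or 0/1) responder flags; at least 2 per class
#' @param var_equal pooled-variance t-test when `TRUE` (default), Welch
#'   otherwise
#' @return list with `t`, `df`, `p`, `mean_pos`, `mean_neg`
#' @export
groupTtest <- function(scores, labels, var_equal = TRUE) {
  labels <- as.logical(labels)
  if (sum(labels) < 2L || sum(!labels) < 2L)
    .fcStop("fcTarget_single_class", "need at least 2 patients per class")
  x <- scores[labels]; y <- scores[!labels]
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0)
    .fcStop("fcTarget_zero_variance", "no within-group variance")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_pos = mean(x), mean_neg = mean(y))
}

#' Export a ROC result as JSON, and its curve as TSV
#'
#' @param roc a `RocResult` from [rocAuc()]
#' @param json_path,curve_tsv_path output paths (either may be `NULL`)
#' @param extra named list echoed into the JSON
#' @return the ROC result, invisibly
#' @export
writeRocResult <- function(roc, json_path = NULL, curve_tsv_path = NULL,
                           extra = list()) {
  if (!is.null(curve_tsv_path))
    utils::write.table(roc$curve, curve_tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    payload <- c(roc[c("auc", "p_value", "p_method", "p_wilcox",
                       "sensitivity", "specificity", "threshold",
                       "youden_j", "n_pos", "n_neg")], extra)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(roc)
}
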