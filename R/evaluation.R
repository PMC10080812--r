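#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Vectors of 0/1 labels (positives coded 1).
#' @return A `confusion_counts` object: integers `TP`, `TN`, `FP`, `FN`
#'   summing to `length(y_true)`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% 0:1), all(y_pred %in% 0:1))
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("TP =", x$TP, " TN =", x$TN, " FP =", x$FP, " FN =", x$FN, "\n")
  invisible(x)
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' SN = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/n reported in PERCENT,
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)). Any zero
#' factor in the MCC denominator yields MCC = 0 (conventional); an empty
#' class makes the corresponding rate `NaN`-free by the same convention
#' (SN/SP default to 0 when their denominator is 0).
#'
#' @param c A [confusion()] result (or a list with TP/TN/FP/FN).
#' @return List with `SN`, `SP` (proportions), `ACC` (percent), `MCC`.
#' @export
classification_metrics <- function(c) {
  tp <- as.numeric(c$TP); tn <- as.numeric(c$TN)
  fp <- as.numeric(c$FP); fn <- as.numeric(c$FN)
  n <- tp + tn + fp + fn
  if (n == 0) stop("no samples")
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  list(SN = sn, SP = sp, ACC = 100 * (tp + tn) / n, MCC = mcc)
}

#' Balanced-accuracy form of the AUC
#'
#' The single-threshold summary (SN + SP) / 2 computed from confusion counts.
#' This is NOT the area under a threshold-swept ROC curve (see [roc_auc()]);
#' both are reported side by side in evaluation output because they answer
#' different questions.
#'
#' @inheritParams classification_metrics
#' @return A number in \[0, 1\].
#' @export
auc_eq10 <- function(c) {
  m <- classification_metrics(c)
  (m$SN + m$SP) / 2
}

#' ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the unique scores (ties grouped), trapezoidal area.
#' Equals the Mann-Whitney rank statistic P(score+ > score-) + 0.5 P(tie).
#'
#' @param y_true 0/1 labels.
#' @param scores Numeric scores, larger = more positive.
#' @return List with `points` (data frame of `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores), all(y_true %in% 0:1))
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("ROC needs both classes")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  # group tied scores: cumulative counts at the end of each tie block
  last_of_block <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y == 1L)[last_of_block]
  fp <- cumsum(y == 0L)[last_of_block]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, s[last_of_block])),
       auc = auc)
}

#' Cross-validated evaluation with mean and standard deviation
#'
#' Runs k-fold cross-validation of an arbitrary train/predict pipeline and
#' reports per-fold SN, SP, ACC (%), MCC and both AUC variants together with
#' their means and sample (n-1) standard deviations — the layout of a
#' mean +/- std performance table.
#'
#' @param table Labelled [feature_table()].
#' @param trainer Function `(train_table) -> function(test_table) -> numeric
#'   positive-class scores` (a pipeline factory).
#' @param k Number of folds (default 10).
#' @param seed Integer seed (stratified folds).
#' @param threshold Label threshold on scores (default 0.5).
#' @return A `cv_report`: list with `folds` (per-fold data frame), `mean`,
#'   `sd`.
#' @export
cross_validate <- function(table, trainer, k = 10L, seed = 1L,
                           threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("cross-validation needs labels")
  folds <- make_folds(table$ids, k = k, seed = seed, labels = table$labels)
  if (max(folds) != k) stop("fold count mismatch")
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- ft_rows(table, folds != f)
    te <- ft_rows(table, folds == f)
    scores <- trainer(tr)(te)
    cc <- confusion(te$labels, as.integer(scores >= threshold))
    m <- classification_metrics(cc)
    data.frame(fold = f, ACC = m$ACC, SN = m$SN, SP = m$SP, MCC = m$MCC,
               AUC_rank = roc_auc(te$labels, scores)$auc,
               AUC_eq10 = auc_eq10(cc))
  })
  df <- do.call(rbind, per_fold)
  metrics <- c("ACC", "SN", "SP", "MCC", "AUC_rank", "AUC_eq10")
  structure(list(folds = df,
                 mean = colMeans(df[metrics]),
                 sd = apply(df[metrics], 2, stats::sd)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (mean +/- std):\n", nrow(x$folds)))
  cat(sprintf("  ACC %.2f%% +/- %.3f | SN %.3f +/- %.3f | SP %.3f +/- %.3f\n",
              x$mean["ACC"], x$sd["ACC"], x$mean["SN"], x$sd["SN"],
              x$mean["SP"], x$sd["SP"]))
  cat(sprintf("  MCC %.3f +/- %.3f | AUC(rank) %.3f +/- %.3f | AUC(bal) %.3f +/- %.3f\n",
              x$mean["MCC"], x$sd["MCC"], x$mean["AUC_rank"], x$sd["AUC_rank"],
              x$mean["AUC_eq10"], x$sd["AUC_eq10"]))
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' @param report A `cv_report`.
#' @param path Output path; per-fold rows plus `mean` and `sd` rows.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  df <- report$folds
  metrics <- c("ACC", "SN", "SP", "MCC", "AUC_rank", "AUC_eq10")
  extra <- data.frame(fold = c("mean", "sd"),
                      rbind(report$mean[metrics], report$sd[metrics]))
  df$fold <- as.character(df$fold)
  utils::write.table(rbind(df, extra), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' McNemar's paired test for two classifiers
#'
#' Compares two prediction vectors on the same samples through the discordant
#' counts b (A right, B wrong) and c (A wrong, B right). `method = "auto"`
#' uses the exact two-sided binomial test when b + c < 25, otherwise the
#' continuity-corrected chi-square statistic (|b - c| - 1)^2 / (b + c) on
#' 1 degree of freedom.
#'
#' @param y_true 0/1 labels.
#' @param pred_a,pred_b 0/1 predictions of the two classifiers.
#' @param method `"auto"`, `"exact"` (binomial) or `"chisq"`
#'   (continuity-corrected).
#' @return A `mcnemar_result`: `b`, `c`, `statistic` (NA for exact),
#'   `p.value`, `method`.
#' @export
mcnemar <- function(y_true, pred_a, pred_b,
                    method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  y_true <- as.integer(y_true)
  a_ok <- as.integer(pred_a) == y_true
  b_ok <- as.integer(pred_b) == y_true
  b <- sum(a_ok & !b_ok)
  c <- sum(!a_ok & b_ok)
  if (method == "auto") method <- if (b + c < 25L) "exact" else "chisq"
  if (b + c == 0L) {
    res <- list(b = b, c = c, statistic = NA_real_, p.value = 1,
                method = "exact-binomial")
  } else if (method == "exact") {
    res <- list(b = b, c = c, statistic = NA_real_,
                p.value = stats::binom.test(b, b + c, 0.5)$p.value,
                method = "exact-binomial")
  } else {
    stat <- (abs(b - c) - 1)^2 / (b + c)
    res <- list(b = b, c = c, statistic = stat,
                p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                method = "chi-square-corrected")
  }
  structure(res, class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat("McNemar's test (", x$method, "): b = ", x$b, ", c = ", x$c, sep = "")
  if (!is.na(x$statistic)) cat(sprintf(", chi^2 = %.4f", x$statistic))
  cat(sprintf(", p = %.4g\n", x$p.value))
  invisible(x)
}
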