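#' Confusion matrix for ordinal grades
#'
#' @param truth,pred Integer ranks `0..K-1`.
#' @param scheme A [grading_scheme()] (or an integer K).
#' @return K x K integer matrix, rows = truth, columns = predicted,
#'   dimnames from the scheme.
#' @export
confusion_matrix <- function(truth, pred, scheme) {
  K <- if (inherits(scheme, "grading_scheme")) scheme$K else as.integer(scheme)
  cls <- if (inherits(scheme, "grading_scheme")) scheme$classes
         else as.character(seq_len(K) - 1L)
  stopifnot(length(truth) == length(pred))
  cm <- matrix(0L, K, K, dimnames = list(truth = cls, predicted = cls))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

# one-vs-rest binary counts for class k (1-based) of a K x K confusion matrix
ovr_counts <- function(cm, k) {
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Clinical utility index of one class
#'
#' One-vs-rest collapse of the confusion matrix for the given class;
#' CUI+ = sensitivity x PPV and CUI- = specificity x NPV, banded as
#' excellent (>= 0.810), good (>= 0.640), satisfactory (>= 0.490) and
#' poor (< 0.490).  A zero denominator (class never present or never
#' predicted) yields an `NA` value flagged `"undefined"`, never an
#' error.
#'
#' @param cm K x K confusion matrix (rows = truth).
#' @param class_index 1-based class index.
#' @return List with `cui_plus`, `cui_minus`, `band_plus`, `band_minus`.
#' @export
cui <- function(cm, class_index) {
  o <- ovr_counts(cm, class_index)
  sens <- safe_div(o$tp, o$tp + o$fn)
  ppv  <- safe_div(o$tp, o$tp + o$fp)
  spec <- safe_div(o$tn, o$tn + o$fp)
  npv  <- safe_div(o$tn, o$tn + o$fn)
  cp <- sens * ppv
  cn <- spec * npv
  list(cui_plus = cp, cui_minus = cn,
       band_plus = cui_band(cp), band_minus = cui_band(cn))
}

#' @rdname cui
#' @param x A CUI value.
#' @export
cui_band <- function(x) {
  if (is.na(x)) return("undefined")
  if (x >= 0.810) "excellent"
  else if (x >= 0.640) "good"
  else if (x >= 0.490) "satisfactory"
  else "poor"
}

# one-vs-rest AUC by rank statistic (midrank ties), NA if single-class
binary_auc <- function(truth01, score) {
  n1 <- sum(truth01 == 1); n0 <- sum(truth01 == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(truth01, score, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Full evaluation report for one grading task
#'
#' Computes the metric stack used for ordinal multiclass grading:
#' accuracy, macro (unweighted) one-vs-rest AUC, macro F1 / precision /
#' recall, per-class NPV, per-class and macro CUI with utility bands,
#' and the quadratic weighted kappa between predicted and true ranks.
#' Classes absent from `y_true` have undefined AUC and are excluded from
#' the macro mean with a warning; other undefined per-class metrics are
#' reported `NA` and excluded from macro averages.
#'
#' @param y_true Integer ranks `0..K-1`.
#' @param y_prob n x K matrix of class probabilities (rows sum to 1).
#' @param scheme A [grading_scheme()].
#' @return An object of class `eval_report`.
#' @export
compute_report <- function(y_true, y_prob, scheme) {
  stopifnot(inherits(scheme, "grading_scheme"))
  y_prob <- as.matrix(y_prob)
  K <- scheme$K
  if (ncol(y_prob) != K)
    stop("y_prob must have K = ", K, " columns", call. = FALSE)
  if (any(abs(rowSums(y_prob) - 1) > 1e-6))
    stop("rows of y_prob must sum to 1", call. = FALSE)
  y_true <- as_ranks(y_true, scheme)
  if (length(y_true) != nrow(y_prob))
    stop("y_true length does not match y_prob rows", call. = FALSE)
  pred <- max.col(y_prob, ties.method = "first") - 1L
  cm <- confusion_matrix(y_true, pred, scheme)

  per_class <- lapply(seq_len(K), function(k) {
    o <- ovr_counts(cm, k)
    auc_k <- if (sum(y_true == k - 1L) == 0L) NA_real_
             else binary_auc(as.integer(y_true == k - 1L), y_prob[, k])
    prec <- safe_div(o$tp, o$tp + o$fp)
    rec  <- safe_div(o$tp, o$tp + o$fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
          else 2 * prec * rec / (prec + rec)
    c(list(auc = auc_k, precision = prec, recall = rec, f1 = f1,
           npv = safe_div(o$tn, o$tn + o$fn)),
      cui(cm, k))
  })
  names(per_class) <- scheme$classes
  aucs <- vapply(per_class, `[[`, 0, "auc")
  if (anyNA(aucs))
    warning("AUC undefined for class(es) absent from y_true: ",
            paste(scheme$classes[is.na(aucs)], collapse = ", "),
            "; excluded from macro-AUC")
  gm <- function(field) mean(vapply(per_class, `[[`, 0, field), na.rm = TRUE)
  structure(
    list(n = length(y_true), scheme = scheme, confusion = cm,
         accuracy = mean(pred == y_true),
         macro_auc = gm("auc"), macro_f1 = gm("f1"),
         macro_precision = gm("precision"), macro_recall = gm("recall"),
         macro_npv = gm("npv"),
         macro_cui_plus = gm("cui_plus"), macro_cui_minus = gm("cui_minus"),
         qwk = quadratic_weighted_kappa(y_true, pred, K),
         per_class = per_class),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report: task %d (%s), n = %d\n",
              x$scheme$task_id, x$scheme$task_name, x$n))
  cat(sprintf("  ACC %.3f | macro-AUC %.3f | macro-F1 %.3f | QWK %.3f\n",
              x$accuracy, x$macro_auc, x$macro_f1, x$qwk))
  cat(sprintf("  macro precision %.3f | recall %.3f | NPV %.3f | CUI+ %.3f (%s) | CUI- %.3f (%s)\n",
              x$macro_precision, x$macro_recall, x$macro_npv,
              x$macro_cui_plus, cui_band(x$macro_cui_plus),
              x$macro_cui_minus, cui_band(x$macro_cui_minus)))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

# flatten an eval_report to a plain named list for JSON export
report_as_list <- function(x) {
  out <- c(list(schema = "milgrade/report/1"),
           x[c("n", "accuracy", "macro_auc", "macro_f1", "macro_precision",
               "macro_recall", "macro_npv", "macro_cui_plus",
               "macro_cui_minus", "qwk")])
  out$task <- x$scheme$task_id
  out$confusion <- unclass(x$confusion)
  out$per_class <- x$per_class
  out
}

#' Quadratic weighted kappa
#'
#' Chance-corrected agreement between two ordinal raters with squared
#' disagreement penalties `w_ij = (i - j)^2 / (K - 1)^2`; the expected
#' table is the outer product of the marginals.
#'
#' @param r1,r2 Integer rank vectors `0..K-1` of equal length.
#' @param K Number of ordinal categories.
#' @return Kappa in `[-1, 1]`.
#' @export
quadratic_weighted_kappa <- function(r1, r2, K) {
  if (length(r1) != length(r2))
    stop("invalid input: rank vectors differ in length", call. = FALSE)
  stopifnot(all(r1 >= 0 & r1 < K), all(r2 >= 0 & r2 < K))
  n <- length(r1)
  O <- matrix(0, K, K)
  for (i in seq_len(n)) O[r1[i] + 1L, r2[i] + 1L] <-
      O[r1[i] + 1L, r2[i] + 1L] + 1
  O <- O / n
  E <- outer(rowSums(O), colSums(O))
  W <- outer(0:(K - 1), 0:(K - 1), function(i, j) (i - j)^2) / (K - 1)^2
  denom <- sum(W * E)
  if (denom == 0) return(1)   # both raters constant and identical
  1 - sum(W * O) / denom
}

#' McNemar's test on discordant pairs
#'
#' Paired comparison of two classifiers' accuracy: `n01` slides correct
#' under the first rater only, `n10` under the second only.  Uses the
#' continuity-corrected chi-squared form, falling back to the exact
#' two-sided binomial test when fewer than 25 discordant pairs are
#' available.
#'
#' @param n01,n10 Discordant counts.
#' @param correction Apply the continuity correction in the chi-squared
#'   form.
#' @param method `"auto"` (exact below 25 discordant pairs), `"chisq"`,
#'   or `"exact"`.
#' @return List with `statistic` (`NA` for the exact form), `p_value`,
#'   `method`, and `undefined` flag (both counts zero).
#' @export
mcnemar_test <- function(n01, n10, correction = TRUE,
                         method = c("auto", "chisq", "exact")) {
  method <- match.arg(method)
  n <- n01 + n10
  if (n < 1)
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "undefined", undefined = TRUE))
  if (method == "auto") method <- if (n < 25) "exact" else "chisq"
  if (method == "exact") {
    p <- min(1, 2 * pbinom(min(n01, n10), n, 0.5))
    return(list(statistic = NA_real_, p_value = p, method = "exact",
                undefined = FALSE))
  }
  d <- abs(n01 - n10)
  if (correction) d <- max(0, d - 1)
  stat <- d^2 / n
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE),
       method = if (correction) "chisq-corrected" else "chisq",
       undefined = FALSE)
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two scores over the same cases using the
#' placement-value (fast DeLong) covariance estimate, two-sided.
#'
#' @param y_true Binary labels (0/1).
#' @param s1,s2 Score vectors aligned to `y_true`.
#' @return List with `auc1`, `auc2`, `z`, `p_value`.
#' @export
delong_test <- function(y_true, s1, s2) {
  y_true <- as.integer(y_true)
  if (length(unique(y_true)) < 2L)
    stop("invalid input: y_true must contain both classes", call. = FALSE)
  r1 <- pROC::roc(y_true, s1, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  r2 <- pROC::roc(y_true, s2, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  a1 <- as.numeric(pROC::auc(r1)); a2 <- as.numeric(pROC::auc(r2))
  if (isTRUE(all.equal(s1, s2)))
    return(list(auc1 = a1, auc2 = a2, z = 0, p_value = 1))
  tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  z <- unname(tst$statistic)
  if (!is.finite(z)) z <- 0
  list(auc1 = a1, auc2 = a2, z = z,
       p_value = if (is.finite(tst$p.value)) tst$p.value else 1)
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Used for the structural-confusion failure-case analysis: comparing
#' the proportion of a given error type between two tasks.  Yates'
#' continuity correction is the default, matching standard practice for
#' 2x2 tables.
#'
#' @param table 2x2 matrix of counts (or four counts `a, b, c, d` by
#'   row).
#' @param yates Apply Yates' continuity correction.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  tb <- matrix(as.numeric(table), 2, 2, byrow = !is.matrix(table))
  if (any(tb < 0) || any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stop("invalid input: all margins of the 2x2 table must be positive",
         call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tb, correct = yates))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, df = 1L)
}
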