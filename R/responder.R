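# Responder stratification (low / medium / high responders per strength
# metric) and the baseline responder-prediction benchmark with
# permutation-calibrated ROC-AUC.

#' Stratify participants into LR / MR / HR by a strength metric
#'
#' High responders lie strictly above the `high_q` empirical quantile of the
#' metric, low responders strictly below the `low_q` quantile, everyone else
#' is a medium responder. Quantiles use the type-7 (linear interpolation)
#' convention; values tied exactly with a cut go to MR. For metrics where
#' improvement means a decrease (BioAge), pass `direction = "lower"`.
#'
#' @param values named numeric vector, participant -> metric value.
#' @param low_q,high_q quantile cuts (defaults 0.2 / 0.8: bottom and top 20%).
#' @param direction "higher" if larger values mean stronger response,
#'   "lower" for the reverse.
#' @return list with `class` (named factor LR/MR/HR), `thresholds`
#'   (low_cut, high_cut on the original scale), `direction`.
#' @export
stratify <- function(values, low_q = 0.2, high_q = 0.8,
                     direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (length(values) < 5) stop("need at least 5 participants")
  if (anyNA(values) || any(!is.finite(values))) stop("metric values must be finite")
  if (length(unique(values)) == 1) {
    stop("degenerate stratification: all metric values identical")
  }
  v <- if (direction == "lower") -values else values
  lo <- stats::quantile(v, low_q, type = 7, names = FALSE)
  hi <- stats::quantile(v, high_q, type = 7, names = FALSE)
  cls <- ifelse(v > hi, "HR", ifelse(v < lo, "LR", "MR"))
  cls <- factor(cls, levels = c("LR", "MR", "HR"))
  names(cls) <- names(values)
  th <- if (direction == "lower") c(low_cut = -lo, high_cut = -hi) else
    c(low_cut = lo, high_cut = hi)
  list(class = cls, thresholds = th, direction = direction)
}

#' Pool of non-high responders across all metrics
#'
#' Participants not classified HR under any of the supplied metrics: the
#' sampling pool for the permutation-subset null.
#'
#' @param labels_list list of [stratify()] results (one per metric).
#' @return character vector of participant ids.
#' @export
non_hr_pool <- function(labels_list) {
  stopifnot(length(labels_list) >= 1)
  ids <- names(labels_list[[1]]$class)
  hr_any <- Reduce(`|`, lapply(labels_list, function(l) {
    l$class[ids] == "HR"
  }))
  ids[!hr_any]
}

#' Predict responder class from baseline features
#'
#' Random Forest (500 trees by default) benchmark of HR-vs-LR separability
#' from baseline-only features, evaluated by stratified 5-fold
#' cross-validated ROC-AUC with a label-permutation null: the observed
#' cross-validation is repeated on `n_perm` permutations of the labels and
#' `p = (1 + #{perm AUC >= observed}) / (1 + n_perm)`. Gini feature
#' importances are averaged over folds and normalised to sum to one.
#'
#' @param features numeric matrix or data.frame, rows = participants.
#' @param labels factor/character with levels HR and LR.
#' @param n_perm number of label permutations (1000 in the full benchmark;
#'   reduce for quick checks).
#' @param seed integer seed.
#' @param n_folds cross-validation folds.
#' @param ntree Random Forest size.
#' @return list with `auc`, `permutation_p`, `feature_importances`,
#'   `n_perm`, `settings`.
#' @export
predict_responders <- function(features, labels, n_perm = 1000, seed = 1,
                               n_folds = 5, ntree = 500) {
  x <- as.data.frame(features)
  y <- factor(as.character(labels), levels = c("LR", "HR"))
  if (nrow(x) != length(y)) stop("feature/label length mismatch")
  leak <- grepl("W4|W8|percent_gain|avg_log2fc", names(x))
  if (any(leak)) {
    stop("post-training features not allowed (baseline only): ",
         paste(names(x)[leak], collapse = ", "))
  }
  if (anyNA(y)) stop("labels must be HR or LR")
  if (any(table(y) < 5)) stop("need at least 5 participants per class")
  with_seed(seed, {
    cv <- rf_cv_auc(x, y, n_folds, ntree, importance = TRUE)
    perm <- vapply(seq_len(n_perm), function(i) {
      rf_cv_auc(x, sample(y), n_folds, ntree, importance = FALSE)$auc
    }, 0)
    imp <- cv$importance / sum(cv$importance)
    list(auc = cv$auc,
         permutation_p = (1 + sum(perm >= cv$auc)) / (1 + n_perm),
         feature_importances = imp, n_perm = n_perm,
         settings = list(n_folds = n_folds, ntree = ntree, seed = seed))
  })
}

# Stratified k-fold CV; AUC pooled over out-of-fold class probabilities.
rf_cv_auc <- function(x, y, n_folds, ntree, importance) {
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  prob <- numeric(length(y))
  imp <- 0
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                      ntree = ntree)
    prob[!tr] <- stats::predict(fit, x[!tr, , drop = FALSE],
                                type = "prob")[, "HR"]
    if (importance) imp <- imp + fit$importance[, "MeanDecreaseGini"]
  }
  list(auc = rank_auc(prob, y == "HR"),
       importance = if (importance) imp / n_folds else NULL)
}

# ROC-AUC via the rank (Mann-Whitney) statistic; ties get half credit.
rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
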