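#' Confusion counts at a classification threshold
#'
#' A site is predicted active when its posterior is greater than or equal
#' to `theta`. TP counts validated active sites predicted active, FP
#' inactive sites predicted active, TN and FN analogously.
#'
#' @param posterior Numeric vector of active-class posteriors.
#' @param label True labels (`"active"` / `"inactive"`).
#' @param theta Threshold; the boundary is inclusive.
#' @return One-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(posterior, label, theta = 0.5) {
  label <- normalize_labels(label)
  if (any(label == "unknown")) {
    abort("confusion counts need active/inactive labels")
  }
  if (length(posterior) != length(label)) {
    abort("`posterior` and `label` lengths differ")
  }
  pred_active <- posterior >= theta
  tibble(
    tp = sum(pred_active & label == "active"),
    fp = sum(pred_active & label == "inactive"),
    tn = sum(!pred_active & label == "inactive"),
    fn = sum(!pred_active & label == "active")
  )
}

#' Performance measures from confusion counts
#'
#' Computes the standard suite: accuracy, Matthews correlation
#' coefficient (`cc`), specificity+ (precision, TP/(TP+FP)), sensitivity+
#' (recall, TP/(TP+FN)), false positive rate and true positive rate.
#' Degenerate 0/0 denominators yield `NA`, never a silently coerced 0
#' or 1.
#'
#' @param counts One-row tibble from [confusion_counts()] (or any list
#'   with `tp`, `fp`, `tn`, `fn`).
#' @return One-row tibble: `accuracy`, `cc`, `specificity_plus`,
#'   `sensitivity_plus`, `fpr`, `tpr`.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  tibble(
    accuracy = safe_div(tp + tn, tp + fp + tn + fn),
    cc = if (denom == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(denom),
    specificity_plus = safe_div(tp, tp + fp),
    sensitivity_plus = safe_div(tp, tp + fn),
    fpr = safe_div(fp, fp + tn),
    tpr = safe_div(tp, tp + fn)
  )
}

#' ROC curve points
#'
#' One point per distinct posterior value taken as threshold, in
#' descending threshold order (ties grouped), plus the (0,0) and (1,1)
#' anchors. The curve is monotone non-decreasing in both coordinates.
#'
#' @inheritParams confusion_counts
#' @return Tibble with columns `threshold` (`Inf` and `-Inf` for the
#'   anchors), `fpr`, `tpr`.
#' @export
roc_points <- function(posterior, label) {
  label <- normalize_labels(label)
  if (length(unique(label)) < 2 || any(label == "unknown")) {
    abort("ROC needs both active and inactive labels")
  }
  n_pos <- sum(label == "active")
  n_neg <- sum(label == "inactive")
  thr <- sort(unique(posterior), decreasing = TRUE)
  pts <- purrr::map_dfr(thr, function(t) {
    tibble(threshold = t,
           fpr = sum(posterior >= t & label == "inactive") / n_neg,
           tpr = sum(posterior >= t & label == "active") / n_pos)
  })
  dplyr::bind_rows(
    tibble(threshold = Inf, fpr = 0, tpr = 0),
    pts,
    tibble(threshold = -Inf, fpr = 1, tpr = 1)
  ) |> dplyr::distinct(.data$fpr, .data$tpr, .keep_all = TRUE)
}

#' Area under the ROC curve (tie-aware)
#'
#' Primary implementation is the Mann-Whitney form:
#' (number of active/inactive pairs where the active site scores higher,
#' plus half the tied pairs) divided by `n_active * n_inactive`. This
#' equals the trapezoidal area under [roc_points()].
#'
#' @inheritParams confusion_counts
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(posterior, label) {
  label <- normalize_labels(label)
  if (length(unique(label)) < 2 || any(label == "unknown")) {
    abort("AUC needs both active and inactive labels")
  }
  pos <- posterior[label == "active"]
  neg <- posterior[label == "inactive"]
  r <- rank(c(pos, neg), ties.method = "average")
  sum_r_pos <- sum(r[seq_along(pos)])
  (sum_r_pos - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Trapezoid cross-check used by the test-suite oracle.
auc_trapezoid <- function(posterior, label) {
  pts <- roc_points(posterior, label)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Threshold maximizing the Matthews correlation coefficient
#'
#' Scans candidate thresholds at midpoints between adjacent distinct
#' posteriors, plus 0 and 1, and returns the smallest candidate achieving
#' the maximal correlation coefficient of the induced confusion matrix.
#'
#' @inheritParams confusion_counts
#' @return The selected threshold.
#' @export
choose_threshold_max_cc <- function(posterior, label) {
  label <- normalize_labels(label)
  if (length(unique(label)) < 2 || any(label == "unknown")) {
    abort("threshold selection needs both classes")
  }
  s <- sort(unique(posterior))
  cand <- unique(c(0, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, 1))
  cc <- vapply(cand, function(t) {
    v <- classification_metrics(confusion_counts(posterior, label, t))$cc
    if (is.na(v)) -Inf else v
  }, numeric(1))
  cand[which.max(cc)]  # which.max returns the first (smallest) maximizer
}

zf_eval <- function(predictions, theta, theta_rule) {
  counts <- confusion_counts(predictions$posterior_active,
                             predictions$label, theta)
  structure(
    list(
      predictions = predictions,
      theta = theta,
      theta_rule = theta_rule,
      counts = counts,
      metrics = classification_metrics(counts),
      roc = roc_points(predictions$posterior_active, predictions$label),
      auc = auc_mw(predictions$posterior_active, predictions$label)
    ),
    class = "zf_eval"
  )
}

#' @export
print.zf_eval <- function(x, ...) {
  m <- x$metrics
  cat("<zf_eval> ", nrow(x$predictions), " sites, theta = ",
      format(x$theta), " (", x$theta_rule, ")\n", sep = "")
  cat(sprintf("  accuracy %.3f | cc %.3f | specificity+ %.3f | sensitivity+ %.3f\n",
              m$accuracy, m$cc, m$specificity_plus, m$sensitivity_plus))
  cat(sprintf("  AUC %.3f | TP %d FP %d TN %d FN %d\n", x$auc,
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  invisible(x)
}

#' Per-site predictions of an evaluation run
#' @param x A `zf_eval` object.
#' @param ... Unused.
#' @return Tibble with `sequence`, `label`, `posterior_active`,
#'   `predicted`, `confidence`.
#' @export
tidy.zf_eval <- function(x, ...) {
  dplyr::mutate(
    x$predictions,
    predicted = ifelse(.data$posterior_active >= x$theta,
                       "active", "inactive"),
    confidence = confidence_score(.data$posterior_active)
  )
}

#' One-row evaluation summary
#' @param x A `zf_eval` object.
#' @param ... Unused.
#' @return Tibble of the confusion counts, six metrics, AUC and theta.
#' @export
glance.zf_eval <- function(x, ...) {
  dplyr::bind_cols(x$counts, x$metrics,
                   tibble(auc = x$auc, theta = x$theta))
}

#' ROC plot for an evaluation run
#' @param object A `zf_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zf_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.2f)", object$auc)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Leave-one-out cross-validation of the naive Bayes classifier
#'
#' For each site, fits the classifier on the remaining sites and records
#' the held-out posterior (implemented by decrementing sufficient-statistic
#' counts, which is exactly equivalent to refitting). The pooled
#' posteriors give one ROC curve, one AUC and one confusion matrix at
#' `theta` (or at the CC-maximizing threshold when `optimize_cc`).
#'
#' @param sites Labeled site table, at least two sites per class.
#' @param encoding Feature encoding.
#' @param alpha Laplace pseudocount.
#' @param theta Classification threshold (default 0.5).
#' @param optimize_cc If `TRUE`, choose the threshold maximizing the
#'   correlation coefficient on the pooled leave-one-out posteriors
#'   (an in-sample threshold choice; see the vignette).
#' @return A `zf_eval` object.
#' @export
loocv_nb <- function(sites, encoding = c("identity", "base_counts",
                                         "positional"),
                     alpha = 1, theta = 0.5, optimize_cc = FALSE) {
  encoding <- match.arg(encoding)
  sites <- validate_sites(sites, require_labels = TRUE)
  tab <- table(sites$label)
  if (any(tab[c("active", "inactive")] < 2)) {
    abort("leave-one-out needs at least two sites per class")
  }
  counts <- nb_count(sites, encoding)
  x <- feature_matrix(sites, encoding)
  post <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    held <- counts
    cls <- sites$label[i]
    held$n_class[cls] <- held$n_class[cls] - 1
    for (j in seq_along(held$tables)) {
      held$tables[[j]][x[i, j], cls] <- held$tables[[j]][x[i, j], cls] - 1
    }
    model <- nb_from_counts(held, alpha)
    post[i] <- nb_posterior(model, sites[i, ])
  }
  predictions <- tibble(sequence = sites$sequence, id = sites$id,
                        label = sites$label, posterior_active = post)
  if (optimize_cc) {
    theta <- choose_threshold_max_cc(post, sites$label)
    zf_eval(predictions, theta, "max-cc")
  } else {
    zf_eval(predictions, theta, "fixed")
  }
}

#' Leave-one-out cross-validation of the balanced-resampling SVM
#'
#' For each held-out site, draws `k` class-balanced training subsets from
#' the remaining sites, trains one calibrated RBF SVM per subset, and
#' scores the site by the mean of the `k` probability estimates.
#' Reproducible given `seed`.
#'
#' @inheritParams loocv_nb
#' @param k Number of balanced subsets per held-out site (default 10).
#' @param cost,gamma RBF hyperparameters (`gamma = NULL` uses 1/dim).
#' @param seed Integer seed.
#' @return A `zf_eval` object.
#' @export
loocv_svm <- function(sites, encoding = c("identity", "base_counts",
                                          "positional"),
                      k = 10, cost = 1, gamma = NULL, seed = 1,
                      theta = 0.5, optimize_cc = FALSE) {
  encoding <- match.arg(encoding)
  sites <- validate_sites(sites, require_labels = TRUE)
  tab <- table(sites$label)
  if (any(tab[c("active", "inactive")] < 2)) {
    abort("leave-one-out needs at least two sites per class")
  }
  post <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    rest <- sites[-i, ]
    sets <- balanced_subsets(rest, k = k, seed = seed + i)
    post[i] <- svm_averaged_posterior(sites[i, ], sets, encoding = encoding,
                                      cost = cost, gamma = gamma,
                                      seed = seed + i)
  }
  predictions <- tibble(sequence = sites$sequence, id = sites$id,
                        label = sites$label, posterior_active = post)
  if (optimize_cc) {
    theta <- choose_threshold_max_cc(post, sites$label)
    zf_eval(predictions, theta, "max-cc")
  } else {
    zf_eval(predictions, theta, "fixed")
  }
}

#' Evaluate a classifier trained on one dataset against a held-out one
#'
#' Fits the naive Bayes classifier on all of `train` and scores `test`.
#' The two site collections must be disjoint by sequence. Optionally
#' stratifies the report by confidence score: sites at or above
#' `conf_split` versus below it.
#'
#' @param train,test Labeled site tables, disjoint by sequence.
#' @param encoding Feature encoding.
#' @param alpha Laplace pseudocount.
#' @param theta Classification threshold.
#' @param conf_split Optional integer 0-9; when given, the result carries
#'   a `stratified` element with one `zf_eval` per stratum.
#' @return A `zf_eval` object; with `conf_split`, it has an extra
#'   `stratified` element, a named list (`high`, `low`).
#' @export
evaluate_holdout <- function(train, test, encoding = c("identity",
                                                       "base_counts",
                                                       "positional"),
                             alpha = 1, theta = 0.5, conf_split = NULL) {
  encoding <- match.arg(encoding)
  train <- validate_sites(train, require_labels = TRUE)
  test <- validate_sites(test, require_labels = TRUE)
  overlap <- intersect(train$sequence, test$sequence)
  if (length(overlap) > 0) {
    abort(paste0("train and test overlap by sequence: ",
                 paste(utils::head(overlap, 3), collapse = ", ")))
  }
  model <- nb_fit(train, encoding = encoding, alpha = alpha)
  post <- nb_posterior(model, test)
  predictions <- tibble(sequence = test$sequence, id = test$id,
                        label = test$label, posterior_active = post)
  out <- zf_eval(predictions, theta, "fixed")
  out$model <- model
  if (!is.null(conf_split)) {
    conf <- confidence_score(post)
    strat <- function(keep) {
      if (!any(keep)) return(NULL)
      counts <- confusion_counts(post[keep], test$label[keep], theta)
      list(counts = counts, metrics = classification_metrics(counts),
           n = sum(keep))
    }
    out$stratified <- list(high = strat(conf >= conf_split),
                           low = strat(conf < conf_split))
  }
  out
}
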