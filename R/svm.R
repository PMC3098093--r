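#' Balanced training subsets for an imbalanced site collection
#'
#' Support vector machines are sensitive to class imbalance, so the
#' evaluation protocol trains each SVM on class-balanced resamples: every
#' subset keeps *all* minority-class sites and draws an equal number of
#' majority-class sites uniformly without replacement, independently per
#' subset.
#'
#' @param sites Labeled site table with both classes present.
#' @param k Number of subsets (default 10).
#' @param seed Integer seed; the same seed reproduces the same subsets.
#' @return A list of `k` site tibbles, each with `2 * n_minority` rows.
#' @export
balanced_subsets <- function(sites, k = 10, seed = 1) {
  if (!is.numeric(k) || k < 1) abort("`k` must be a positive integer")
  k <- as.integer(k)
  sites <- validate_sites(sites, require_labels = TRUE)
  n_by_class <- table(factor(sites$label, levels = CLASSES))
  minority <- names(n_by_class)[which.min(n_by_class)]
  majority <- setdiff(CLASSES, minority)
  n_min <- min(n_by_class)
  idx_min <- which(sites$label == minority)
  idx_maj <- which(sites$label == majority)
  with_local_seed(seed, {
    lapply(seq_len(k), function(i) {
      take <- sample(idx_maj, n_min, replace = FALSE)
      sites[sort(c(idx_min, take)), ]
    })
  })
}

# Run `code` under a fixed RNG seed without disturbing the caller's
# random state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fit one RBF SVM with probability calibration on a labeled site tibble
# and return P(active) for the query sites.
svm_fit_predict <- function(train, test, encoding, cost, gamma) {
  xtr <- svm_design(train, encoding)
  ytr <- factor(train$label, levels = CLASSES)
  if (length(unique(ytr)) < 2) {
    abort("SVM training set contains a single class")
  }
  fit <- e1071::svm(x = xtr, y = ytr, kernel = "radial",
                    cost = cost, gamma = gamma,
                    probability = TRUE, scale = FALSE)
  pr <- stats::predict(fit, svm_design(test, encoding), probability = TRUE)
  probs <- attr(pr, "probabilities")
  unname(probs[, "active"])
}

# Numeric design matrix for the SVM: identity becomes 4-level one-hot per
# position; count encodings are used as numeric values scaled to [0, 1].
svm_design <- function(sites, encoding) {
  if (encoding == "identity") {
    chars <- feature_matrix(sites, "identity")
    cols <- lapply(1:9, function(j) {
      m <- outer(chars[, j], DNA_BASES, "==") * 1
      colnames(m) <- paste0("p", j, "_", DNA_BASES)
      m
    })
    do.call(cbind, cols)
  } else {
    feats <- encode_sites(sites, encoding)
    m <- as.matrix(feats[, setdiff(names(feats), "label"), drop = FALSE])
    storage.mode(m) <- "double"
    m / if (encoding == "base_counts") 9 else 3
  }
}

#' Averaged SVM posterior over balanced training subsets
#'
#' Trains one RBF-kernel SVM with calibrated probability output per
#' balanced subset and returns the arithmetic mean of the per-subset
#' probability estimates for each query site.
#'
#' @param test Site table to score (labels ignored).
#' @param balanced_sets List of labeled site tibbles (from
#'   [balanced_subsets()]); the caller guarantees the query sites are
#'   excluded from every subset.
#' @param encoding Feature encoding.
#' @param cost,gamma RBF SVM hyperparameters.
#' @param seed Integer seed for the solver's internal cross-validation
#'   used by probability calibration.
#' @return Numeric vector of averaged `P(active)` per query site.
#' @export
svm_averaged_posterior <- function(test, balanced_sets,
                                   encoding = c("identity", "base_counts",
                                                "positional"),
                                   cost = 1, gamma = NULL, seed = 1) {
  encoding <- match.arg(encoding)
  test <- validate_sites(test)
  if (length(balanced_sets) < 1) abort("need at least one training set")
  if (is.null(gamma)) gamma <- 1 / ncol(svm_design(test, encoding))
  # the RNG (used by the solver's internal probability-calibration CV) is
  # reset per subset so identical subsets yield identical estimates
  per_set <- vapply(
    balanced_sets,
    function(tr) with_local_seed(
      seed,
      svm_fit_predict(validate_sites(tr, require_labels = TRUE),
                      test, encoding, cost, gamma)),
    numeric(nrow(test))
  )
  if (nrow(test) == 1L) per_set <- matrix(per_set, nrow = 1)
  rowMeans(per_set)
}

#' Grid search for RBF SVM hyperparameters
#'
#' Evaluates every (cost, gamma) pair by stratified k-fold
#' cross-validation on the training sites and returns the pair that
#' maximizes the objective (default: Matthews correlation coefficient of
#' the pooled fold predictions at threshold 0.5). Ties break toward
#' smaller cost, then smaller gamma. Folds that end up single-class are
#' skipped. Default grids follow common libsvm practice:
#' cost 2^-5..2^15, gamma 2^-15..2^3, step 2^2.
#'
#' @param sites Labeled site table.
#' @param encoding Feature encoding.
#' @param cost_grid,gamma_grid Numeric vectors of candidate values.
#' @param folds Number of internal stratified folds (default 5).
#' @param objective `"cc"` (Matthews correlation) or `"auc"`.
#' @param seed Integer seed controlling fold assignment.
#' @return A list with `cost`, `gamma` (the winning pair) and `grid`, a
#'   tibble of all evaluated pairs with their objective values.
#' @export
grid_search_rbf <- function(sites, encoding = c("identity", "base_counts",
                                                "positional"),
                            cost_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            folds = 5, objective = c("cc", "auc"),
                            seed = 1) {
  encoding <- match.arg(encoding)
  objective <- match.arg(objective)
  if (length(cost_grid) == 0 || length(gamma_grid) == 0) {
    abort("hyperparameter grids must be non-empty")
  }
  sites <- validate_sites(sites, require_labels = TRUE)
  if (nrow(sites) < folds) abort("fewer sites than folds")

  fold_id <- with_local_seed(seed, {
    id <- integer(nrow(sites))
    for (c in CLASSES) {
      idx <- which(sites$label == c)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })

  grid <- tidyr::expand_grid(cost = sort(cost_grid),
                             gamma = sort(gamma_grid))
  score_pair <- function(cost, gamma) {
    post <- rep(NA_real_, nrow(sites))
    for (f in seq_len(folds)) {
      tr <- sites[fold_id != f, ]
      te <- sites[fold_id == f, ]
      if (nrow(te) == 0) next
      if (length(unique(tr$label)) < 2 || length(unique(te$label)) < 2) next
      post[fold_id == f] <- with_local_seed(
        seed + f, svm_fit_predict(tr, te, encoding, cost, gamma))
    }
    keep <- !is.na(post)
    if (!any(keep) || length(unique(sites$label[keep])) < 2) return(NA_real_)
    if (objective == "auc") {
      auc_mw(post[keep], sites$label[keep])
    } else {
      cc <- classification_metrics(
        confusion_counts(post[keep], sites$label[keep], theta = 0.5))$cc
      if (is.na(cc)) 0 else cc
    }
  }
  grid$objective <- purrr::map2_dbl(grid$cost, grid$gamma, score_pair)
  best <- which(grid$objective == max(grid$objective, na.rm = TRUE))[1]
  list(cost = grid$cost[best], gamma = grid$gamma[best], grid = grid)
}
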