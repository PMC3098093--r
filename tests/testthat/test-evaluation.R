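test_that("confusion counts tally the inclusive threshold rule", {
  post <- c(0.9, 0.6, 0.7, 0.2)
  lab <- c("active", "active", "inactive", "inactive")
  cc <- confusion_counts(post, lab, 0.5)
  expect_equal(unlist(cc), c(tp = 2, fp = 1, tn = 1, fn = 0))
  expect_equal(unlist(confusion_counts(post, lab, 1.1))[c("tp", "fp")],
               c(tp = 0, fp = 0))
  expect_equal(unlist(confusion_counts(post, lab, 0))[c("tn", "fn")],
               c(tn = 0, fn = 0))
  expect_error(confusion_counts(0.5, "unknown"), "active/inactive")
})

test_that("metric formulas match hand arithmetic and mark 0/0 as NA", {
  m <- classification_metrics(list(tp = 3, fp = 1, tn = 2, fn = 0))
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$specificity_plus, 0.75)
  expect_equal(m$sensitivity_plus, 1)
  expect_equal(m$cc, 6 / sqrt(72))
  perfect <- classification_metrics(list(tp = 4, fp = 0, tn = 3, fn = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$cc, 1)
  degen <- classification_metrics(list(tp = 0, fp = 0, tn = 5, fn = 2))
  expect_true(is.na(degen$specificity_plus))
  expect_false(is.na(degen$accuracy))
})

test_that("cc negates under label swap and stays in [-1, 1]", {
  set.seed(31)
  for (i in 1:20) {
    post <- runif(20)
    lab <- sample(c("active", "inactive"), 20, replace = TRUE)
    if (length(unique(lab)) < 2) next
    cc <- classification_metrics(confusion_counts(post, lab, 0.5))$cc
    swapped <- ifelse(lab == "active", "inactive", "active")
    cc2 <- classification_metrics(confusion_counts(post, swapped, 0.5))$cc
    if (!is.na(cc) && !is.na(cc2)) {
      expect_equal(cc, -cc2, tolerance = 1e-12)
      expect_true(abs(cc) <= 1 + 1e-12)
    }
  }
})

test_that("ROC curves are anchored, monotone, and match known shapes", {
  sep <- roc_points(c(0.9, 0.8, 0.2, 0.1),
                    c("active", "active", "inactive", "inactive"))
  expect_equal(sep[1, c("fpr", "tpr")], tibble::tibble(fpr = 0, tpr = 0))
  expect_equal(unlist(sep[nrow(sep), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  tied <- roc_points(rep(0.4, 6), rep(c("active", "inactive"), 3))
  expect_equal(nrow(tied), 2)  # single jump (0,0) -> (1,1)
  r <- roc_points(c(0.9, 0.4, 0.6, 0.2),
                  c("active", "active", "inactive", "inactive"))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_error(roc_points(c(0.1, 0.2), c("active", "active")), "both")
})

test_that("Mann-Whitney AUC equals enumerated pairs and the trapezoid", {
  post <- c(0.9, 0.4, 0.6, 0.2)
  lab <- c("active", "active", "inactive", "inactive")
  expect_equal(auc_mw(post, lab), 0.75)  # 3 of 4 pairs won
  expect_equal(auc_mw(c(1, 0.9, 0.1), c("active", "active", "inactive")), 1)
  expect_equal(auc_mw(rep(0.3, 4), rep(c("active", "inactive"), 2)), 0.5)
  set.seed(41)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    post <- sample(round(runif(n), sample(c(1, 2, 6), 1)))  # force ties
    lab <- sample(c("active", "inactive"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(auc_mw(post, lab), openzfp:::auc_trapezoid(post, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (i in 1:10) {
    post <- round(runif(30), 2)
    lab <- sample(c("active", "inactive"), 30, replace = TRUE)
    if (length(unique(lab)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = lab, predictor = post, levels = c("inactive", "active"),
      direction = "<", quiet = TRUE)))
    expect_equal(auc_mw(post, lab), ref, tolerance = 1e-12)
  }
})

test_that("threshold search maximizes CC and breaks ties downward", {
  theta <- choose_threshold_max_cc(
    c(0.9, 0.8, 0.2, 0.1), c("active", "active", "inactive", "inactive"))
  expect_equal(theta, 0.5)  # smallest candidate midpoint achieving CC = 1
  flat <- choose_threshold_max_cc(rep(0.7, 4),
                                  rep(c("active", "inactive"), 2))
  expect_equal(flat, 0)  # all thresholds tie at CC 0 -> smallest candidate
  expect_error(choose_threshold_max_cc(c(0.2, 0.4), c("active", "active")),
               "both")
})

test_that("TPR and FPR are non-increasing in the threshold", {
  set.seed(51)
  post <- runif(40)
  lab <- sample(c("active", "inactive"), 40, replace = TRUE)
  thetas <- seq(0, 1, by = 0.05)
  mets <- lapply(thetas, function(t)
    classification_metrics(confusion_counts(post, lab, t)))
  tpr <- vapply(mets, function(m) m$tpr, numeric(1))
  fpr <- vapply(mets, function(m) m$fpr, numeric(1))
  expect_true(all(diff(tpr) <= 1e-12))
  expect_true(all(diff(fpr) <= 1e-12))
})

test_that("naive Bayes LOOCV is exact, order-invariant, and separable-aware", {
  d <- toy_separable()
  ev <- loocv_nb(d)
  expect_s3_class(ev, "zf_eval")
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(ev$auc, 1)

  # the count-decrement fast path equals literally refitting per fold
  d2 <- zf_sites(random_9mers(14, seed = 61),
                 rep(c("active", "inactive"), 7))
  ev2 <- loocv_nb(d2, encoding = "positional")
  refit <- vapply(seq_len(nrow(d2)), function(i) {
    nb_posterior(nb_fit(d2[-i, ], encoding = "positional"), d2[i, ])
  }, numeric(1))
  expect_equal(ev2$predictions$posterior_active, refit, tolerance = 1e-12)

  # row order does not change the multiset of posteriors
  perm <- sample(nrow(d2))
  ev3 <- loocv_nb(d2[perm, ], encoding = "positional")
  expect_equal(sort(ev3$predictions$posterior_active),
               sort(ev2$predictions$posterior_active), tolerance = 1e-12)

  # the four-site hand example, leave each out
  hand <- toy_hand()
  evh <- loocv_nb(hand)
  oracle <- vapply(seq_len(4), function(i) {
    nb_oracle_posterior(hand[-i, ], hand$sequence[i], "identity", 1)
  }, numeric(1))
  expect_equal(evh$predictions$posterior_active, oracle, tolerance = 1e-10)

  expect_error(loocv_nb(zf_sites(c("GGGGGGGGG", "TTTTTTTTT", "TTTTTTTTC"),
                                 c("active", "inactive", "inactive"))),
               "two sites per class")
})

test_that("optimize_cc selects the threshold on pooled posteriors", {
  d <- toy_separable()
  ev <- loocv_nb(d, optimize_cc = TRUE)
  expect_equal(ev$theta_rule, "max-cc")
  expect_equal(ev$metrics$cc, 1)
})

test_that("holdout evaluation guards overlap and stratifies by confidence", {
  bench <- generate_benchmark(60, 40, seed = 71, beta_t = -2)
  ev <- evaluate_holdout(bench$train, bench$test, conf_split = 6)
  expect_equal(nrow(ev$predictions), 40)
  expect_named(ev$stratified, c("high", "low"))
  n_high <- if (is.null(ev$stratified$high)) 0 else ev$stratified$high$n
  n_low <- if (is.null(ev$stratified$low)) 0 else ev$stratified$low$n
  expect_equal(n_high + n_low, 40)
  expect_error(evaluate_holdout(bench$train, bench$train), "overlap")
})

test_that("eval objects expose tidy, glance and a ROC autoplot", {
  ev <- loocv_nb(toy_separable())
  td <- tidy(ev)
  expect_true(all(c("posterior_active", "predicted", "confidence") %in%
                    names(td)))
  g <- glance(ev)
  expect_equal(g$tp + g$fp + g$tn + g$fn, 8)
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})
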