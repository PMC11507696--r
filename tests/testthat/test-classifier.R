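toy_features <- function(n = 40, sep = TRUE, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  kl <- if (sep) ifelse(y, 10, 0) + rnorm(n, 0, 0.1) else rnorm(n)
  data.frame(kl_score = kl, z_score = rnorm(n), noise = rnorm(n))
}

test_that("separable features are learned perfectly by both variants", {
  x <- toy_features()
  y <- rep(c("decoy", "homolog"), each = 20)
  for (v in c("probability-weighted", "discrete-vote")) {
    fit <- decoy_classifier(x, y, n_estimators = 25, variant = v)
    expect_equal(roc_curve(predict(fit, x), y)$auc, 1)
    expect_true(all(predict(fit, x, type = "prob") >= 0 &
                    predict(fit, x, type = "prob") <= 1))
  }
})

test_that("label-free noise yields chance-level held-out AUC", {
  x <- toy_features(n = 200, sep = FALSE, seed = 2)
  y <- rep(c("decoy", "homolog"), 100)
  fit <- decoy_classifier(x[1:100, ], y[1:100], n_estimators = 100)
  auc <- roc_curve(predict(fit, x[101:200, ]), y[101:200])$auc
  expect_gt(auc, 0.3); expect_lt(auc, 0.7)
})

test_that("fits and predictions are deterministic", {
  x <- toy_features(seed = 3)
  y <- rep(c("decoy", "homolog"), each = 20)
  f1 <- decoy_classifier(x, y, n_estimators = 50)
  f2 <- decoy_classifier(x, y, n_estimators = 50)
  expect_identical(predict(f1, x), predict(f2, x))
  expect_error(decoy_classifier(x, rep("decoy", 40)), "single class")
})

test_that("one boosting round reproduces the hand-computed stage", {
  # four equally weighted points; the best stump puts decoys above 0.3 and
  # miscalls only the decoy at 0.1: error 1/4, alpha = log(0.75/0.25)
  x <- data.frame(f = c(0.1, 0.2, 0.4, 0.9))
  y <- c(TRUE, FALSE, TRUE, TRUE)
  fit <- decoy_classifier(x, y, n_estimators = 1, learning_rate = 1,
                          variant = "discrete-vote")
  st <- fit$stages[[1]]
  expect_equal(st$alpha, log(3), tolerance = 1e-12)
  expect_equal(st$threshold, 0.3)
  expect_equal(st$direction, 1L)
})

test_that("ROC sweep matches hand enumeration and pROC", {
  r <- roc_curve(c(0.9, 0.8, 0.7, 0.1), c("decoy", "homolog", "decoy",
                                          "homolog"))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_curve(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(roc_curve(1:3, rep(TRUE, 3)), "both classes")

  set.seed(5)
  sc <- rnorm(60); y <- runif(60) < 0.4
  ours <- roc_curve(sc, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = sc,
                                        quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(ours, ref, tolerance = 1e-12)
  # monotone curve, AUC within [0, 1]
  pts <- roc_curve(sc, y)$points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_gte(ours, 0); expect_lte(ours, 1)
})

test_that("the 5 percent FPR operating point interpolates the curve", {
  # every decoy scores above every homolog: the curve reaches (0, 1), so
  # the interpolated sensitivity at any FPR is 1
  sc <- c(rep(0.1, 19), 0.8, rep(0.85, 5))
  y <- c(rep(FALSE, 20), rep(TRUE, 5))
  r <- roc_curve(sc, y)
  expect_equal(r$sens_at_fpr05, 1)
})

test_that("grid search returns single points and covers both variants", {
  x <- toy_features(n = 60, seed = 7)
  y <- rep(c("decoy", "homolog"), each = 30)
  groups <- rep(paste0("g", 1:12), each = 5)
  single <- data.frame(n_estimators = 10L, learning_rate = 1,
                       variant = "discrete-vote", stringsAsFactors = FALSE)
  gs <- grid_search_boost(x, y, groups, grid = single, folds = 3, seed = 1)
  expect_equal(gs$best$n_estimators, 10L)
  expect_equal(nrow(gs$results), 1L)

  grid <- expand.grid(n_estimators = c(5L, 20L), learning_rate = 1,
                      variant = c("probability-weighted", "discrete-vote"),
                      stringsAsFactors = FALSE)
  gs2 <- grid_search_boost(x, y, groups, grid = grid, folds = 3, seed = 1)
  gs3 <- grid_search_boost(x, y, groups, grid = grid, folds = 3, seed = 1)
  expect_identical(gs2$results, gs3$results)
  expect_setequal(unique(gs2$results$variant),
                  c("probability-weighted", "discrete-vote"))
  expect_error(grid_search_boost(x, y, groups, grid = grid, folds = 50),
               "folds")
})

test_that("feature importances sum to one and name the informative feature", {
  x <- toy_features(seed = 11)
  y <- rep(c("decoy", "homolog"), each = 20)
  fit <- decoy_classifier(x, y, n_estimators = 30)
  imp <- coef(fit)
  expect_equal(sum(imp), 1)
  expect_equal(names(which.max(imp)), "kl_score")
})

test_that("group classification respects the threshold semantics", {
  g <- make_decoy_group(seed = 21, n_homologs = 4, length = 50)
  tr <- run_turbo(g)
  x <- toy_features(seed = 13)
  y <- rep(c("decoy", "homolog"), each = 20)
  fit <- decoy_classifier(x[, 1:2], y, n_estimators = 20)
  feats <- feature_table(tr)
  rep0 <- classify_group(fit, tr, threshold = 0)
  expect_true(all(rep0$verdict == "decoy"))
  rep1 <- classify_group(fit, tr, threshold = 1 + 1e-9)
  expect_true(all(rep1$verdict == "homolog"))
  expect_equal(nrow(rep0), length(g))
  expect_identical(rep0$id, g$ids)
})

test_that("classifier files round trip through the text serialization", {
  x <- toy_features(seed = 17)
  y <- rep(c("decoy", "homolog"), each = 20)
  for (v in c("probability-weighted", "discrete-vote")) {
    fit <- decoy_classifier(x, y, n_estimators = 15, learning_rate = 1.5,
                            variant = v)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_classifier(fit, f)
    back <- read_classifier(f)
    expect_equal(predict(back, x), predict(fit, x), tolerance = 1e-12)
    expect_equal(back$variant, v)
  }
  junk <- withr::local_tempfile(fileext = ".tsv")
  writeLines("nope", junk)
  expect_error(read_classifier(junk), "not an rnadecoy model")
})
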