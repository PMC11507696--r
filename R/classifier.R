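#' Fit an adaptive-boosting decoy classifier
#'
#' Boosted depth-one decision trees (stumps) on the six per-sequence
#' features, in one of two flavors: `"discrete-vote"` is the classic
#' two-class SAMME update (each stump casts a weighted vote) and
#' `"probability-weighted"` stages half log-odds of the stump's weighted
#' leaf probabilities (real boosting). Fitting is deterministic: stumps
#' are chosen by exhaustive threshold search with fixed tie-breaking, so
#' `seed` only matters for downstream resampling helpers.
#'
#' @param x data frame or matrix of feature columns (non-numeric columns
#'   such as `id`/`label` are dropped from a data frame automatically).
#' @param labels per-row truth: `"decoy"`/`"homolog"` (or a logical vector,
#'   TRUE = decoy).
#' @param n_estimators maximum number of boosting stages.
#' @param learning_rate shrinkage applied to each stage.
#' @param variant `"probability-weighted"` or `"discrete-vote"`.
#' @param seed optional seed (kept for interface symmetry; the fit itself
#'   draws no random numbers).
#' @return an object of class `decoy_classifier` with `print`, `summary`,
#'   `predict`, `coef` and `plot` methods.
#' @examples
#' x <- data.frame(kl_score = c(0, 0.1, 5, 6), z_score = c(0, 0, 1, 1))
#' fit <- decoy_classifier(x, c(FALSE, FALSE, TRUE, TRUE), n_estimators = 5)
#' predict(fit, x)
#' @export
decoy_classifier <- function(x, labels, n_estimators = 500L,
                             learning_rate = 1,
                             variant = c("probability-weighted",
                                         "discrete-vote"),
                             seed = NULL) {
  variant <- match.arg(variant)
  xm <- feature_matrix(x)
  y <- as_decoy_labels(labels)
  stopifnot(nrow(xm) == length(y), n_estimators >= 1L, learning_rate > 0)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  n <- nrow(xm)
  w <- rep(1 / n, n)
  ord <- lapply(seq_len(ncol(xm)), function(j) order(xm[, j]))
  stages <- vector("list", n_estimators)
  eps <- 1e-6
  for (t in seq_len(n_estimators)) {
    st <- fit_stump(xm, y, w, ord)
    if (is.null(st)) break
    pred <- stump_predict(st, xm)
    if (variant == "discrete-vote") {
      err <- sum(w[pred != y])
      err <- min(max(err, eps), 1 - eps)
      if (err >= 0.5) break
      alpha <- learning_rate * log((1 - err) / err)
      w <- w * exp(alpha * (pred != y))
      st$alpha <- alpha
    } else {
      side <- stump_side(st, xm)            # TRUE where x on the ">" side
      p_hi <- leaf_prob(y, w, side)
      p_lo <- leaf_prob(y, w, !side)
      f <- ifelse(side, 0.5 * log(p_hi / (1 - p_hi)),
                  0.5 * log(p_lo / (1 - p_lo))) * learning_rate
      yy <- ifelse(y, 1, -1)
      w <- w * exp(-yy * f)
      st$f_hi <- learning_rate * 0.5 * log(p_hi / (1 - p_hi))
      st$f_lo <- learning_rate * 0.5 * log(p_lo / (1 - p_lo))
    }
    w <- w / sum(w)
    stages[[t]] <- st
    # stop early once the stump is (numerically) perfect
    if (variant == "discrete-vote" && sum(pred != y) == 0) break
  }
  stages <- stages[!vapply(stages, is.null, TRUE)]
  if (!length(stages)) stop("boosting could not fit a single stump")
  structure(list(stages = stages, variant = variant,
                 n_estimators = length(stages),
                 learning_rate = learning_rate,
                 feature_names = colnames(xm)),
            class = "decoy_classifier")
}

feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    keep <- vapply(x, is.numeric, TRUE)
    x <- as.matrix(x[keep])
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

as_decoy_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("decoy", "homolog"))
  if (length(bad)) stop("labels must be decoy/homolog, got: ", bad[1L])
  labels == "decoy"
}

leaf_prob <- function(y, w, sel, eps = 1e-6) {
  tot <- sum(w[sel])
  p <- if (tot > 0) sum(w[sel & y]) / tot else 0.5
  min(max(p, eps), 1 - eps)
}

# best weighted stump over all features/thresholds; predicts decoy on the
# ">" side when direction is +1, on the "<=" side when -1. Tie-break:
# lowest feature index, then lowest threshold, then direction +1.
fit_stump <- function(xm, y, w, ord) {
  best <- NULL
  best_err <- Inf
  W_pos <- sum(w[y]); W_neg <- sum(w[!y])
  for (j in seq_len(ncol(xm))) {
    o <- ord[[j]]
    v <- xm[o, j]
    wy <- w[o] * y[o]
    wn <- w[o] * !y[o]
    cpos <- cumsum(wy); cneg <- cumsum(wn)
    # split after sorted index k: "<=" side is 1..k
    valid <- which(v[-length(v)] < v[-1L])    # distinct neighbors only
    if (!length(valid)) next
    err_hi <- cpos[valid] + (W_neg - cneg[valid])   # decoy on ">" side
    err_lo <- (W_pos - cpos[valid]) + cneg[valid]    # decoy on "<=" side
    for (dir in c(1L, -1L)) {
      errs <- if (dir == 1L) err_hi else err_lo
      k <- which.min(errs)
      if (errs[k] < best_err - 1e-12) {
        best_err <- errs[k]
        thr <- (v[valid[k]] + v[valid[k] + 1L]) / 2
        best <- list(feature = j, threshold = thr, direction = dir)
      }
    }
  }
  best
}

stump_side <- function(st, xm) xm[, st$feature] > st$threshold

stump_predict <- function(st, xm) {
  side <- stump_side(st, xm)
  if (st$direction == 1L) side else !side
}

classifier_score <- function(object, xm) {
  f <- numeric(nrow(xm))
  if (object$variant == "discrete-vote") {
    tot <- 0
    for (st in object$stages) {
      vote <- ifelse(stump_predict(st, xm), 1, -1)
      f <- f + st$alpha * vote
      tot <- tot + st$alpha
    }
    f / tot                       # in [-1, 1]
  } else {
    for (st in object$stages) {
      side <- stump_side(st, xm)
      f <- f + ifelse(side, st$f_hi, st$f_lo)
    }
    f
  }
}

#' Predict decoy probabilities
#'
#' @param object a [decoy_classifier].
#' @param newdata feature data frame or matrix with the training columns.
#' @param type `"prob"` (default) for the decoy probability, `"score"` for
#'   the raw boosted score, `"verdict"` for the thresholded call.
#' @param threshold decoy-call threshold used for `type = "verdict"`.
#' @param ... unused.
#' @return numeric vector (or character vector of verdicts).
#' @export
predict.decoy_classifier <- function(object, newdata,
                                     type = c("prob", "score", "verdict"),
                                     threshold = 0.4971, ...) {
  type <- match.arg(type)
  xm <- feature_matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(xm))
  if (length(missing))
    stop("newdata lacks feature column: ", missing[1L])
  xm <- xm[, object$feature_names, drop = FALSE]
  f <- classifier_score(object, xm)
  if (type == "score") return(f)
  p <- if (object$variant == "discrete-vote") (f + 1) / 2
       else 1 / (1 + exp(-2 * f))
  if (type == "prob") p else ifelse(p >= threshold, "decoy", "homolog")
}

#' @export
print.decoy_classifier <- function(x, ...) {
  cat("<decoy_classifier> ", x$n_estimators, " stumps, variant ",
      x$variant, ", learning rate ", x$learning_rate, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::summary
summary.decoy_classifier <- function(object, ...) {
  cat("Adaptive-boosting decoy classifier\n")
  print(object)
  imp <- coef(object)
  cat("Feature importances (share of total stage weight):\n")
  print(round(imp, 3))
  invisible(imp)
}

#' Feature importances of a boosted classifier
#'
#' The share of total absolute stage weight carried by stumps splitting on
#' each feature.
#'
#' @param object a [decoy_classifier].
#' @param ... unused.
#' @return named numeric vector summing to one.
#' @exportS3Method stats::coef
coef.decoy_classifier <- function(object, ...) {
  wt <- vapply(object$stages, function(st)
    if (!is.null(st$alpha)) abs(st$alpha)
    else abs(st$f_hi) + abs(st$f_lo), 0)
  feat <- vapply(object$stages, function(st) st$feature, 0L)
  imp <- vapply(seq_along(object$feature_names),
                function(j) sum(wt[feat == j]), 0)
  names(imp) <- object$feature_names
  imp / sum(imp)
}

#' @exportS3Method base::plot
plot.decoy_classifier <- function(x, ...) {
  imp <- coef(x)
  barplot(sort(imp, decreasing = TRUE), las = 2,
          ylab = "importance", main = "stump weight by feature", ...)
  invisible(x)
}

#' ROC curve and AUC for decoy scores
#'
#' Threshold sweep over the unique scores; reports the trapezoidal area
#' under the curve and the sensitivity at a 5 percent false-positive rate
#' (linearly interpolated), the conventional operating point for decoy
#' screening.
#'
#' @param scores numeric decoy scores or probabilities (higher = more
#'   decoy-like).
#' @param labels truth per score (`"decoy"`/`"homolog"` or logical).
#' @return object of class `roc_curve`: list with `points` (data frame of
#'   threshold, fpr, tpr), `auc`, and `sens_at_fpr05`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_decoy_labels(labels)
  stopifnot(length(scores) == length(y))
  if (!any(y) || all(y)) stop("ROC needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(y); nneg <- sum(!y)
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / npos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / nneg, 0)
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc,
                 sens_at_fpr05 = sens_at_fpr(pts, 0.05)),
            class = "roc_curve")
}

sens_at_fpr <- function(pts, target) {
  # vertical ROC segments: keep the highest sensitivity per FPR value
  agg <- tapply(pts$tpr, pts$fpr, max)
  stats::approx(as.numeric(names(agg)), as.numeric(agg),
                xout = target, rule = 2)$y
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f; sensitivity %.3f at 5%% FPR\n",
              x$auc, x$sens_at_fpr05))
  invisible(x)
}

#' @exportS3Method base::plot
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity", ...)
  abline(0, 1, lty = 3)
  points(0.05, x$sens_at_fpr05, pch = 19)
  invisible(x)
}

#' Export an ROC curve as a tab-separated table
#' @param roc a [roc_curve].
#' @param path output path.
#' @export
write_roc <- function(roc, path) {
  out <- roc$points
  out$sensitivity <- out$tpr
  out$specificity <- 1 - out$fpr
  write.table(out[, c("threshold", "sensitivity", "specificity")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Grouped-fold grid search for boosting parameters
#'
#' Cross-validated AUC over a parameter grid, with folds assigned at the
#' group level so all sequences of a group stay in one fold. The default
#' desk-scale grid subsamples the conventional ranges logarithmically
#' (estimators 20-2000, learning rate 0.5-20, both variants).
#'
#' @param x feature data frame or matrix.
#' @param labels decoy/homolog truth per row.
#' @param groups group identifier per row.
#' @param grid data frame with columns `n_estimators`, `learning_rate`,
#'   `variant`.
#' @param folds number of cross-validation folds (at most the number of
#'   groups).
#' @param seed seed for the fold assignment.
#' @return list with `best` (the winning grid row), `results` (the grid
#'   plus a `cv_auc` column).
#' @export
grid_search_boost <- function(x, labels, groups, grid = default_boost_grid(),
                              folds = 3L, seed = 1L) {
  xm <- feature_matrix(x)
  y <- as_decoy_labels(labels)
  groups <- as.character(groups)
  stopifnot(nrow(grid) >= 1L, nrow(xm) == length(y),
            length(groups) == length(y))
  ug <- unique(groups)
  if (folds > length(ug)) stop("more folds than groups")
  fold_of <- with_seed(seed, {
    gshuf <- sample(ug)
    setNames(rep_len(seq_len(folds), length(ug)), gshuf)
  })
  fold <- fold_of[groups]
  cv_auc <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
        return(NA_real_)
      fit <- decoy_classifier(xm[tr, , drop = FALSE], y[tr],
                              n_estimators = grid$n_estimators[r],
                              learning_rate = grid$learning_rate[r],
                              variant = grid$variant[r])
      roc_curve(predict(fit, xm[!tr, , drop = FALSE]), y[!tr])$auc
    }, 0)
    cv_auc[r] <- mean(aucs, na.rm = TRUE)
  }
  results <- cbind(grid, cv_auc = cv_auc)
  list(best = grid[which.max(cv_auc), , drop = FALSE], results = results)
}

#' @rdname grid_search_boost
#' @export
default_boost_grid <- function() {
  expand.grid(n_estimators = c(20L, 100L, 500L, 2000L),
              learning_rate = c(0.5, 1, 5, 20),
              variant = c("probability-weighted", "discrete-vote"),
              stringsAsFactors = FALSE)
}

#' Classify every sequence of an analyzed group
#'
#' Computes the feature table from a consensus-folding result and queries a
#' trained classifier; a sequence is called a decoy when its probability
#' reaches `threshold` (the default corresponds to an operating point at
#' a 5 percent false-positive rate, but the threshold is model-specific
#' and should be re-derived from the ROC of any retrained model).
#'
#' @param model a [decoy_classifier].
#' @param result a [run_turbo()] result.
#' @param threshold decoy probability threshold.
#' @return data frame: `id`, the six features, `decoy_probability`,
#'   `verdict`.
#' @export
classify_group <- function(model, result, threshold = 0.4971) {
  feats <- feature_table(result)
  p <- predict(model, feats)
  feats$decoy_probability <- p
  feats$verdict <- ifelse(p >= threshold, "decoy", "homolog")
  feats
}

#' Serialize a classifier to a versioned text file
#'
#' @param model a [decoy_classifier].
#' @param path output path.
#' @export
write_classifier <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# rnadecoy-model v1",
               paste0("# variant=", model$variant,
                      " learning_rate=", model$learning_rate),
               paste0("# features=", paste(model$feature_names,
                                           collapse = ","))), con)
  df <- do.call(rbind, lapply(model$stages, function(st)
    data.frame(feature = st$feature, threshold = st$threshold,
               direction = st$direction,
               alpha = st$alpha %||% NA_real_,
               f_hi = st$f_hi %||% NA_real_,
               f_lo = st$f_lo %||% NA_real_)))
  write.table(format(df, digits = 17L), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a classifier written by [write_classifier()]
#' @param path path to the model file.
#' @return a [decoy_classifier].
#' @export
read_classifier <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "# rnadecoy-model"))
    stop("not an rnadecoy model file: ", path)
  meta <- lines[2L]
  variant <- sub(".*variant=(\\S+).*", "\\1", meta)
  lr <- as.numeric(sub(".*learning_rate=(\\S+).*", "\\1", meta))
  feats <- strsplit(sub("# features=", "", lines[3L]), ",")[[1L]]
  df <- read.table(text = lines[-(1:3)], header = TRUE)
  stages <- lapply(seq_len(nrow(df)), function(r) {
    st <- list(feature = df$feature[r], threshold = df$threshold[r],
               direction = df$direction[r])
    if (!is.na(df$alpha[r])) st$alpha <- df$alpha[r]
    if (!is.na(df$f_hi[r])) { st$f_hi <- df$f_hi[r]; st$f_lo <- df$f_lo[r] }
    st
  })
  structure(list(stages = stages, variant = variant,
                 n_estimators = length(stages), learning_rate = lr,
                 feature_names = feats),
            class = "decoy_classifier")
}
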