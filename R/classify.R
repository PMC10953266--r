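# Random-forest discrimination of patient vs control from fitted SGM
# parameters (+ age), with repeated nested stratified cross-validation
# for max-depth tuning and mean-decrease-impurity feature importances.

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation; ties in scores contribute 1/2.
#'
#' @param scores numeric predictions (higher = more patient-like).
#' @param labels 0/1 or logical truth.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("need both classes for AUROC")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validation configuration for cohort classification
#'
#' @param n_outer_folds outer stratified folds (default 5).
#' @param n_repeats repetitions of the whole CV (100 for production;
#'   default 10 in the desk-scale profile).
#' @param inner_folds folds of the inner tuning CV.
#' @param max_depth_grid candidate tree depth caps; `Inf` = unbounded.
#' @param n_trees trees per forest (sklearn-style default 100).
#' @param seed base seed.
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(n_outer_folds = 5, n_repeats = 10, inner_folds = 5,
                      max_depth_grid = c(Inf, 2, 3, 4), n_trees = 100,
                      seed = 1) {
  stopifnot(n_outer_folds >= 2, inner_folds >= 2, n_repeats >= 1)
  structure(list(n_outer_folds = n_outer_folds, n_repeats = n_repeats,
                 inner_folds = inner_folds, max_depth_grid = max_depth_grid,
                 n_trees = n_trees, seed = seed),
            class = "cv_config")
}

# Stratified fold assignment: within each class, shuffle and deal round
# robin. Deterministic given the RNG state.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit a random forest (Gini CART ensemble)
#'
#' @param X numeric feature matrix.
#' @param y 0/1 labels.
#' @param n_trees number of trees.
#' @param max_depth depth cap (`Inf` = unbounded).
#' @param mtry candidate features per split (default `floor(sqrt(p))`).
#' @param seed integer seed (forest growth is deterministic given it).
#' @return an object of class `sgm_forest` with `trees` and normalized
#'   `importance`.
#' @export
rf_fit <- function(X, y, n_trees = 100, max_depth = Inf,
                   mtry = max(1L, floor(sqrt(ncol(X)))), seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("single-class input")
  md <- if (is.finite(max_depth)) as.integer(max_depth) else 0L
  res <- .rf_build_cpp(X, y, as.integer(n_trees), md, as.integer(mtry),
                       as.integer(seed) %% 2147483647L)
  structure(list(trees = res$trees,
                 importance = setNames(as.numeric(res$importance),
                                       colnames(X)),
                 n_trees = n_trees, max_depth = max_depth, mtry = mtry),
            class = "sgm_forest")
}

#' @rdname rf_fit
#' @param object a fitted `sgm_forest`.
#' @param newdata feature matrix to score.
#' @param ... unused.
#' @return predicted class-1 probabilities.
#' @export
predict.sgm_forest <- function(object, newdata, ...) {
  .rf_predict_cpp(object$trees, as.matrix(newdata))
}

#' Classify a cohort with repeated nested stratified cross-validation
#'
#' Per repeat: stratified outer split; per outer fold an inner stratified
#' CV grid search selects the tree-depth cap by mean inner AUROC (ties
#' broken toward shallower trees), the forest is refit on the full outer
#' training fold and evaluated on the held-out fold. Metrics are
#' aggregated over repeats x folds; feature importances are averaged
#' over all outer-fold forests.
#'
#' @param features subjects x features numeric matrix or data.frame
#'   (e.g. the 7 fitted parameters + age).
#' @param labels group labels (`control`/`patient`, factor, or 0/1;
#'   patient = positive class).
#' @param cfg a [cv_config()].
#' @return an object of class `classifier_report`: `auroc_mean`,
#'   `auroc_sd`, `accuracy`, `precision`, `recall`, `f1`,
#'   `feature_importances`, `confusion_matrix`, `depth_choices`.
#' @export
classify_cohort <- function(features, labels, cfg = cv_config()) {
  X <- as.matrix(features)
  y <- if (is.numeric(labels)) as.integer(labels)
       else as.integer(labels == "patient")
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("single-class input")
  if (is.null(colnames(X))) colnames(X) <- paste0("feat", seq_len(ncol(X)))

  aucs <- c(); accs <- c(); precs <- c(); recs <- c(); f1s <- c()
  imps <- matrix(0, 0, ncol(X), dimnames = list(NULL, colnames(X)))
  cm <- matrix(0L, 2, 2, dimnames = list(truth = c("control", "patient"),
                                         pred = c("control", "patient")))
  depth_choices <- c()
  grid <- cfg$max_depth_grid

  for (rep in seq_len(cfg$n_repeats)) {
    folds <- with_seed(derive_seed(cfg$seed, "outer", rep),
                       stratified_folds(y, cfg$n_outer_folds))
    for (fo in seq_len(cfg$n_outer_folds)) {
      tr <- folds != fo; te <- !tr
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      # inner grid search over depth on the training fold only
      inner <- with_seed(derive_seed(cfg$seed, "inner", rep, fo),
                         stratified_folds(ytr, cfg$inner_folds))
      mean_auc <- vapply(seq_along(grid), function(gi) {
        a <- vapply(seq_len(cfg$inner_folds), function(fi) {
          itr <- inner != fi
          if (length(unique(ytr[!itr])) < 2) return(NA_real_)
          m <- rf_fit(Xtr[itr, , drop = FALSE], ytr[itr],
                      n_trees = cfg$n_trees, max_depth = grid[gi],
                      seed = derive_seed(cfg$seed, rep, fo, gi, fi))
          auroc(predict(m, Xtr[!itr, , drop = FALSE]), ytr[!itr])
        }, numeric(1))
        mean(a, na.rm = TRUE)
      }, numeric(1))
      cand <- which(mean_auc >= max(mean_auc) - 1e-12)
      best_depth <- grid[cand[which.min(grid[cand])]]
      depth_choices <- c(depth_choices, best_depth)

      m <- rf_fit(Xtr, ytr, n_trees = cfg$n_trees, max_depth = best_depth,
                  seed = derive_seed(cfg$seed, "refit", rep, fo))
      pr <- predict(m, X[te, , drop = FALSE])
      yte <- y[te]
      aucs <- c(aucs, auroc(pr, yte))
      pred <- as.integer(pr >= 0.5)
      tp <- sum(pred == 1 & yte == 1); fp <- sum(pred == 1 & yte == 0)
      tn <- sum(pred == 0 & yte == 0); fn <- sum(pred == 0 & yte == 1)
      accs <- c(accs, (tp + tn) / length(yte))
      prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      precs <- c(precs, prec); recs <- c(recs, rec)
      f1s <- c(f1s, if (is.na(prec) || is.na(rec) || prec + rec == 0)
                      NA_real_ else 2 * prec * rec / (prec + rec))
      cm <- cm + matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE)
      imps <- rbind(imps, m$importance)
    }
  }
  fi <- colMeans(imps)
  fi <- fi / sum(fi)
  structure(list(auroc_mean = mean(aucs), auroc_sd = sd(aucs),
                 accuracy = mean(accs), precision = mean(precs, na.rm = TRUE),
                 recall = mean(recs, na.rm = TRUE),
                 f1 = mean(f1s, na.rm = TRUE),
                 feature_importances = fi, confusion_matrix = cm,
                 depth_choices = depth_choices, n_forests = nrow(imps),
                 cfg = cfg),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "classification: AUROC %.3f (sd %.3f), acc %.2f, prec %.2f, rec %.2f, f1 %.2f\n",
    x$auroc_mean, x$auroc_sd, x$accuracy, x$precision, x$recall, x$f1))
  cat("feature importances:\n")
  print(round(sort(x$feature_importances, decreasing = TRUE), 3))
  invisible(x)
}
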