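#' Stratified train/test split
#'
#' Splits samples into train and test sets, stratified by group, so an
#' 80/20 split of a 50+50 cohort yields 40+40 training and 10+10 test
#' samples. Deterministic under the seed.
#'
#' @param meta sample metadata (sample_id, group).
#' @param train_fraction fraction of each group assigned to training.
#' @param seed RNG seed.
#' @return list(train = sample ids, test = sample ids).
#' @export
splitTrainTest <- function(meta, train_fraction = 0.8, seed = 1) {
  if (any(table(meta$group) < 2)) stop("every group needs >= 2 samples")
  set.seed(seed)
  train <- character()
  for (g in unique(meta$group)) {
    ids <- meta$sample_id[meta$group == g]
    train <- c(train, sample(ids, round(train_fraction * length(ids))))
  }
  list(train = sort(train), test = sort(setdiff(meta$sample_id, train)))
}

# stratified fold assignment: shuffles within class, deals folds round-robin
.stratifiedFolds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in levels(y)) {
    i <- sample(which(y == cl))
    f[i] <- rep_len(seq_len(folds), length(i))
  }
  f
}

#' Cross-validation error curve over candidate feature counts
#'
#' Ranks features once on the full training set by random-forest permutation
#' importance (mean decrease in accuracy), then, for each candidate count k,
#' estimates the misclassification error of a forest restricted to the top k
#' features by stratified 10-fold cross-validation repeated over
#' \code{trials} reshuffles. The selected k is the argmin of the mean error
#' (ties towards the smallest k). Candidate counts above the number of
#' available features are skipped with a warning.
#'
#' @param X samples x features numeric matrix (rownames = sample ids).
#' @param y two-level factor of class labels, aligned with rows of X.
#' @param ks candidate feature counts.
#' @param trials,folds cross-validation design (default 5 trials of
#'   10-fold).
#' @param seed RNG seed.
#' @param ntree forest size.
#' @return list(cv_curve = data.frame(k, error), k_selected,
#'   importance = data.frame(feature, importance) sorted descending).
#' @export
cvErrorCurve <- function(X, y, ks = c(5, 10, 20, 50, 70, 100, 200, 500, 1000),
                         trials = 5, folds = 10, seed = 1, ntree = 500) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("two classes required")
  if (nrow(X) < folds) stop("fewer training samples than folds")
  set.seed(seed)
  rf <- randomForest::randomForest(X, y, ntree = ntree, importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)[, 1]
  ranking <- data.frame(feature = names(sort(imp, decreasing = TRUE)),
                        importance = sort(imp, decreasing = TRUE),
                        row.names = NULL)
  ks_use <- sort(unique(as.integer(ks)))
  drop <- ks_use > ncol(X)
  if (any(drop)) {
    warning("skipping k > available features: ",
            paste(ks_use[drop], collapse = ", "))
    ks_use <- ks_use[!drop]
  }
  if (!length(ks_use)) ks_use <- ncol(X)
  err <- matrix(NA_real_, trials, length(ks_use))
  for (tr in seq_len(trials)) {
    fold <- .stratifiedFolds(y, folds)
    for (ki in seq_along(ks_use)) {
      feats <- ranking$feature[seq_len(ks_use[ki])]
      wrong <- 0L
      for (fd in seq_len(folds)) {
        hold <- fold == fd
        fit <- randomForest::randomForest(
          X[!hold, feats, drop = FALSE], y[!hold], ntree = ntree)
        pred <- stats::predict(fit, X[hold, feats, drop = FALSE])
        wrong <- wrong + sum(pred != y[hold])
      }
      err[tr, ki] <- wrong / length(y)
    }
  }
  curve <- data.frame(k = ks_use, error = colMeans(err))
  list(cv_curve = curve, k_selected = ks_use[which.min(curve$error)],
       importance = ranking)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a random positive scores above a random
#' negative (ties count one half). The ROC step curve is returned over all
#' score thresholds.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical or two-level factor; TRUE / second level =
#'   positive.
#' @return list(auc, roc = data.frame(fpr, tpr)).
#' @export
evaluateROC <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else
    as.factor(labels) == levels(as.factor(labels))[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(thr, function(t) sum(scores[!pos] >= t) / n0, numeric(1)),
    tpr = vapply(thr, function(t) sum(scores[pos] >= t) / n1, numeric(1)))
  list(auc = auc, roc = roc)
}

#' DeLong confidence interval for an AUC
#'
#' Analytic (DeLong) variance estimate as implemented in pROC, truncated to
#' [0, 1]. A perfectly separating score has zero DeLong variance; the CI
#' then collapses to the point estimate and is flagged.
#'
#' @param scores,labels as in [evaluateROC()].
#' @param level confidence level.
#' @return list(lower, upper, degenerate).
#' @export
aucCI <- function(scores, labels, level = 0.95) {
  pos <- if (is.logical(labels)) labels else
    as.factor(labels) == levels(as.factor(labels))[2]
  if (sum(pos) < 2 || sum(!pos) < 2) stop("need >= 2 per class")
  roc <- pROC::roc(response = pos, predictor = scores, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
  ci <- suppressWarnings(pROC::ci.auc(roc, conf.level = level,
                                      method = "delong"))
  lower <- max(0, ci[1]); upper <- min(1, ci[3])
  list(lower = lower, upper = upper, degenerate = lower == upper)
}

#' Train and evaluate the CAG-based disease classifier
#'
#' The discrimination stage: stratified 80/20 split, permutation-importance
#' ranking and 5x10-fold cross-validation error curve over candidate feature
#' counts on the training set, a final forest on the selected top-k
#' features, and ROC/AUC with DeLong 95% confidence intervals. Training-set
#' probabilities are out-of-bag (so the training AUC is not trivially 1);
#' test-set probabilities come from the held-out prediction.
#'
#' @param cag_abundance CAG x sample abundance matrix (or [CAGSet-class]).
#' @param meta sample metadata (sample_id, group with case/control).
#' @param ks candidate feature counts for the CV curve.
#' @param train_fraction,trials,folds,ntree,seed tuning as in
#'   [cvErrorCurve()] and [splitTrainTest()].
#' @return A [ClassifierReport-class].
#' @export
trainCagClassifier <- function(cag_abundance, meta,
                               ks = c(5, 10, 20, 50, 70, 100, 200, 500, 1000),
                               train_fraction = 0.8, trials = 5, folds = 10,
                               ntree = 500, seed = 1) {
  ab <- if (is(cag_abundance, "CAGSet")) abundances(cag_abundance)
        else as.matrix(cag_abundance)
  X <- t(ab)
  grp <- meta$group[match(rownames(X), meta$sample_id)]
  y <- factor(grp, levels = c("control", "case"))
  split <- splitTrainTest(meta[meta$sample_id %in% rownames(X), ],
                          train_fraction, seed)
  itr <- rownames(X) %in% split$train
  cv <- cvErrorCurve(X[itr, , drop = FALSE], y[itr], ks = ks,
                     trials = trials, folds = min(folds, sum(itr)),
                     seed = seed, ntree = ntree)
  feats <- cv$importance$feature[seq_len(cv$k_selected)]
  set.seed(seed + 1L)
  final <- randomForest::randomForest(X[itr, feats, drop = FALSE], y[itr],
                                      ntree = ntree)
  prob_train <- stats::predict(final, type = "prob")[, "case"]
  prob_test <- stats::predict(final, X[!itr, feats, drop = FALSE],
                              type = "prob")[, "case"]
  train_roc <- evaluateROC(prob_train, y[itr] == "case")
  test_roc <- evaluateROC(prob_test, y[!itr] == "case")
  train_ci <- aucCI(prob_train, y[itr] == "case")
  test_ci <- aucCI(prob_test, y[!itr] == "case")
  probs <- rbind(
    data.frame(sample_id = rownames(X)[itr], group = grp[itr],
               set = "train", prob_case = unname(prob_train)),
    data.frame(sample_id = rownames(X)[!itr], group = grp[!itr],
               set = "test", prob_case = unname(prob_test)))
  new("ClassifierReport",
      trainIds = split$train, testIds = split$test,
      importance = cv$importance, cvCurve = cv$cv_curve,
      kSelected = as.integer(cv$k_selected),
      trainAUC = train_roc$auc, trainCI = c(train_ci$lower, train_ci$upper),
      testAUC = test_roc$auc, testCI = c(test_ci$lower, test_ci$upper),
      probabilities = probs)
}
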