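## Classifiers and cross-validation schemes.
##
## Three model families: Gaussian-kernel SVM (SVM-G, e1071/libsvm),
## L1-regularized logistic regression (the "SVM-LASSO" reading: a linear
## maximum-margin-style classifier with lasso shrinkage, glmnet), and random
## forest (ranger). Features are z-scored with training-fold statistics only;
## hyper-parameters are tuned recursively on all but one fold of the training
## set and tested on the remaining fold; the positive class is ASD and a
## subject's group is decided by the averaged posterior score of its records.

#' Model specification
#'
#' @param family one of `svmg`, `svmlasso`, `rf`.
#' @param grid data frame of hyper-parameter candidates. Defaults:
#'   SVM-G cost in \{0.1, 1, 10, 100\} x gamma in 10^seq(-3, 1, len 5);
#'   SVM-LASSO lambda in 10^seq(-3, 1, len 7); RF 500 trees with
#'   mtry rule in \{sqrt(p), p/3\}. A single-row grid skips inner tuning.
#' @param num_trees random-forest tree count (default 500).
#' @return a `model_spec`.
#' @export
model_spec <- function(family = c("svmg", "svmlasso", "rf"), grid = NULL,
                       num_trees = 500) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      svmg = expand.grid(cost = c(0.1, 1, 10, 100),
                         gamma = 10^seq(-3, 1, length.out = 5)),
      svmlasso = data.frame(lambda = 10^seq(-3, 1, length.out = 7)),
      rf = data.frame(mtry_rule = c("sqrt", "third"),
                      stringsAsFactors = FALSE)
    )
  }
  if (nrow(grid) == 0) stop("hyper-parameter grid must be non-empty")
  # order by model complexity so ties resolve to the smoothest model:
  # smallest cost then smallest gamma (SVM-G), largest lambda (lasso),
  # smallest mtry (RF)
  grid <- switch(family,
    svmg = grid[order(grid$cost, grid$gamma), , drop = FALSE],
    svmlasso = grid[order(-grid$lambda), , drop = FALSE],
    rf = grid[order(grid$mtry_rule != "sqrt"), , drop = FALSE]
  )
  structure(list(family = family, grid = grid, num_trees = num_trees),
            class = "model_spec")
}

#' Compact tuned specification
#'
#' A 2 x 2 SVM-G grid (cost 1/10, gamma 0.02/0.2 on standardized features)
#' bracketing the 1/p heuristic, spanning the useful range of the default
#' 20-point grid at a fraction of the refit cost; the grid used by the
#' headline analyses.
#'
#' @return a `model_spec`.
#' @export
model_spec_compact <- function() {
  model_spec("svmg", grid = expand.grid(cost = c(1, 10),
                                        gamma = c(0.02, 0.2)))
}

#' Reduced single-point specification
#'
#' Fixed hyper-parameters (SVM-G cost 1, gamma 1/p on standardized features),
#' used where a tuned grid would be re-fit hundreds of times, e.g. inside
#' permutation-null recomputation and the 40-class identity analysis.
#'
#' @param family model family.
#' @return a `model_spec` with a one-row grid.
#' @export
model_spec_reduced <- function(family = "svmg") {
  grid <- switch(family,
    svmg = data.frame(cost = 1, gamma = 1 / 50),
    svmlasso = data.frame(lambda = 0.01),
    rf = data.frame(mtry_rule = "sqrt", stringsAsFactors = FALSE)
  )
  model_spec(family, grid = grid)
}

feature_matrix <- function(ds) {
  as.matrix(ds[, feature_names()])
}

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mu), 2, scaler$sd, `/`)
}

rf_mtry <- function(rule, p) {
  switch(rule, sqrt = max(1L, floor(sqrt(p))), third = max(1L, floor(p / 3)),
         stop("unknown mtry rule: ", rule))
}

## Fit one model family at fixed hyper-parameters on standardized features.
fit_one <- function(family, x, y, params, num_trees = 500) {
  switch(family,
    svmg = e1071::svm(x, y, kernel = "radial", cost = params$cost,
                      gamma = params$gamma, scale = FALSE),
    svmlasso = glmnet::glmnet(
      x, y, family = if (nlevels(y) > 2) "multinomial" else "binomial",
      alpha = 1, lambda = params$lambda),
    rf = ranger::ranger(
      x = x, y = y, num.trees = num_trees,
      mtry = rf_mtry(params$mtry_rule, ncol(x)),
      probability = nlevels(y) == 2, num.threads = 1,
      seed = sample.int(.Machine$integer.max, 1))
  )
}

## Predicted class labels on standardized features.
predict_labels <- function(family, model, x, levels = NULL) {
  switch(family,
    svmg = as.character(stats::predict(model, x)),
    svmlasso = {
      pr <- stats::predict(model, x, type = "class")
      as.character(pr[, 1])
    },
    rf = {
      pr <- stats::predict(model, data = x, num.threads = 1)$predictions
      if (is.matrix(pr)) colnames(pr)[max.col(pr, ties.method = "first")]
      else as.character(pr)
    }
  )
}

## Posterior score for the positive class (ASD), binary tasks only.
## SVM-G uses the logistic-squashed signed margin; glmnet and ranger report
## model probabilities directly.
predict_posterior <- function(family, model, x) {
  switch(family,
    svmg = {
      pr <- stats::predict(model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      nm <- colnames(dv)[1]
      d <- as.numeric(dv[, 1])
      # libsvm orients the decision value toward the first-listed class
      pos_first <- startsWith(nm, "ASD")
      stats::plogis(if (pos_first) d else -d)
    },
    rf = {
      pr <- stats::predict(model, data = x, num.threads = 1)$predictions
      as.numeric(pr[, "ASD"])
    }
  )
}

glmnet_posterior_asd <- function(model, x) {
  p_second <- as.numeric(stats::predict(model, x, type = "response"))
  if (model$classnames[2] == "ASD") p_second else 1 - p_second
}

#' Record-wise cross-validation folds
#'
#' Each fold receives the same number of records from every subject, drawn at
#' random within subject, so records of one individual appear in both the
#' training and the test side of every split.
#'
#' @param ds feature dataset.
#' @param k fold count; must divide the per-subject record count (10 or 40 in
#'   the full design).
#' @return a `fold_assignment`: list with `scheme`, `k` and integer `fold`
#'   per record.
#' @export
record_wise_folds <- function(ds, k) {
  counts <- table(ds$subject)
  n_rec <- unique(as.integer(counts))
  if (length(n_rec) != 1) stop("all subjects must have equal record counts")
  if (n_rec %% k != 0) {
    stop("k = ", k, " does not divide the per-subject record count ", n_rec)
  }
  fold <- integer(nrow(ds))
  for (s in names(counts)) {
    idx <- which(ds$subject == s)
    fold[idx] <- sample(rep(seq_len(k), each = n_rec / k))
  }
  structure(list(scheme = "record-wise", k = k, fold = fold),
            class = "fold_assignment")
}

#' Record-wise folds balanced by intention
#'
#' Each fold holds the same number of movements per (subject, intention)
#' cell — one each in the 10-fold, 600-record intention design.
#'
#' @param ds feature dataset (typically one diagnostic group).
#' @param k fold count; must divide every (subject, intention) cell count.
#' @return a `fold_assignment`.
#' @export
record_wise_intention_folds <- function(ds, k = 10) {
  cell <- paste(ds$subject, ds$intention, sep = "\r")
  counts <- table(cell)
  n_cell <- unique(as.integer(counts))
  if (length(n_cell) != 1 || n_cell %% k != 0) {
    stop("unbalanced design: every (subject, intention) cell must hold a ",
         "multiple of k records")
  }
  fold <- integer(nrow(ds))
  for (cl in names(counts)) {
    idx <- which(cell == cl)
    fold[idx] <- sample(rep(seq_len(k), each = n_cell / k))
  }
  structure(list(scheme = "record-wise", k = k, fold = fold),
            class = "fold_assignment")
}

#' Subject-wise cross-validation folds
#'
#' All records of a subject share one fold, so training and test folds
#' contain records from different subjects. Default is leave-one-subject-out
#' (one fold per subject); with `k` set, subjects are dealt into `k`
#' group-balanced folds (ASD:TD ratio within one subject per fold).
#'
#' @param ds feature dataset.
#' @param k fold count, or NULL for LOSO.
#' @return a `fold_assignment`.
#' @export
subject_wise_folds <- function(ds, k = NULL) {
  subjects <- unique(ds$subject)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  if (is.null(k) || k == length(subjects)) {
    fold <- match(ds$subject, subjects)
    return(structure(list(scheme = "subject-wise", k = length(subjects),
                          fold = fold), class = "fold_assignment"))
  }
  if (k > length(subjects)) stop("k exceeds the number of subjects")
  sg <- ds$group[match(subjects, ds$subject)]
  sfold <- integer(length(subjects))
  for (g in unique(sg)) {
    idx <- sample(which(sg == g))
    sfold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold <- sfold[match(ds$subject, subjects)]
  structure(list(scheme = "subject-wise", k = k, fold = fold),
            class = "fold_assignment")
}

#' Tune hyper-parameters on inner folds and fit the final model
#'
#' Standardizes features with training statistics only, evaluates every grid
#' point by mean record-level accuracy over the inner folds (train on all but
#' one inner fold, test on the remaining one, recursively), picks the best —
#' ties resolve to the lowest-complexity candidate — and refits on the full
#' training set.
#'
#' @param x training feature matrix (raw scale).
#' @param y training labels (factor).
#' @param spec a `model_spec`.
#' @param inner_fold integer vector assigning each training record to an
#'   inner fold; ignored for single-row grids.
#' @return fitted model: list with `scaler`, `model`, `params`, `family`,
#'   `levels`.
#' @export
tune_and_train <- function(x, y, spec, inner_fold = NULL) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training data contain a single class")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  grid <- spec$grid
  best <- 1L
  if (nrow(grid) > 1) {
    if (is.null(inner_fold)) stop("inner folds required to tune a grid")
    accs <- vapply(seq_len(nrow(grid)), function(gi) {
      params <- as.list(grid[gi, , drop = FALSE])
      mean(vapply(unique(inner_fold), function(f) {
        tr <- inner_fold != f
        if (nlevels(droplevels(y[tr])) < 2) return(NA_real_)
        m <- fit_one(spec$family, xs[tr, , drop = FALSE], droplevels(y[tr]),
                     params, spec$num_trees)
        mean(predict_labels(spec$family, m, xs[!tr, , drop = FALSE]) ==
               as.character(y[!tr]))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    best <- which.max(accs)  # grid is complexity-ordered; first max wins
  }
  params <- as.list(grid[best, , drop = FALSE])
  model <- fit_one(spec$family, xs, y, params, spec$num_trees)
  structure(list(scaler = scaler, model = model, params = params,
                 family = spec$family, levels = levels(y)),
            class = "reachcv_model")
}

#' Predict per-record posterior scores (P(ASD)) or class labels
#'
#' @param fit a fitted `reachcv_model`.
#' @param x feature matrix on the raw scale.
#' @return for binary group tasks, numeric posteriors in `[0, 1]` with 1 =
#'   ASD; multiclass models return class labels via [predict_classes()].
#' @export
predict_posteriors <- function(fit, x) {
  if (ncol(x) != length(fit$scaler$mu)) {
    stop("feature length mismatch: model expects ", length(fit$scaler$mu),
         ", got ", ncol(x))
  }
  if (length(fit$levels) != 2) {
    stop("posterior scores are defined for binary tasks; use predict_classes")
  }
  xs <- apply_scaler(fit$scaler, x)
  if (fit$family == "svmlasso") return(glmnet_posterior_asd(fit$model, xs))
  predict_posterior(fit$family, fit$model, xs)
}

#' Predict class labels
#' @param fit a fitted `reachcv_model`.
#' @param x feature matrix on the raw scale.
#' @return character vector of predicted labels.
#' @export
predict_classes <- function(fit, x) {
  if (ncol(x) != length(fit$scaler$mu)) {
    stop("feature length mismatch: model expects ", length(fit$scaler$mu),
         ", got ", ncol(x))
  }
  xs <- apply_scaler(fit$scaler, x)
  predict_labels(fit$family, fit$model, xs, fit$levels)
}

#' Aggregate record posteriors into a subject-level group call
#'
#' The subject's group is ASD when the mean posterior exceeds 0.5 and TD
#' otherwise; an exact tie goes to TD (deterministic, conservative toward
#' non-diagnosis).
#'
#' @param posteriors posteriors of one subject's records.
#' @return `"ASD"` or `"TD"`.
#' @export
aggregate_subject <- function(posteriors) {
  if (length(posteriors) == 0) stop("no posteriors to aggregate")
  if (mean(posteriors) > 0.5) "ASD" else "TD"
}

#' Subject-level accuracy, sensitivity and specificity
#'
#' Accuracy is the fraction of correctly classified subjects; sensitivity the
#' fraction of ASD cases classified ASD among all ASD cases; specificity the
#' fraction of TD cases classified TD among all TD cases.
#'
#' @param predictions named character vector (names = subjects).
#' @param truth named character vector of true groups covering the same
#'   subjects.
#' @return list with `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_subject_level <- function(predictions, truth) {
  unknown <- setdiff(names(predictions), names(truth))
  if (length(unknown) > 0) {
    stop("unknown subject(s) in predictions: ", paste(unknown, collapse = ", "))
  }
  truth <- truth[names(predictions)]
  correct <- predictions == truth
  list(accuracy = mean(correct),
       sensitivity = mean(correct[truth == "ASD"]),
       specificity = mean(correct[truth == "TD"]))
}

## Inner fold assignment for the training portion of an outer fold. For
## record-wise and k-fold subject-wise schemes the remaining outer folds are
## reused as inner folds (tune on all but one, test on the remaining one).
## For LOSO, inner LOSO would multiply cost ~40x for no statistical gain, so
## training subjects are dealt into 5 group-balanced subject-wise folds.
inner_fold_for <- function(ds, folds, outer, train_idx) {
  if (folds$scheme == "subject-wise" &&
      folds$k == length(unique(ds$subject))) {
    sub <- ds[train_idx, ]
    subject_wise_folds(sub, k = min(5L, length(unique(sub$subject))))$fold
  } else {
    match(folds$fold[train_idx], setdiff(sort(unique(folds$fold)), outer))
  }
}

#' Run a full cross-validation pass
#'
#' For each fold: tune and train on the remaining folds (inner splitter of
#' the same scheme), predict the held-out records, then aggregate each
#' subject's held-out posteriors into a group call. Metrics are subject-level
#' for binary group tasks and record-level for multiclass tasks; bootstrap
#' SEMs accompany both.
#'
#' @param ds feature dataset.
#' @param folds a `fold_assignment` consistent with `ds`.
#' @param spec a `model_spec`.
#' @param label column holding the class label (default `group`).
#' @param seed integer seed (model fits and bootstrap).
#' @param eval_folds optional integer vector of fold ids to evaluate; the
#'   remaining folds still contribute training records but are not scored.
#'   Each fold's held-out accuracy has the same marginal distribution as in
#'   a full pass, so metrics stay unbiased; used to keep permutation nulls
#'   of leave-one-subject-out runs tractable.
#' @return a `cv_result`: records tibble (truth, prediction, posterior,
#'   fold), `fold_accuracy`, `subject_predictions`, `metrics`,
#'   `chosen_params`, `scheme`, `seed`.
#' @export
run_cv <- function(ds, folds, spec, label = "group", seed = 1L,
                   eval_folds = NULL) {
  stopifnot(inherits(folds, "fold_assignment"),
            length(folds$fold) == nrow(ds))
  set.seed(seed)
  x <- feature_matrix(ds)
  yc <- as.character(ds[[label]])
  lv <- if (label == "group") GROUP_LEVELS else sort(unique(yc))
  y <- factor(yc, levels = lv)
  binary <- nlevels(y) == 2 && label == "group"
  pred <- rep(NA_character_, nrow(ds))
  post <- rep(NA_real_, nrow(ds))
  chosen <- list()
  if (is.null(eval_folds)) eval_folds <- sort(unique(folds$fold))
  keep <- folds$fold %in% eval_folds
  for (f in sort(eval_folds)) {
    test <- folds$fold == f
    train <- !test
    inner <- inner_fold_for(ds, folds, f, which(train))
    fit <- tune_and_train(x[train, , drop = FALSE], y[train], spec,
                          inner_fold = inner)
    chosen[[as.character(f)]] <- fit$params
    if (binary) {
      post[test] <- predict_posteriors(fit, x[test, , drop = FALSE])
      pred[test] <- ifelse(post[test] > 0.5, "ASD", "TD")
    } else {
      pred[test] <- predict_classes(fit, x[test, , drop = FALSE])
    }
  }
  records <- tibble::tibble(subject = ds$subject[keep], truth = yc[keep],
                            prediction = pred[keep], posterior = post[keep],
                            fold = folds$fold[keep])
  fold_acc <- tapply(records$prediction == records$truth, records$fold, mean)
  out <- list(records = records,
              fold_accuracy = as.numeric(fold_acc),
              scheme = folds$scheme, k = folds$k,
              chosen_params = chosen, label = label, seed = seed)
  if (binary) {
    subj_post <- tapply(records$posterior, records$subject, mean)
    subj_pred <- vapply(split(records$posterior, records$subject),
                        aggregate_subject, "")
    truth_s <- tapply(records$truth, records$subject, function(v) v[1])
    m <- evaluate_subject_level(subj_pred, truth_s)
    correct_s <- subj_pred == truth_s[names(subj_pred)]
    m$accuracy_sem <- bootstrap_sem(as.numeric(correct_s), seed = seed)
    out$subject_predictions <- tibble::tibble(
      subject = names(subj_pred), truth = as.character(truth_s[names(subj_pred)]),
      prediction = as.character(subj_pred),
      mean_posterior = as.numeric(subj_post[names(subj_pred)]))
    out$metrics <- m
  } else {
    out$metrics <- list(
      accuracy = mean(records$prediction == records$truth),
      accuracy_sem = bootstrap_sem(as.numeric(fold_acc), seed = seed))
  }
  structure(out, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s (k = %d), %s task: accuracy %.3f\n",
              x$scheme, x$k, x$label, x$metrics$accuracy))
  invisible(x)
}
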