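# Fold construction, nested tuning, posterior aggregation and the
# record-wise/subject-wise dissociation on feature-space toys.

test_that("record-wise folds balance records per subject and partition exactly", {
  ds <- toy_features(n_per_group = 20, n_records = 40, seed = 1)
  set.seed(1)
  f10 <- record_wise_folds(ds, 10)
  expect_identical(sort(unique(f10$fold)), 1:10)
  per_fold <- table(f10$fold)
  expect_true(all(per_fold == 160))  # 4 records x 40 subjects
  per_cell <- table(ds$subject, f10$fold)
  expect_true(all(per_cell == 4))

  f40 <- record_wise_folds(ds, 40)
  expect_true(all(table(ds$subject, f40$fold) == 1))
  expect_identical(length(f40$fold), nrow(ds))  # exact partition

  expect_error(record_wise_folds(ds, 7), "does not divide")
})

test_that("intention-balanced folds hold one movement per subject per intention", {
  ds <- toy_intention_features(n_subjects = 20, n_trials = 10, seed = 2)
  set.seed(2)
  f <- record_wise_intention_folds(ds, k = 10)
  expect_true(all(table(f$fold) == 60))
  cell <- table(paste(ds$subject, ds$intention), f$fold)
  expect_true(all(cell == 1))
  expect_true(all(table(ds$subject, f$fold) == 3))

  tiny <- toy_intention_features(n_subjects = 2, n_trials = 2, seed = 3)
  set.seed(3)
  f2 <- record_wise_intention_folds(tiny, k = 2)
  expect_true(all(table(f2$fold) == 6))
  expect_true(all(table(paste(tiny$subject, tiny$intention), f2$fold) == 1))

  expect_error(record_wise_intention_folds(tiny, k = 4), "unbalanced")
})

test_that("subject-wise folds never split a subject and balance groups", {
  ds <- toy_features(n_per_group = 4, n_records = 5, seed = 4)
  loso <- subject_wise_folds(ds)
  expect_identical(loso$k, 8L)
  expect_true(all(tapply(loso$fold, ds$subject,
                         function(v) length(unique(v))) == 1))

  set.seed(4)
  f4 <- subject_wise_folds(ds, k = 4)
  grp_fold <- table(ds$group[!duplicated(ds$subject)],
                    f4$fold[!duplicated(ds$subject)])
  expect_true(all(grp_fold == 1))  # 1 ASD + 1 TD subject per fold

  expect_error(subject_wise_folds(ds, k = 9), "exceeds")
})

test_that("tuning maximizes inner-fold accuracy with a complexity tie-break", {
  ds <- toy_features(n_per_group = 4, n_records = 5, subject_sep = 0,
                     group_sep = 30, seed = 5)
  x <- as.matrix(ds[, feature_names()])
  y <- factor(ds$group, levels = c("ASD", "TD"))

  # single-point grid: that point is selected, no inner folds needed
  fit1 <- tune_and_train(x, y, model_spec_reduced())
  expect_equal(fit1$params$cost, 1)

  # separable toy: training accuracy 1.0
  expect_identical(predict_classes(fit1, x), as.character(y))

  # independent oracle: exhaustively evaluate the inner CV per grid point
  # with libsvm directly and check the tuner picks the argmax
  grid <- data.frame(cost = 1, gamma = c(1e-4, 0.02, 100))
  spec <- model_spec("svmg", grid = grid)
  set.seed(5)
  inner <- sample(rep(1:4, length.out = nrow(ds)))
  fit <- tune_and_train(x, y, spec, inner_fold = inner)
  mu <- colMeans(x); sdv <- apply(x, 2, sd)
  xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  oracle <- sapply(grid$gamma, function(g) {
    mean(sapply(1:4, function(f) {
      m <- e1071::svm(xs[inner != f, ], y[inner != f], kernel = "radial",
                      cost = 1, gamma = g, scale = FALSE)
      mean(predict(m, xs[inner == f, ]) == y[inner == f])
    }))
  })
  # tie-break: smallest gamma among the maximizers
  expect_equal(fit$params$gamma,
               grid$gamma[grid$gamma == min(grid$gamma[oracle == max(oracle)])])

  expect_error(tune_and_train(x, factor(rep("ASD", nrow(x))), spec),
               "single class")
})

test_that("posterior scores are oriented toward ASD and complement to 1", {
  ds <- toy_features(n_per_group = 6, n_records = 6, subject_sep = 0,
                     group_sep = 30, seed = 6)
  x <- as.matrix(ds[, feature_names()])
  y <- factor(ds$group, levels = c("ASD", "TD"))
  for (fam in c("svmg", "svmlasso", "rf")) {
    fit <- tune_and_train(x, y, model_spec_reduced(fam))
    p <- predict_posteriors(fit, x)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(mean(p[y == "ASD"]) > 0.5)
    expect_true(mean(p[y == "TD"]) < 0.5)
    # duplicate records receive identical posteriors
    expect_identical(p[1], predict_posteriors(fit, x[1, , drop = FALSE]))
  }
  fit <- tune_and_train(x, y, model_spec_reduced())
  expect_error(predict_posteriors(fit, x[, 1:10]), "feature length mismatch")
})

test_that("subject aggregation averages posteriors with ties going to TD", {
  expect_identical(aggregate_subject(c(0.9, 0.8, 0.7)), "ASD")
  expect_identical(aggregate_subject(c(0.5, 0.5)), "TD")
  expect_identical(aggregate_subject(c(rep(0.6, 30), rep(0.1, 10))), "TD")
  expect_error(aggregate_subject(numeric(0)), "no posteriors")
})

test_that("subject-level metrics follow the sensitivity/specificity definitions", {
  truth <- setNames(rep(c("ASD", "TD"), each = 20), sprintf("S%02d", 1:40))
  all_right <- evaluate_subject_level(truth, truth)
  expect_equal(unlist(all_right), c(accuracy = 1, sensitivity = 1,
                                    specificity = 1))
  pred <- truth
  pred[c(1:5, 21:25)] <- rev(c("ASD", "TD"))[match(pred[c(1:5, 21:25)],
                                                   c("ASD", "TD"))]
  m <- evaluate_subject_level(pred, truth)
  expect_equal(unlist(m), c(accuracy = 0.75, sensitivity = 0.75,
                            specificity = 0.75))
  all_asd <- setNames(rep("ASD", 40), names(truth))
  m2 <- evaluate_subject_level(all_asd, truth)
  expect_equal(unlist(m2), c(accuracy = 0.5, sensitivity = 1, specificity = 0))
  expect_error(evaluate_subject_level(c(S99 = "ASD"), truth), "unknown subject")
})

test_that("standardization and tuning see only training records", {
  ds <- toy_features(n_per_group = 4, n_records = 6, seed = 7)
  x <- as.matrix(ds[, feature_names()])
  y <- factor(ds$group, levels = c("ASD", "TD"))
  tr <- seq_len(30)
  fit <- tune_and_train(x[tr, ], y[tr], model_spec_reduced())
  expect_equal(fit$scaler$mu, colMeans(x[tr, ]))
  # perturbing held-out records cannot change the fitted model's predictions
  # on a fixed probe
  probe <- x[31:34, ]
  p1 <- predict_posteriors(fit, probe)
  fit2 <- tune_and_train(x[tr, ], y[tr], model_spec_reduced())
  expect_identical(p1, predict_posteriors(fit2, probe))
})

test_that("run_cv is deterministic and dissociates record-wise from subject-wise", {
  # identity-signature toys with zero group effect: record-wise succeeds via
  # subject signatures, subject-wise cannot beat chance
  diffs <- sapply(1:8, function(i) {
    ds <- toy_features(n_per_group = 5, n_records = 8, subject_sep = 3,
                       group_sep = 0, within_sd = 0.3, seed = 100 + i)
    set.seed(i)
    rw <- run_cv(ds, record_wise_folds(ds, 4), model_spec_reduced(), seed = i)
    sw <- run_cv(ds, subject_wise_folds(ds), model_spec_reduced(), seed = i)
    rw$metrics$accuracy - sw$metrics$accuracy
  })
  expect_gte(mean(diffs), 0.3)

  # strong group effect, no subject signature: the schemes agree
  agree <- sapply(1:4, function(i) {
    ds <- toy_features(n_per_group = 5, n_records = 8, subject_sep = 0,
                       group_sep = 30, seed = 200 + i)
    set.seed(i)
    rw <- run_cv(ds, record_wise_folds(ds, 4), model_spec_reduced(), seed = i)
    sw <- run_cv(ds, subject_wise_folds(ds), model_spec_reduced(), seed = i)
    abs(rw$metrics$accuracy - sw$metrics$accuracy)
  })
  expect_true(all(agree <= 0.1))

  ds <- toy_features(n_per_group = 4, n_records = 4, seed = 300)
  set.seed(9); f <- record_wise_folds(ds, 4)
  a <- run_cv(ds, f, model_spec_reduced(), seed = 9)
  b <- run_cv(ds, f, model_spec_reduced(), seed = 9)
  expect_identical(a$records, b$records)
})
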