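# Permutation schemes, p-value conventions and the identity-confounding
# diagnostics.

test_that("subject-block permutation relabels subjects as units", {
  ds <- toy_features(n_per_group = 5, n_records = 4, seed = 1)
  set.seed(1)
  perm <- block_permute_labels(ds)
  # one label per subject, counts preserved, features untouched
  expect_true(all(tapply(perm$group, perm$subject,
                         function(v) length(unique(v))) == 1))
  sub_lab <- perm$group[!duplicated(perm$subject)]
  expect_identical(sum(sub_lab == "ASD"), 5L)
  expect_identical(sum(sub_lab == "TD"), 5L)
  expect_identical(perm[, feature_names()], ds[, feature_names()])

  # 2 subjects: both assignments occur with frequency ~1/2
  tiny <- toy_features(n_per_group = 1, n_records = 3, seed = 2)
  set.seed(2)
  first <- replicate(1000, block_permute_labels(tiny)$group[1])
  expect_lt(abs(mean(first == "ASD") - 0.5), 0.05)

  bad <- ds
  bad$group[1] <- "TD"
  expect_error(block_permute_labels(bad), "constant within subject")
})

test_that("record-level permutation breaks the subject-label association", {
  ds <- toy_features(n_per_group = 4, n_records = 10, seed = 3)
  set.seed(3)
  perm <- record_permute_labels(ds)
  expect_identical(sort(perm$group), sort(ds$group))
  set.seed(7); a <- record_permute_labels(ds)
  set.seed(7); b <- record_permute_labels(ds)
  expect_identical(a$group, b$group)

  # chi-square statistic of subject x label near its null expectation
  set.seed(4)
  stats <- replicate(200, {
    p <- record_permute_labels(ds)
    suppressWarnings(chisq.test(table(p$subject, p$group))$statistic)
  })
  df <- (8 - 1) * (2 - 1)
  expect_lt(abs(mean(stats) - df) / df, 0.35)
})

test_that("permutation p-values use the add-one convention", {
  expect_equal(perm_pvalue(0.2, rep(0.5, 100)), 1)
  expect_equal(perm_pvalue(0.9, rep(0.5, 100)), 1 / 101)
  null <- c(rep(0.4, 90), rep(0.8, 10))
  expect_equal(perm_pvalue(0.7, null), 11 / 101)
})

test_that("permutation_test recomputes CV accuracy under matched relabelling", {
  ds <- toy_features(n_per_group = 4, n_records = 6, subject_sep = 0,
                     group_sep = 30, seed = 5)
  set.seed(5)
  folds <- subject_wise_folds(ds, k = 4)
  pr <- permutation_test(ds, folds, model_spec_reduced(),
                         scheme = "subject-block", n_perm = 19, seed = 5)
  expect_length(pr$null, 19)
  expect_true(all(pr$null >= 0 & pr$null <= 1))
  expect_equal(pr$observed, 1)          # separable group effect
  # block permutations occasionally resemble the true labelling, so a few
  # null draws can also reach 1; the add-one convention must hold exactly
  expect_equal(pr$p_value, perm_pvalue(pr$observed, pr$null))
  expect_lte(pr$p_value, 3 / 20)
  expect_error(permutation_test(ds, folds, model_spec_reduced(), n_perm = 0),
               "n_perm")
})

test_that("identity classification is perfect on duplicated records and near chance after shuffling", {
  # zero within-subject noise: every record equals its subject centroid
  ds <- toy_features(n_per_group = 4, n_records = 6, within_sd = 0, seed = 6)
  id <- identity_classification(ds, model_spec_reduced(), k = 3, seed = 6)
  expect_equal(id$metrics$accuracy, 1)

  # shuffled identities: record-level accuracy within a binomial band of 1/8
  shuf <- ds
  set.seed(8)
  shuf[, feature_names()] <- shuf[sample(nrow(shuf)), feature_names()]
  id0 <- identity_classification(shuf, model_spec_reduced(), k = 3, seed = 8)
  n <- nrow(ds)
  band <- 3 * sqrt((1 / 8) * (7 / 8) / n)
  expect_lt(id0$metrics$accuracy, 1 / 8 + band + 0.1)

  one_rec <- ds[!duplicated(ds$subject), ]
  expect_error(identity_classification(one_rec, k = 2), "at least 2 records")
})

test_that("hybrid CV never shows the outer test subject to tuning and is seeded", {
  ds <- toy_features(n_per_group = 3, n_records = 10, subject_sep = 0,
                     group_sep = 20, seed = 7)
  h1 <- hybrid_cv(ds, model_spec_reduced(), tuning = "record", seed = 7)
  h2 <- hybrid_cv(ds, model_spec_reduced(), tuning = "record", seed = 7)
  expect_identical(h1$records, h2$records)
  # with a pure group effect and no subject signature the two tuning schemes
  # agree on unseen subjects
  hs <- hybrid_cv(ds, model_spec_reduced(), tuning = "subject", seed = 7)
  expect_lte(abs(h1$metrics$accuracy - hs$metrics$accuracy), 0.1)
  # leakage check: perturbing one subject's features changes only that
  # subject's outer fold (models for other folds trained without it are
  # unaffected only if the subject is excluded — here we assert the
  # held-out predictions exist for every subject exactly once)
  expect_identical(sort(unique(h1$records$subject)),
                   sort(unique(ds$subject)))
  expect_true(all(table(h1$subject_predictions$subject) == 1))
})

test_that("confounding report flags above-chance nulls and genuine group signal", {
  mk <- function(obs, null, cv_scheme) {
    structure(list(observed = obs, null = null, perm_scheme = "subject-block",
                   cv_scheme = cv_scheme, p_value = perm_pvalue(obs, null),
                   n_perm = length(null), seed = 1),
              class = "permutation_result")
  }
  set.seed(9)
  # confounded, no group signal: record-wise null sits at 0.75
  rec <- mk(0.76, rnorm(100, 0.75, 0.02), "record-wise")
  sub <- mk(0.55, rnorm(100, 0.5, 0.05), "subject-wise")
  rep1 <- confounding_report(rec, sub)
  expect_true(rep1$confounded)
  expect_false(rep1$group_signal_record)

  # clean null at 0.5 with clear signal
  rec2 <- mk(0.75, rnorm(100, 0.5, 0.03), "record-wise")
  sub2 <- mk(0.75, rnorm(100, 0.5, 0.05), "subject-wise")
  rep2 <- confounding_report(rec2, sub2)
  expect_false(rep2$confounded)
  expect_true(rep2$group_signal_record)
  expect_true(rep2$group_signal_subject)

  # degenerate: observed equals a flat null at exactly 0.5
  rec3 <- mk(0.5, rep(0.5, 100), "record-wise")
  sub3 <- mk(0.5, rep(0.5, 100), "subject-wise")
  rep3 <- confounding_report(rec3, sub3)
  expect_false(rep3$confounded)
  expect_false(rep3$group_signal_record)

  expect_error(confounding_report(sub, rec), "scheme mismatch")
})
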