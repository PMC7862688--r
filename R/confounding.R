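## Identity-confounding diagnostics.
##
## The key manipulation is the subject-block permutation: diagnostic labels
## are shuffled across subjects as blocks, so every record of a subject keeps
## one (permuted) label. This preserves the identity-label confound while
## destroying any label-feature relationship; a record-wise permutation null
## sitting above the 0.5 chance level therefore diagnoses identity
## confounding. Record-level permutation breaks both associations and is the
## matched null for intention tasks.

#' Permute diagnostic labels subject-as-block
#'
#' The multiset of subject-level labels is uniformly permuted across subjects
#' (group sizes preserved); all records of a subject share the permuted
#' label; feature rows and identity-record structure are untouched.
#'
#' @param ds feature dataset with group constant within subject.
#' @param label label column (default `group`).
#' @return relabelled copy of `ds`.
#' @export
block_permute_labels <- function(ds, label = "group") {
  subjects <- unique(ds$subject)
  lab_s <- vapply(subjects, function(s) {
    v <- unique(ds[[label]][ds$subject == s])
    if (length(v) != 1) {
      stop("label must be constant within subject; violated by ", s)
    }
    v
  }, character(1))
  perm <- sample(lab_s)
  ds[[label]] <- perm[match(ds$subject, subjects)]
  ds
}

#' Permute labels across individual records
#'
#' Uniform permutation of the label column over all records, breaking both
#' the group and the identity association while preserving label counts.
#'
#' @param ds feature dataset.
#' @param label label column to permute.
#' @return relabelled copy of `ds`.
#' @export
record_permute_labels <- function(ds, label = "group") {
  if (nrow(ds) == 0) return(ds)
  ds[[label]] <- sample(ds[[label]])
  ds
}

#' Add-one permutation p-value
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`; guaranteed positive,
#' one-sided against the null of no class information.
#'
#' @param observed observed statistic.
#' @param null numeric null distribution.
#' @return p-value in (0, 1].
#' @export
perm_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Permutation test of cross-validated classification accuracy
#'
#' The observed statistic is the cross-validated accuracy on the true labels
#' (subject-level for group tasks, record-level otherwise). The null
#' distribution re-runs the identical cross-validation on `n_perm`
#' relabelled datasets: subject-as-block relabelling for group tasks (both
#' record-wise confounding diagnosis and subject-wise inference) and
#' record-level relabelling for intention-style tasks.
#'
#' @param ds feature dataset.
#' @param folds a `fold_assignment` (reused across permutations; fold
#'   structure does not depend on labels).
#' @param spec a `model_spec` (a reduced grid keeps 100 re-fits tractable).
#' @param scheme `subject-block` or `record-level` relabelling.
#' @param n_perm number of permutations (default 100).
#' @param label label column (default `group`).
#' @param seed integer seed.
#' @param eval_folds_per_perm optional: number of outer folds scored per null
#'   permutation (a fresh random subset each time; the observed statistic
#'   always uses the full pass). Per-fold held-out accuracies are exchangeable
#'   across folds, so the null mean is unchanged in expectation; this keeps
#'   100-permutation leave-one-subject-out nulls tractable on one CPU.
#' @return a `permutation_result`: `observed`, `null`, `perm_scheme`,
#'   `cv_scheme`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(ds, folds, spec,
                             scheme = c("subject-block", "record-level"),
                             n_perm = 100, label = "group", seed = 1L,
                             eval_folds_per_perm = NULL) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  statistic <- function(res) res$metrics$accuracy
  obs <- statistic(run_cv(ds, folds, spec, label = label, seed = seed))
  all_folds <- sort(unique(folds$fold))
  set.seed(seed + 1L)
  null <- vapply(seq_len(n_perm), function(i) {
    perm_ds <- if (scheme == "subject-block") {
      block_permute_labels(ds, label)
    } else {
      record_permute_labels(ds, label)
    }
    ev <- if (is.null(eval_folds_per_perm)) NULL else {
      sample(all_folds, min(eval_folds_per_perm, length(all_folds)))
    }
    fit_seed <- sample.int(2^30, 1)
    statistic(run_cv(perm_ds, folds, spec, label = label, seed = fit_seed,
                     eval_folds = ev))
  }, numeric(1))
  structure(list(observed = obs, null = null, perm_scheme = scheme,
                 cv_scheme = folds$scheme, k = folds$k,
                 p_value = perm_pvalue(obs, null),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s CV, %s null: observed %.3f, null mean %.3f, p = %.4f\n",
    x$cv_scheme, x$perm_scheme, x$observed, mean(x$null), x$p_value))
  invisible(x)
}

#' Subject-identity classification
#'
#' Relabels every record with its subject identity and runs multiclass
#' record-wise cross-validation; accuracy is the fraction of records assigned
#' to the correct subject (chance = 1/n_subjects). Near-ceiling accuracy
#' demonstrates that records carry a recoverable individual signature — the
#' raw material of identity confounding.
#'
#' @param ds feature dataset (every subject needs at least `k` records).
#' @param spec a `model_spec`; defaults to the reduced SVM-G.
#' @param k record-wise fold count (default 10).
#' @param seed integer seed.
#' @return a `cv_result` with record-level metrics.
#' @export
identity_classification <- function(ds, spec = model_spec_reduced(), k = 10,
                                    seed = 1L) {
  counts <- table(ds$subject)
  if (any(counts < 2)) {
    stop("record-wise folding requires at least 2 records per subject")
  }
  set.seed(seed)
  folds <- record_wise_folds(ds, k)
  run_cv(ds, folds, spec, label = "subject", seed = seed)
}

#' Hybrid cross-validation for unseen-subject prediction
#'
#' Outer loop: leave-one-subject-out, so the test subject is never seen in
#' training. Inner loop on the remaining subjects tunes hyper-parameters
#' either record-wise (the hybrid of interest: tuning still enjoys identity
#' leakage) or subject-wise (fully leakage-free), on identical outer folds.
#' The held-out subject is predicted from its averaged record posteriors.
#'
#' @param ds feature dataset.
#' @param spec a `model_spec`.
#' @param tuning `record` or `subject` inner tuning scheme.
#' @param seed integer seed.
#' @return a `cv_result`.
#' @export
hybrid_cv <- function(ds, spec, tuning = c("record", "subject"), seed = 1L) {
  tuning <- match.arg(tuning)
  subjects <- unique(ds$subject)
  if (length(subjects) < 3) stop("need at least 3 subjects")
  set.seed(seed)
  x <- feature_matrix(ds)
  y <- factor(as.character(ds$group), levels = GROUP_LEVELS)
  post <- rep(NA_real_, nrow(ds))
  fold <- match(ds$subject, subjects)
  for (i in seq_along(subjects)) {
    test <- fold == i
    tr_ds <- ds[!test, ]
    inner <- if (tuning == "record") {
      n_rec <- as.integer(table(tr_ds$subject))
      k_in <- if (length(unique(n_rec)) == 1 && unique(n_rec) %% 10 == 0)
        10L else min(unique(n_rec))
      record_wise_folds(tr_ds, k_in)$fold
    } else {
      subject_wise_folds(tr_ds, k = min(5L, length(subjects) - 1L))$fold
    }
    fit <- tune_and_train(x[!test, , drop = FALSE], y[!test], spec,
                          inner_fold = inner)
    post[test] <- predict_posteriors(fit, x[test, , drop = FALSE])
  }
  records <- tibble::tibble(subject = ds$subject,
                            truth = as.character(ds$group),
                            prediction = ifelse(post > 0.5, "ASD", "TD"),
                            posterior = post, fold = fold)
  subj_pred <- vapply(split(post, ds$subject), aggregate_subject, "")
  truth_s <- tapply(as.character(ds$group), ds$subject, function(v) v[1])
  m <- evaluate_subject_level(subj_pred, truth_s)
  correct_s <- subj_pred == truth_s[names(subj_pred)]
  m$accuracy_sem <- bootstrap_sem(as.numeric(correct_s), seed = seed)
  structure(list(records = records,
                 fold_accuracy = as.numeric(
                   tapply(records$prediction == records$truth, fold, mean)),
                 subject_predictions = tibble::tibble(
                   subject = names(subj_pred),
                   truth = as.character(truth_s[names(subj_pred)]),
                   prediction = as.character(subj_pred)),
                 metrics = m, scheme = paste0("hybrid-", tuning, "-tuned"),
                 k = length(subjects), label = "group", seed = seed),
            class = "cv_result")
}

#' Identity-confounding diagnostic report
#'
#' Combines the record-wise and subject-wise permutation results on the same
#' data and model. Identity confounding is flagged when the record-wise null
#' mean exceeds the 0.5 chance level (one-sample t test, alpha = 0.05);
#' genuine group information is flagged when the observed accuracy exceeds
#' its scheme-matched null (permutation p <= 0.05).
#'
#' @param record_perm `permutation_result` from record-wise CV.
#' @param subject_perm `permutation_result` from subject-wise CV.
#' @param alpha significance level (default 0.05).
#' @return list with `confounded`, `null_mean_record`, `null_mean_subject`,
#'   `group_signal_record`, `group_signal_subject`, and the test p-values.
#' @export
confounding_report <- function(record_perm, subject_perm, alpha = 0.05) {
  stopifnot(inherits(record_perm, "permutation_result"),
            inherits(subject_perm, "permutation_result"))
  if (record_perm$cv_scheme != "record-wise" ||
      subject_perm$cv_scheme != "subject-wise") {
    stop("scheme mismatch: expected a record-wise and a subject-wise result")
  }
  null_rw <- record_perm$null
  conf_p <- if (stats::sd(null_rw) == 0) {
    if (mean(null_rw) > 0.5) 0 else 1
  } else {
    stats::t.test(null_rw, mu = 0.5, alternative = "greater")$p.value
  }
  list(
    confounded = conf_p < alpha,
    confounding_p = conf_p,
    null_mean_record = mean(null_rw),
    null_mean_subject = mean(subject_perm$null),
    group_signal_record = record_perm$p_value <= alpha,
    group_signal_subject = subject_perm$p_value <= alpha,
    p_record = record_perm$p_value,
    p_subject = subject_perm$p_value
  )
}
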