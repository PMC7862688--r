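## End-to-end experiment drivers and small reporting statistics.

#' Two-tailed exact paired sign test
#'
#' Ties are discarded; the p-value is the exact two-tailed binomial tail for
#' the number of positive differences under P = 0.5. All ties give p = 1.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list with `p_value`, `n_pairs` (after tie removal), `n_positive`.
#' @export
sign_test <- function(a, b) {
  if (length(a) == 0 || length(a) != length(b)) {
    stop("sign test needs paired vectors of equal, positive length")
  }
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(p_value = 1, n_pairs = 0L, n_positive = 0L))
  s <- sum(d > 0)
  list(p_value = stats::binom.test(s, n, p = 0.5)$p.value,
       n_pairs = n, n_positive = s)
}

#' Bootstrap standard error of the mean
#'
#' SD of `n_boot` resampled means.
#'
#' @param values numeric vector.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return scalar SEM.
#' @export
bootstrap_sem <- function(values, n_boot = 1000, seed = NULL) {
  n <- length(values)
  if (n == 0) stop("cannot bootstrap an empty vector")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  if (stats::sd(values) == 0 || n == 1) return(0)
  stats::sd(vapply(seq_len(n_boot),
                   function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                   numeric(1)))
}

#' Group summary statistics
#' @param mean,sd,n group mean, SD and size.
#' @return a `summary_stats` list.
#' @export
summary_stats <- function(mean, sd, n) {
  if (sd < 0) stop("SD must be non-negative")
  if (n < 2) stop("n must be at least 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

#' Equal-variance two-sample t statistic from group summaries
#'
#' Pooled-variance t with `df = n_a + n_b - 2`, the test used for group
#' matching on demographics reported as mean and SD.
#'
#' @param a,b `summary_stats` objects.
#' @return list with `t`, `df`, `p_value` (two-tailed).
#' @export
pooled_t <- function(a, b) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  diff <- a$mean - b$mean
  if (sp2 == 0) {
    if (diff == 0) return(list(t = 0, df = df, p_value = 1))
    warning("zero pooled variance with nonzero mean difference")
    return(list(t = sign(diff) * Inf, df = df, p_value = 0))
  }
  t <- diff / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Equate pass trials and assemble one group's intention-task dataset
#'
#' Randomly keeps `keep` trials per pass block per subject so the three
#' intentions contribute equally (default 5, giving 20 subjects x 10 trials
#' x 3 intentions = 600 records in the full design). Uses the current RNG
#' state.
#'
#' @param ds feature dataset restricted to one group.
#' @param keep pass trials kept per block per subject (default 5).
#' @return subsampled feature dataset.
#' @export
equate_pass_trials <- function(ds, keep = 5) {
  drop <- logical(nrow(ds))
  for (s in unique(ds$subject)) {
    for (b in c("pass1", "pass2")) {
      idx <- which(ds$subject == s & ds$block == b)
      if (length(idx) < keep) stop("insufficient pass trials for ", s)
      if (length(idx) > keep) {
        drop[sample(idx, length(idx) - keep)] <- TRUE
      }
    }
  }
  ds[!drop, ]
}

#' Intention classification within one diagnostic group
#'
#' Equates pass trials (5 per block), builds intention-balanced record-wise
#' folds (one movement per subject per intention per fold at the default
#' design), runs 3-class cross-validation and a record-level permutation
#' null. Accuracy is the fraction of correctly classified trials.
#'
#' @param ds full feature dataset.
#' @param group `ASD` or `TD`.
#' @param spec a `model_spec`.
#' @param k fold count (default 10).
#' @param n_perm permutations for the null (default 100).
#' @param seed integer seed.
#' @return list with `cv` (`cv_result`) and `perm` (`permutation_result`).
#' @export
run_intention_experiment <- function(ds, group, spec = model_spec_reduced(),
                                     k = 10, n_perm = 100, seed = 1L) {
  stopifnot(group %in% GROUP_LEVELS)
  set.seed(seed)
  sub <- equate_pass_trials(ds[ds$group == group, ])
  folds <- record_wise_intention_folds(sub, k = k)
  cv <- run_cv(sub, folds, spec, label = "intention", seed = seed)
  perm <- permutation_test(sub, folds, spec, scheme = "record-level",
                           n_perm = n_perm, label = "intention", seed = seed)
  list(cv = cv, perm = perm, n_records = nrow(sub))
}

#' Group classification under record-wise and subject-wise schemes
#'
#' Runs record-wise 10-fold, record-wise 40-fold (when the per-subject record
#' count allows) and subject-wise LOSO cross-validation for each model
#' family, and compares schemes with two-tailed paired sign tests on
#' per-subject correctness.
#'
#' @param ds full feature dataset.
#' @param specs named list of `model_spec`s (default SVM-G only).
#' @param seed integer seed.
#' @return list with `results` (nested `cv_result`s by family and scheme) and
#'   `comparisons` (sign tests record-wise 10-fold vs subject-wise).
#' @export
run_group_experiment <- function(ds, specs = list(svmg = model_spec("svmg")),
                                 seed = 1L) {
  set.seed(seed)
  n_rec <- unique(as.integer(table(ds$subject)))
  results <- list()
  comparisons <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    r10 <- run_cv(ds, record_wise_folds(ds, 10), spec, seed = seed)
    r40 <- if (length(n_rec) == 1 && n_rec %% 40 == 0) {
      run_cv(ds, record_wise_folds(ds, 40), spec, seed = seed)
    } else NULL
    sw <- run_cv(ds, subject_wise_folds(ds), spec, seed = seed)
    results[[nm]] <- list(record10 = r10, record40 = r40, subject = sw)
    cr <- subject_correct(r10)
    cs <- subject_correct(sw)
    comparisons[[nm]] <- sign_test(cr[sort(names(cr))], cs[sort(names(cs))])
  }
  list(results = results, comparisons = comparisons)
}

subject_correct <- function(cv) {
  sp <- cv$subject_predictions
  stats::setNames(as.numeric(sp$prediction == sp$truth), sp$subject)
}

#' Learning curve: accuracy versus training-set size
#'
#' For each training size `s` and repeat, draws `s` training subjects
#' group-balanced (draws are nested across sizes within a repeat) and tests
#' on the held-out subjects. The subject-wise variant trains only on the `s`
#' subjects' records. The record-wise variant additionally places all but
#' `holdout_records` records of every test subject in the training pool and
#' scores the remaining held-out records — the regime in which classifiers
#' have seen the test subjects' other movements.
#'
#' @param ds full feature dataset.
#' @param sizes training-set sizes (default 4, 10, 20, 39).
#' @param repeats random draws per size (default 20).
#' @param spec a `model_spec`.
#' @param holdout_records test-subject records held out in the record-wise
#'   variant (default 4, one 10-fold-worth).
#' @param seed integer seed.
#' @return tibble: size, repeat, scheme, subject-level accuracy.
#' @export
run_learning_curve <- function(ds, sizes = c(4, 10, 20, 39), repeats = 20,
                               spec = model_spec_reduced(),
                               holdout_records = 4, seed = 1L) {
  subjects <- unique(ds$subject)
  n_sub <- length(subjects)
  if (any(sizes > n_sub - 1)) stop("sizes must leave at least one test subject")
  set.seed(seed)
  sg <- ds$group[match(subjects, ds$subject)]
  x <- feature_matrix(ds)
  y <- factor(as.character(ds$group), levels = GROUP_LEVELS)
  out <- list()
  draws <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    # one balanced subject order per repeat; size-s training set = first s
    # entries, so smaller sets are nested inside larger ones
    ord_asd <- sample(subjects[sg == "ASD"])
    ord_td <- sample(subjects[sg == "TD"])
    interleave <- as.vector(rbind(ord_asd, ord_td))
    draws[[r]] <- interleave
    for (s in sizes) {
      train_subj <- interleave[seq_len(s)]
      test_subj <- setdiff(subjects, train_subj)
      for (scheme in c("subject-wise", "record-wise")) {
        tr <- ds$subject %in% train_subj
        te <- !tr
        if (scheme == "record-wise") {
          # move most of each test subject's records into the training pool
          for (ts in test_subj) {
            idx <- which(ds$subject == ts)
            keep_out <- sample(idx, min(holdout_records, length(idx)))
            tr[setdiff(idx, keep_out)] <- TRUE
            te[idx] <- FALSE
            te[keep_out] <- TRUE
          }
        }
        fit <- tune_and_train(x[tr, , drop = FALSE], y[tr], spec,
                              inner_fold = if (nrow(spec$grid) > 1)
                                sample(rep(1:5, length.out = sum(tr))) else NULL)
        post <- predict_posteriors(fit, x[te, , drop = FALSE])
        subj_pred <- vapply(split(post, ds$subject[te]), aggregate_subject, "")
        truth_s <- tapply(as.character(ds$group[te]), ds$subject[te],
                          function(v) v[1])
        acc <- mean(subj_pred == truth_s[names(subj_pred)])
        out[[length(out) + 1]] <- data.frame(
          size = s, rep = r, scheme = scheme, accuracy = acc)
      }
    }
  }
  res <- tibble::as_tibble(do.call(rbind, out))
  attr(res, "draws") <- draws  # per-repeat subject order; size-s set = prefix
  res
}

#' Per-intention group classification
#'
#' Predicts diagnostic group separately from grasp-to-place, grasp-to-pour
#' and grasp-to-pass movements (both pass blocks kept), each with
#' subject-wise LOSO cross-validation and a subject-block permutation
#' p-value.
#'
#' @param ds full feature dataset.
#' @param spec a `model_spec`.
#' @param n_perm permutations per intention (default 100).
#' @param seed integer seed.
#' @return named list per intention: `cv`, `perm`, `n_records`.
#' @export
run_intention_specific <- function(ds, spec = model_spec_reduced(),
                                   n_perm = 100, seed = 1L) {
  out <- list()
  for (intn in INTENTION_LEVELS) {
    sub <- ds[ds$intention == intn, ]
    if (nrow(sub) == 0) stop("no records for intention ", intn)
    folds <- subject_wise_folds(sub)
    cv <- run_cv(sub, folds, spec, seed = seed)
    perm <- permutation_test(sub, folds, spec, scheme = "subject-block",
                             n_perm = n_perm, seed = seed)
    out[[intn]] <- list(cv = cv, perm = perm, n_records = nrow(sub))
  }
  out
}
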