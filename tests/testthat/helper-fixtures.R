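# Shared fixtures, generated once per test run and memoised. Sizes are the
# package's scaled-down study designs (see the methods vignette).

FX <- new.env(parent = emptyenv())

fx_memo <- function(name, builder) {
  if (is.null(FX[[name]])) FX[[name]] <- builder()
  FX[[name]]
}

# full study design: 40 subjects x 4 blocks x 10 trials, identity-signature
# regime with the default small group timing shift
fx_full <- function() {
  fx_memo("full", function() {
    generate_dataset(generator_config(seed = 101), keep_trajectories = FALSE)
  })
}

# same design with the group effect switched off (pure identity confound)
fx_full_null <- function() {
  fx_memo("full_null", function() {
    generate_dataset(generator_config(group_timing_shift = 0, seed = 102),
                     keep_trajectories = FALSE)
  })
}

# reduced design for permutation-heavy checks: 20 subjects x 4 blocks x 5
# trials = 400 movements
fx_medium <- function() {
  fx_memo("medium", function() {
    generate_dataset(generator_config(n_per_group = 10, trials_per_block = 5,
                                      seed = 103),
                     keep_trajectories = FALSE)$features
  })
}

# noise-free minimum-jerk reference trial (no warp, no jitter)
fx_minjerk_trial <- function() {
  fx_memo("minjerk", function() {
    cfg <- generator_config(n_per_group = 1, subject_sd = 0, trial_sd = 0,
                            measurement_noise_mm = 0, group_timing_shift = 0,
                            seed = 104)
    set.seed(104)
    sub <- sample_subjects(cfg)
    list(trial = generate_trial(sub[1, ], "place", cfg), config = cfg,
         subject = sub)
  })
}

# feature-space toy datasets: Gaussian subject clusters with optional group
# separation, bypassing the kinematics pipeline (fast CV mechanics tests)
toy_features <- function(n_per_group = 5, n_records = 8, subject_sep = 3,
                         group_sep = 0, within_sd = 1, seed = 1) {
  set.seed(seed)
  n_sub <- 2 * n_per_group
  subjects <- sprintf("T%02d", seq_len(n_sub))
  group <- rep(c("ASD", "TD"), each = n_per_group)
  cen <- matrix(rnorm(n_sub * 50, sd = subject_sep), n_sub, 50)
  cen[group == "ASD", ] <- cen[group == "ASD", ] + group_sep / sqrt(50)
  idx <- rep(seq_len(n_sub), each = n_records)
  x <- cen[idx, ] + matrix(rnorm(n_sub * n_records * 50, sd = within_sd),
                           n_sub * n_records, 50)
  colnames(x) <- feature_names()
  blocks <- rep_len(c("place", "pour", "pass1", "pass2"), n_records)
  ds <- tibble::tibble(subject = subjects[idx], group = group[idx],
                       block = rep(blocks, n_sub),
                       trial = rep(seq_len(n_records), n_sub),
                       intention = block_intention(rep(blocks, n_sub)))
  tibble::as_tibble(cbind(ds, as.data.frame(x)))
}

# balanced intention-task toy: n_trials records per (subject, intention)
toy_intention_features <- function(n_subjects = 2, n_trials = 2, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(trial = seq_len(n_trials),
                      intention = c("place", "pour", "pass"),
                      subject = sprintf("T%02d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  x <- matrix(rnorm(nrow(rows) * 50), nrow(rows), 50)
  colnames(x) <- feature_names()
  ds <- tibble::tibble(
    subject = rows$subject, group = "TD",
    block = ifelse(rows$intention == "pass", "pass1", rows$intention),
    trial = rows$trial, intention = rows$intention)
  tibble::as_tibble(cbind(ds, as.data.frame(x)))
}
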