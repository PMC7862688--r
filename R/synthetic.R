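## Synthetic reach-to-grasp generator.
##
## The wrist transport is a minimum-jerk reach with a landmark time-warp:
## along-track position is  d * pbeta(tau, a, b)  with a = 1 + 4*pf,
## b = 5 - 4*pf, so tangential speed is (d/T) * dbeta(tau, a, b), a
## bell-shaped profile peaking at fraction pf of movement duration. At
## pf = 0.5 this is exactly the minimum-jerk speed profile
## 30 (d/T) tau^2 (1-tau)^2 with peak 15 d / (8 T) at mid-movement — a free
## closed-form oracle. Grip aperture and wrist height follow beta-shaped
## arcs. Subject identity is a vector of random effects on the generative
## parameters (consistent within, different between individuals); the
## diagnostic-group effect shifts the timing of the wrist-velocity landmark;
## intentions modulate duration, peak aperture, and landmark timing.

GEN_PARAMS <- c("duration", "amplitude", "peak_frac", "aperture_peak",
                "aperture_rest", "height_peak", "aperture_frac")

## Population means and base between-subject SDs, chosen to resemble
## children's reach-to-grasp at a 44 cm target (durations about a second,
## peak speeds near 800 mm/s, apertures near 90 mm). The rest aperture is a
## postural signature (hand size / habitual finger posture).
GEN_MEANS <- c(duration = 1.0, amplitude = 440, peak_frac = 0.5,
               aperture_peak = 90, aperture_rest = 30, height_peak = 60,
               aperture_frac = 0.75)
GEN_BASE_SD <- c(duration = 0.10, amplitude = 20, peak_frac = 0.03,
                 aperture_peak = 6, aperture_rest = 3, height_peak = 8,
                 aperture_frac = 0.02)

## Intention modulation is deliberately subtle: in the study population the
## prospective intention is decodable only modestly above chance from the
## reach, while individual signatures support near-perfect identity
## decoding. Offsets are a fraction of the between-subject SDs.
default_intention_effects <- function() {
  list(
    place = c(duration = 0.00, aperture_peak = 0, peak_frac = 0.00),
    pour  = c(duration = 0.03, aperture_peak = 2, peak_frac = -0.01),
    pass  = c(duration = -0.02, aperture_peak = 1, peak_frac = 0.01)
  )
}

#' Configuration of the synthetic reach-to-grasp generator
#'
#' Defaults reproduce the study design this package analyses: 20 subjects per
#' diagnostic group, 4 blocks (place, pour, pass x2) of 10 trials, a 440 mm
#' reach sampled at 100 Hz, strong per-subject kinematic signatures
#' (between-subject parameter SD 10x the trial-to-trial SD), and a small
#' group effect that delays the wrist peak-velocity landmark of the ASD-like
#' group by a fraction of movement duration.
#'
#' @param n_per_group subjects per group (default 20).
#' @param trials_per_block trials in each of the 4 blocks (default 10).
#' @param reach_amplitude reach distance in mm (default 440).
#' @param mean_duration mean movement duration in s (default 1).
#' @param group_timing_shift fraction of duration by which ASD-like
#'   peak-velocity landmarks occur later; scalar, or named vector over
#'   intentions (`place`, `pour`, `pass`) for intention-specific effects.
#'   Default 0.05.
#' @param intention_effects named list of per-intention offsets on
#'   `duration` (s), `aperture_peak` (mm) and `peak_frac`.
#' @param subject_sd multiplier on the base between-subject SDs (the identity
#'   signature; default 1).
#' @param trial_sd multiplier on the base SDs for trial-to-trial variation
#'   (default 0.1).
#' @param measurement_noise_mm isotropic marker jitter SD (default 0.5).
#' @param fs_hz sampling rate (default 100).
#' @param rest_pad_s stationary padding before and after the movement so
#'   onset/offset detection is exercised (default 0.3).
#' @param seed integer seed.
#' @return a `generator_config` list; `$param_sd` holds the effective
#'   per-parameter between-subject SDs, `$trial_param_sd` the within-subject
#'   ones.
#' @export
generator_config <- function(n_per_group = 20, trials_per_block = 10,
                             reach_amplitude = 440, mean_duration = 1.0,
                             group_timing_shift = 0.05,
                             intention_effects = default_intention_effects(),
                             subject_sd = 1.0, trial_sd = 0.1,
                             measurement_noise_mm = 0.5, fs_hz = 100,
                             rest_pad_s = 0.3, seed = 1L) {
  if (subject_sd < 0 || trial_sd < 0 || measurement_noise_mm < 0) {
    stop("standard deviations must be non-negative")
  }
  if (trials_per_block < 1) stop("trials_per_block must be >= 1")
  if (any(abs(group_timing_shift) >= 0.3)) {
    stop("group_timing_shift must lie in (-0.3, 0.3)")
  }
  if (is.null(names(group_timing_shift))) {
    group_timing_shift <- stats::setNames(rep(group_timing_shift[1], 3),
                                          INTENTION_LEVELS)
  }
  stopifnot(all(INTENTION_LEVELS %in% names(group_timing_shift)),
            all(INTENTION_LEVELS %in% names(intention_effects)))
  means <- GEN_MEANS
  means["amplitude"] <- reach_amplitude
  means["duration"] <- mean_duration
  structure(list(
    n_per_group = as.integer(n_per_group),
    blocks = BLOCK_LEVELS,
    trials_per_block = as.integer(trials_per_block),
    means = means,
    param_sd = subject_sd * GEN_BASE_SD,
    trial_param_sd = trial_sd * GEN_BASE_SD,
    group_timing_shift = group_timing_shift,
    intention_effects = intention_effects,
    measurement_noise_mm = measurement_noise_mm,
    fs_hz = fs_hz,
    rest_pad_s = rest_pad_s,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Draw per-subject generative parameters
#'
#' Each subject's parameter vector is the population mean plus an independent
#' Gaussian random effect per parameter — the idiosyncratic movement
#' signature. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param config a `generator_config`.
#' @return tibble with `subject`, `group` and one column per generative
#'   parameter.
#' @export
sample_subjects <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- 2L * config$n_per_group
  ids <- sprintf("S%02d", seq_len(n))
  group <- rep(GROUP_LEVELS, each = config$n_per_group)
  par <- sapply(GEN_PARAMS, function(p) {
    config$means[[p]] + stats::rnorm(n, 0, config$param_sd[[p]])
  })
  par <- as.data.frame(par)
  if (any(par$duration <= 0) || any(par$amplitude <= 0)) {
    stop("degenerate subject parameters (non-positive duration/amplitude); ",
         "reduce subject_sd")
  }
  tibble::as_tibble(cbind(data.frame(subject = ids, group = group,
                                     stringsAsFactors = FALSE), par))
}

## Beta-shape helpers: speed-profile exponents from the peak fraction
## (concentration fixed at a+b = 6, the minimum-jerk value).
beta_shape <- function(peak_frac) {
  c(a = 1 + 4 * peak_frac, b = 5 - 4 * peak_frac)
}

#' Generate one synthetic reach-to-grasp trial
#'
#' Builds the wrist path (time-warped minimum-jerk transport along +x with a
#' beta-shaped vertical arc), drives the thumb/index-tip separation with a
#' beta-shaped aperture curve, places the remaining markers rigidly around
#' the wrist, adds stationary rest padding and i.i.d. Gaussian marker jitter.
#' Uses the current RNG state.
#'
#' @param subject one row of [sample_subjects()] output.
#' @param intention `place`, `pour` or `pass`.
#' @param config a `generator_config`.
#' @param block block label stored in the metadata (default derived from
#'   intention).
#' @param trial trial number.
#' @return a `trial_trajectory`.
#' @export
generate_trial <- function(subject, intention, config,
                           block = c(place = "place", pour = "pour",
                                     pass = "pass1")[[intention]],
                           trial = 1L) {
  stopifnot(inherits(config, "generator_config"),
            intention %in% INTENTION_LEVELS)
  p <- stats::setNames(unlist(subject[1, GEN_PARAMS]), GEN_PARAMS)
  # trial-to-trial jitter on every generative parameter
  p <- p + stats::rnorm(length(p), 0, config$trial_param_sd[GEN_PARAMS])
  eff <- config$intention_effects[[intention]]
  eff_of <- function(nm) if (nm %in% names(eff)) eff[[nm]] else 0
  p["duration"] <- p["duration"] + eff_of("duration")
  p["aperture_peak"] <- p["aperture_peak"] + eff_of("aperture_peak")
  p["peak_frac"] <- p["peak_frac"] + eff_of("peak_frac")
  if (subject$group[1] == "ASD") {
    p["peak_frac"] <- p["peak_frac"] + config$group_timing_shift[[intention]]
  }
  # guard rails against extreme random draws
  p["duration"] <- max(p["duration"], 0.3)
  p["amplitude"] <- max(p["amplitude"], 100)
  p["peak_frac"] <- min(max(p["peak_frac"], 0.2), 0.8)
  p["aperture_frac"] <- min(max(p["aperture_frac"], 0.3), 0.9)
  p["aperture_rest"] <- max(p["aperture_rest"], 10)
  p["aperture_peak"] <- max(p["aperture_peak"], p["aperture_rest"] + 10)

  fs <- config$fs_hz
  n_pad <- round(config$rest_pad_s * fs)
  n_mov <- round(p["duration"] * fs)
  tau <- seq_len(n_mov) / n_mov
  sh <- beta_shape(p[["peak_frac"]])
  along <- p[["amplitude"]] * stats::pbeta(tau, sh["a"], sh["b"])
  hsh <- beta_shape(0.5)
  height <- p[["height_peak"]] *
    stats::dbeta(tau, hsh["a"], hsh["b"]) / stats::dbeta(0.5, hsh["a"], hsh["b"])
  ash <- beta_shape(p[["aperture_frac"]])
  ap_rest <- p[["aperture_rest"]]
  ap <- ap_rest + (p[["aperture_peak"]] - ap_rest) *
    stats::dbeta(tau, ash["a"], ash["b"]) /
    stats::dbeta(p[["aperture_frac"]], ash["a"], ash["b"])

  along <- c(rep(0, n_pad), along, rep(p[["amplitude"]], n_pad))
  height <- c(rep(0, n_pad), height, rep(height[n_mov], n_pad))
  ap <- c(rep(ap_rest, n_pad), ap, rep(ap[n_mov], n_pad))
  nf <- length(along)
  wrist <- cbind(along, 0, height)

  offsets <- list(
    wrist = c(0, 0, 0), dorsum = c(40, 0, 15), hand_ref = c(20, -15, 10),
    index_mcp = c(70, 25, 5), little_mcp = c(60, -35, 5),
    little_tip = c(95, -40, 0)
  )
  grasp_centre <- sweep(wrist, 2, c(90, 0, -10), `+`)
  markers <- lapply(offsets, function(o) sweep(wrist, 2, o, `+`))
  markers$thumb <- grasp_centre + cbind(0, -ap / 2, 0)
  markers$index_tip <- grasp_centre + cbind(0, ap / 2, 0)
  if (config$measurement_noise_mm > 0) {
    markers <- lapply(markers, function(m) {
      m + matrix(stats::rnorm(nf * 3, 0, config$measurement_noise_mm), nf, 3)
    })
  }
  markers <- lapply(markers, function(m) { dimnames(m) <- NULL; m })
  as_trial_trajectory(markers, subject$subject[1], subject$group[1], block,
                      trial, fs)
}

#' Generate a full synthetic dataset
#'
#' Full factorial subjects x blocks x trials at the configured design
#' (default 40 x 4 x 10 = 1600 movements), with features extracted through
#' the kinematics pipeline. Fully reproducible from `config$seed`.
#'
#' @param config a `generator_config`.
#' @param keep_trajectories keep the marker-level trials (default TRUE; set
#'   FALSE to save memory when only features are needed).
#' @return list with `subjects` (parameter tibble), `trajectories` (list of
#'   `trial_trajectory` or NULL) and `features` (feature tibble).
#' @export
generate_dataset <- function(config, keep_trajectories = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  subjects <- sample_subjects(config)
  trials <- vector("list",
                   nrow(subjects) * length(config$blocks) * config$trials_per_block)
  i <- 0L
  for (s in seq_len(nrow(subjects))) {
    for (b in config$blocks) {
      for (tr in seq_len(config$trials_per_block)) {
        i <- i + 1L
        trials[[i]] <- generate_trial(subjects[s, ], block_intention(b),
                                      config, block = b, trial = tr)
      }
    }
  }
  features <- extract_features(trials)
  list(subjects = subjects,
       trajectories = if (keep_trajectories) trials else NULL,
       features = features)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
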