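#' @keywords internal
"_PACKAGE"

## Marker set carried by the hand model: metacarpal joint and tip of index and
## little finger, trapezium bone of the thumb, radial wrist, hand dorsum, plus
## a reference marker on the back of the hand.
MARKER_NAMES <- c(
  "index_mcp", "index_tip", "little_mcp", "little_tip",
  "thumb", "wrist", "dorsum", "hand_ref"
)

GROUP_LEVELS <- c("ASD", "TD")
BLOCK_LEVELS <- c("place", "pour", "pass1", "pass2")
INTENTION_LEVELS <- c("place", "pour", "pass")

#' Map a block label to its prospective-intention label
#'
#' The two grasp-to-pass blocks share a single intention label.
#'
#' @param block character vector of block labels (`place`, `pour`, `pass1`,
#'   `pass2`).
#' @return character vector of intention labels (`place`, `pour`, `pass`).
#' @export
block_intention <- function(block) {
  bad <- setdiff(unique(block), BLOCK_LEVELS)
  if (length(bad) > 0) {
    stop("unknown block label(s): ", paste(bad, collapse = ", "))
  }
  ifelse(block %in% c("pass1", "pass2"), "pass", block)
}

## Second-order low-pass Butterworth, applied forward and backward
## (zero-phase). Edges are handled scipy-style: odd-reflection padding plus
## steady-state initialization, so a constant series passes through exactly.
FILT_PADLEN <- 9L

butter_coefs <- function(cutoff_hz, fs_hz) {
  if (fs_hz <= 2 * cutoff_hz) {
    stop("sampling rate must exceed twice the cutoff (fs = ", fs_hz,
         ", cutoff = ", cutoff_hz, ")")
  }
  signal::butter(2, W = cutoff_hz / (fs_hz / 2), type = "low")
}

## Single causal pass with steady-state initial conditions: filtering the
## deviation from the first sample with zero state and adding the first sample
## back is exact because the DC gain is 1.
filt_ss <- function(bf, x) {
  as.numeric(signal::filter(bf, x - x[1])) + x[1]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Second-order Butterworth run forward and backward over the series (nominal
#' cutoff, no dual-pass correction — standard motion-analysis practice).
#' Edge transients are controlled by odd-reflection padding with steady-state
#' filter initialization, so the DC component is preserved exactly.
#'
#' @param x numeric vector, or a matrix whose columns are filtered
#'   independently.
#' @param cutoff_hz low-pass cutoff in Hz (default 6).
#' @param fs_hz sampling rate in Hz (default 100).
#' @return filtered series, same shape as `x`.
#' @export
lowpass_filter <- function(x, cutoff_hz = 6, fs_hz = 100) {
  if (is.matrix(x)) {
    return(apply(x, 2, lowpass_filter, cutoff_hz = cutoff_hz, fs_hz = fs_hz))
  }
  n <- length(x)
  if (n < 3 * FILT_PADLEN) {
    stop("series too short to filter: need at least ", 3 * FILT_PADLEN,
         " samples, got ", n)
  }
  if (anyNA(x)) stop("series contains NA; fill gaps before filtering")
  bf <- butter_coefs(cutoff_hz, fs_hz)
  p <- FILT_PADLEN
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- filt_ss(bf, ext)
  y <- rev(filt_ss(bf, rev(y)))
  y[(p + 1):(p + n)]
}

## Central differences with one-sided differences at the ends.
finite_diff <- function(x, fs_hz) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples to differentiate")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * fs_hz
  d[n] <- (x[n] - x[n - 1]) * fs_hz
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs_hz / 2
  d
}

#' Wrist speed, acceleration and jerk from a 3D position series
#'
#' Speed is the magnitude of the first time-derivative of 3D position
#' (tangential speed, mm/s); acceleration and jerk are the first and second
#' time-derivatives of speed (mm/s^2, mm/s^3). Derivatives use central
#' differences on the (already filtered) input, one-sided at the ends, so all
#' series have the input length.
#'
#' @param xyz numeric matrix, frames x 3, positions in mm.
#' @param fs_hz sampling rate in Hz.
#' @return list with numeric vectors `speed`, `acceleration`, `jerk`.
#' @export
kinematic_derivatives <- function(xyz, fs_hz = 100) {
  if (!is.matrix(xyz) || ncol(xyz) != 3) stop("xyz must be a frames x 3 matrix")
  if (nrow(xyz) < 5) stop("need at least 5 frames, got ", nrow(xyz))
  v <- apply(xyz, 2, finite_diff, fs_hz = fs_hz)
  speed <- sqrt(rowSums(v^2))
  acceleration <- finite_diff(speed, fs_hz)
  jerk <- finite_diff(acceleration, fs_hz)
  list(speed = speed, acceleration = acceleration, jerk = jerk)
}

#' Grip aperture series
#'
#' Per-frame Euclidean distance between the thumb (trapezium) and index-tip
#' markers, the classic grasp pre-shaping variable.
#'
#' @param thumb_xyz,index_tip_xyz frames x 3 matrices, mm.
#' @return non-negative numeric vector, mm.
#' @export
grip_aperture <- function(thumb_xyz, index_tip_xyz) {
  if (!all(dim(thumb_xyz) == dim(index_tip_xyz))) {
    stop("thumb and index-tip series must have identical dimensions")
  }
  sqrt(rowSums((thumb_xyz - index_tip_xyz)^2))
}

#' Detect reach onset and offset from a speed series
#'
#' Onset is the first frame of the principal movement — the suprathreshold
#' run containing the global speed peak, which must stay above `threshold`
#' for at least `sustain_s`; offset is the first subsequent frame where speed
#' falls to or below `threshold` for at least `sustain_s` (object contact).
#' Anchoring on the peak-containing run rather than the first sustained run
#' makes the rule robust to brief suprathreshold noise at the series edges.
#' Frames are 0-based, matching the trajectory frame clock.
#'
#' @param speed numeric vector, mm/s, computed on filtered data.
#' @param fs_hz sampling rate in Hz.
#' @param threshold speed threshold in mm/s (default 20).
#' @param sustain_s minimum time above/below threshold in seconds
#'   (default 0.05).
#' @return list with integers `onset` and `offset` (0-based frames).
#' @export
detect_bounds <- function(speed, fs_hz = 100, threshold = 20,
                          sustain_s = 0.05) {
  m <- max(1L, as.integer(round(sustain_s * fs_hz)))
  above <- speed > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peak <- which.max(speed)
  peak_run <- which(starts <= peak & ends >= peak)
  if (!r$values[peak_run] || r$lengths[peak_run] < m) {
    stop("no movement detected: speed never exceeds ", threshold,
         " mm/s for ", sustain_s, " s")
  }
  onset_idx <- starts[peak_run]
  off_runs <- which(!r$values & r$lengths >= m & starts > onset_idx)
  if (length(off_runs) == 0) {
    stop("no offset: speed never returns below ", threshold, " mm/s for ",
         sustain_s, " s after onset")
  }
  offset_idx <- starts[off_runs[1]]
  list(onset = onset_idx - 1L, offset = offset_idx - 1L)
}

#' Sample a series at deciles of movement duration
#'
#' Linear interpolation of the series at times
#' `onset + p * (offset - onset)` for p = 0.1, 0.2, ..., 1.0.
#'
#' @param x numeric vector.
#' @param onset,offset 0-based frame bounds, `onset < offset`, both inside the
#'   series.
#' @param n_points number of normalized samples (default 10).
#' @return numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, onset, offset, n_points = 10) {
  n <- length(x)
  if (onset < 0 || offset > n - 1) stop("bounds outside series")
  if (onset >= offset) stop("onset must precede offset")
  p <- seq_len(n_points) / n_points
  idx <- onset + p * (offset - onset)
  stats::approx(x = 0:(n - 1), y = x, xout = idx)$y
}

## Fill interior NA gaps of at most `max_gap` frames by cubic (spline)
## interpolation; longer gaps or edge NAs are an error (such trials should
## have been excluded as poor reconstructions upstream).
fill_gaps <- function(mat, max_gap = 10L) {
  if (!anyNA(mat)) return(mat)
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    if (!anyNA(v)) next
    na <- is.na(v)
    if (na[1] || na[length(v)]) stop("gap at series edge cannot be filled")
    r <- rle(na)
    if (max(r$lengths[r$values]) > max_gap) {
      stop("marker gap longer than ", max_gap, " frames")
    }
    idx <- seq_along(v)
    mat[, j] <- stats::spline(idx[!na], v[!na], xout = idx, method = "fmm")$y
  }
  mat
}

#' Extract the five-variable kinematic profile of a trial
#'
#' Runs the full processing chain: gap-fill, zero-phase 6 Hz low-pass
#' filtering of marker positions, wrist speed/acceleration/jerk, grip aperture
#' (thumb to index tip), wrist height (vertical coordinate of the wrist
#' marker), onset/offset detection on wrist speed, and decile time
#' normalization of each variable.
#'
#' @param trial a `trial_trajectory` (see [as_trial_trajectory()]).
#' @param cutoff_hz filter cutoff in Hz (default 6).
#' @param onset_threshold onset/offset speed threshold, mm/s (default 20).
#' @param sustain_s sustain time for bound detection, s (default 0.05).
#' @return a `kinematic_profile`: list with length-10 numeric vectors
#'   `velocity`, `acceleration`, `jerk`, `aperture`, `height`, integers
#'   `onset_frame`, `offset_frame`, and the trial `meta` data.
#' @export
extract_profile <- function(trial, cutoff_hz = 6, onset_threshold = 20,
                            sustain_s = 0.05) {
  stopifnot(inherits(trial, "trial_trajectory"))
  fs <- trial$fs_hz
  res <- tryCatch({
    wrist <- lowpass_filter(fill_gaps(trial$markers$wrist), cutoff_hz, fs)
    thumb <- lowpass_filter(fill_gaps(trial$markers$thumb), cutoff_hz, fs)
    index <- lowpass_filter(fill_gaps(trial$markers$index_tip), cutoff_hz, fs)
    der <- kinematic_derivatives(wrist, fs)
    aperture <- grip_aperture(thumb, index)
    height <- wrist[, 3]
    b <- detect_bounds(der$speed, fs, threshold = onset_threshold,
                       sustain_s = sustain_s)
    norm10 <- function(x) time_normalize(x, b$onset, b$offset)
    structure(list(
      velocity = norm10(der$speed),
      acceleration = norm10(der$acceleration),
      jerk = norm10(der$jerk),
      aperture = norm10(aperture),
      height = norm10(height),
      onset_frame = b$onset,
      offset_frame = b$offset,
      meta = trial$meta
    ), class = "kinematic_profile")
  }, error = function(e) {
    stop("trial ", trial$meta$subject, "/", trial$meta$block, "/",
         trial$meta$trial, ": ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' Flatten a kinematic profile into the 50-element feature vector
#'
#' Concatenation order is fixed: velocity, acceleration, jerk, aperture,
#' height, each at 10%..100% of movement duration. Names are `f001`..`f050`.
#'
#' @param profile a `kinematic_profile`.
#' @return named numeric vector of length 50.
#' @export
flatten_profile <- function(profile) {
  stopifnot(inherits(profile, "kinematic_profile"))
  v <- c(profile$velocity, profile$acceleration, profile$jerk,
         profile$aperture, profile$height)
  names(v) <- feature_names()
  v
}

#' Feature column names (`f001`..`f050`)
#' @return character vector of length 50.
#' @export
feature_names <- function() sprintf("f%03d", 1:50)

#' Extract features for a collection of trials
#'
#' @param trials list of `trial_trajectory` objects.
#' @param ... passed to [extract_profile()].
#' @return a tibble with columns `subject`, `group`, `block`, `trial`,
#'   `intention`, `f001`..`f050` — the feature dataset all classification
#'   analyses operate on.
#' @export
extract_features <- function(trials, ...) {
  rows <- lapply(trials, function(tr) {
    pr <- extract_profile(tr, ...)
    m <- tr$meta
    c(list(subject = m$subject, group = m$group, block = m$block,
           trial = m$trial, intention = block_intention(m$block)),
      as.list(flatten_profile(pr)))
  })
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  })))
}

#' Fraction of movement duration at which wrist speed peaks
#'
#' Full-resolution diagnostic used to recover configured timing effects:
#' the peak-speed frame expressed as a fraction of the onset-offset interval.
#'
#' @param trial a `trial_trajectory`.
#' @param cutoff_hz,onset_threshold,sustain_s as in [extract_profile()].
#' @return scalar in (0, 1).
#' @export
peak_speed_fraction <- function(trial, cutoff_hz = 6, onset_threshold = 20,
                                sustain_s = 0.05) {
  stopifnot(inherits(trial, "trial_trajectory"))
  fs <- trial$fs_hz
  wrist <- lowpass_filter(fill_gaps(trial$markers$wrist), cutoff_hz, fs)
  der <- kinematic_derivatives(wrist, fs)
  b <- detect_bounds(der$speed, fs, threshold = onset_threshold,
                     sustain_s = sustain_s)
  seg <- der$speed[(b$onset + 1):(b$offset + 1)]
  (which.max(seg) - 1) / (b$offset - b$onset)
}
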