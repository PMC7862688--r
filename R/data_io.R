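## On-disk dialects.
## Trajectory CSV: comma-separated, UTF-8, one row per (frame, marker),
##   header exactly  subject,group,block,trial,frame,marker,x,y,z
##   coordinates in mm, right-handed lab frame, z vertical (up positive).
## Feature CSV: subject,group,block,trial,intention,f001..f050, features at
##   full double precision (17 significant digits).

TRAJ_HEADER <- c("subject", "group", "block", "trial", "frame", "marker",
                 "x", "y", "z")

#' Build a single-trial trajectory object
#'
#' @param markers named list of frames x 3 numeric matrices (mm), one per
#'   marker (index_mcp, index_tip, little_mcp, little_tip, thumb, wrist,
#'   dorsum, hand_ref); all with the same frame count.
#' @param subject,group,block,trial trial metadata; `group` is `ASD` or `TD`,
#'   `block` one of `place`, `pour`, `pass1`, `pass2`.
#' @param fs_hz sampling rate in Hz (default 100).
#' @return a `trial_trajectory` object.
#' @export
as_trial_trajectory <- function(markers, subject, group, block, trial,
                                fs_hz = 100) {
  stopifnot(is.list(markers), all(MARKER_NAMES %in% names(markers)))
  nf <- unique(vapply(markers, nrow, 1L))
  if (length(nf) != 1) stop("all markers must share one frame count")
  if (!group %in% GROUP_LEVELS) stop("unknown group: ", group)
  if (!block %in% BLOCK_LEVELS) stop("unknown block: ", block)
  structure(list(
    markers = markers[MARKER_NAMES],
    fs_hz = fs_hz,
    n_frames = nf,
    meta = list(subject = as.character(subject), group = group, block = block,
                trial = as.integer(trial),
                intention = block_intention(block))
  ), class = "trial_trajectory")
}

#' @export
print.trial_trajectory <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<trial_trajectory> %s %s %s trial %d: %d frames @ %g Hz\n",
              m$subject, m$group, m$block, m$trial, x$n_frames, x$fs_hz))
  invisible(x)
}

## Quality rule for "poor marker reconstruction": a trial is discarded when
## more than `max_missing_frac` of its frames lack any marker, or when any
## marker has a gap longer than `max_gap_ms`. Shorter gaps are filled by
## cubic interpolation.
trial_quality <- function(frame_grid, max_missing_frac = 0.10,
                          max_gap_ms = 100, fs_hz = 100) {
  missing <- is.na(frame_grid)          # frames x markers logical
  frac_missing <- mean(apply(missing, 1, any))
  max_gap <- 0L
  for (j in seq_len(ncol(missing))) {
    r <- rle(missing[, j])
    if (any(r$values)) max_gap <- max(max_gap, max(r$lengths[r$values]))
  }
  list(ok = frac_missing <= max_missing_frac &&
         max_gap * 1000 / fs_hz <= max_gap_ms,
       frac_missing = frac_missing, max_gap_frames = max_gap)
}

#' Read a trajectory CSV into trial objects
#'
#' Validates the dialect (header, marker/group/block vocabularies, frame
#' continuity), reconstructs one `trial_trajectory` per (subject, block,
#' trial), fills marker gaps up to 100 ms by cubic interpolation, and
#' discards trials with poor marker reconstruction (more than 10% of frames
#' missing any marker, or any gap over 100 ms). Nothing is dropped silently:
#' excluded trials are enumerated in the `exclusions` element.
#'
#' @param path CSV file path.
#' @param fs_hz sampling rate in Hz (default 100).
#' @return list with `trials` (list of `trial_trajectory`) and `exclusions`
#'   (tibble: subject, block, trial, reason).
#' @export
read_trajectories <- function(path, fs_hz = 100) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(TRAJ_HEADER, hdr)
  if (length(missing_cols) > 0) {
    stop("trajectory format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (!identical(hdr, TRAJ_HEADER)) {
    stop("trajectory format error: header must be exactly ",
         paste(TRAJ_HEADER, collapse = ","))
  }
  df <- utils::read.csv(path, colClasses = c(
    subject = "character", group = "character", block = "character",
    trial = "integer", frame = "integer", marker = "character",
    x = "numeric", y = "numeric", z = "numeric"), encoding = "UTF-8")
  bad_marker <- setdiff(unique(df$marker), MARKER_NAMES)
  if (length(bad_marker) > 0) {
    stop("trajectory format error: unknown marker name(s) ",
         paste(bad_marker, collapse = ", "))
  }
  bad_group <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad_group) > 0) {
    stop("trajectory format error: unknown group ",
         paste(bad_group, collapse = ", "))
  }
  bad_block <- setdiff(unique(df$block), BLOCK_LEVELS)
  if (length(bad_block) > 0) {
    stop("trajectory format error: unknown block ",
         paste(bad_block, collapse = ", "))
  }
  grp_per_subj <- tapply(df$group, df$subject, function(g) length(unique(g)))
  if (any(grp_per_subj > 1)) {
    stop("group must be constant within subject; violated by: ",
         paste(names(grp_per_subj)[grp_per_subj > 1], collapse = ", "))
  }

  key <- paste(df$subject, df$block, df$trial, sep = "\r")
  trials <- list()
  exclusions <- list()
  for (k in unique(key)) {
    d <- df[key == k, ]
    frames <- sort(unique(d$frame))
    if (!identical(frames, seq(0L, max(frames)))) {
      stop("frames of trial ", d$subject[1], "/", d$block[1], "/", d$trial[1],
           " are not consecutive from 0")
    }
    if (anyDuplicated(d[, c("frame", "marker")])) {
      stop("duplicate (frame, marker) rows in trial ", d$subject[1], "/",
           d$block[1], "/", d$trial[1])
    }
    nf <- length(frames)
    # frames x markers presence grid (NA = marker absent that frame)
    grid <- matrix(NA_real_, nf, length(MARKER_NAMES),
                   dimnames = list(NULL, MARKER_NAMES))
    midx <- match(d$marker, MARKER_NAMES)
    grid[cbind(d$frame + 1L, midx)] <- 0
    q <- trial_quality(grid, fs_hz = fs_hz)
    if (!q$ok) {
      exclusions[[length(exclusions) + 1]] <- data.frame(
        subject = d$subject[1], block = d$block[1], trial = d$trial[1],
        reason = sprintf(
          "poor reconstruction: %.0f%% frames incomplete, max gap %d frames",
          100 * q$frac_missing, q$max_gap_frames),
        stringsAsFactors = FALSE)
      next
    }
    markers <- lapply(MARKER_NAMES, function(mk) {
      dm <- d[d$marker == mk, ]
      mat <- matrix(NA_real_, nf, 3)
      mat[dm$frame + 1L, ] <- as.matrix(dm[, c("x", "y", "z")])
      fill_gaps(mat)
    })
    names(markers) <- MARKER_NAMES
    trials[[length(trials) + 1]] <- as_trial_trajectory(
      markers, d$subject[1], d$group[1], d$block[1], d$trial[1], fs_hz)
  }
  excl <- if (length(exclusions) > 0) {
    tibble::as_tibble(do.call(rbind, exclusions))
  } else {
    tibble::tibble(subject = character(), block = character(),
                   trial = integer(), reason = character())
  }
  list(trials = trials, exclusions = excl)
}

#' Write trial trajectories to the trajectory CSV dialect
#'
#' @param trials list of `trial_trajectory` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trials, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(TRAJ_HEADER, collapse = ","), con)
  for (tr in trials) {
    m <- tr$meta
    nf <- tr$n_frames
    for (mk in MARKER_NAMES) {
      xyz <- tr$markers[[mk]]
      writeLines(sprintf("%s,%s,%s,%d,%d,%s,%.17g,%.17g,%.17g",
                         m$subject, m$group, m$block, m$trial, 0:(nf - 1),
                         mk, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}

#' Write a feature dataset to CSV at full double precision
#'
#' Columns: `subject,group,block,trial,intention,f001..f050`; feature values
#' are written with 17 significant digits so the round trip is lossless.
#' Non-finite features are written as their IEEE sentinels (`NaN`, `Inf`).
#'
#' @param dataset feature tibble as produced by [extract_features()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(dataset, path) {
  fc <- feature_names()
  need <- c("subject", "group", "block", "trial", "intention", fc)
  missing_cols <- setdiff(need, names(dataset))
  if (length(missing_cols) > 0) {
    stop("feature format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(need, collapse = ","), con)
  if (nrow(dataset) > 0) {
    feat <- as.matrix(dataset[, fc])
    featc <- matrix(sprintf("%.17g", feat), nrow(feat), ncol(feat))
    lines <- paste(dataset$subject, dataset$group, dataset$block,
                   dataset$trial, dataset$intention,
                   apply(featc, 1, paste, collapse = ","), sep = ",")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a feature CSV
#'
#' Inverse of [write_features()]. Rows containing non-finite features are
#' preserved but flagged with a warning and recorded in the
#' `nonfinite_rows` attribute.
#'
#' @param path CSV file path.
#' @return feature tibble.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  need <- c("subject", "group", "block", "trial", "intention", feature_names())
  if (!identical(hdr, need)) {
    missing_cols <- setdiff(need, hdr)
    if (length(missing_cols) > 0) {
      stop("feature format error: missing column(s) ",
           paste(missing_cols, collapse = ", "))
    }
    stop("feature format error: unexpected header")
  }
  df <- utils::read.csv(path, colClasses = c(
    subject = "character", group = "character", block = "character",
    trial = "integer", intention = "character",
    stats::setNames(rep("numeric", 50), feature_names())))
  ds <- tibble::as_tibble(df)
  if (nrow(ds) > 0) {
    bad <- which(!apply(is.finite(as.matrix(ds[, feature_names()])), 1, all))
    if (length(bad) > 0) {
      warning(length(bad), " row(s) contain non-finite features")
      attr(ds, "nonfinite_rows") <- bad
    }
  }
  ds
}

#' Write a results bundle as JSON
#'
#' A results bundle is a named list of metrics, null distributions, per-fold
#' or per-subject predictions, the configuration echo and the seed. All
#' numeric leaves must be finite; metrics survive a round trip exactly
#' (written at full precision).
#'
#' @param bundle named list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(bundle, path) {
  check_finite <- function(x, nm) {
    if (is.list(x)) {
      for (i in seq_along(x)) {
        check_finite(x[[i]], paste0(nm, "$", names(x)[i] %||% i))
      }
    } else if (is.numeric(x) && length(x) > 0 && any(!is.finite(x))) {
      stop("non-finite metric in results bundle at ", nm)
    }
  }
  check_finite(bundle, "bundle")
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a results bundle written by [write_results()]
#' @param path JSON file path.
#' @return named list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
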