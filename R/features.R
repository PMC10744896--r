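# Personal-baseline calibration and the 94-features-per-window posture schema:
# original (RAW) window means, baseline-offset means, SD-interval status
# proportions, neck-normalized positions, and variation features.

.window_names <- c("whole", "typing", "gaming", "watching")

# Resolve a window given as 0..3 or by name; returns its name.
.window_name <- function(window) {
  if (is.numeric(window)) {
    stopifnot(window %in% 0:3)
    .window_names[window + 1]
  } else match.arg(window, .window_names)
}

# Kept frames falling in a window; hard error when QC emptied it.
window_frames <- function(recording, window) {
  wn <- .window_name(window)
  b <- recording$window_bounds[[wn]]
  fr <- recording$frames
  out <- fr[fr$frame >= b[1] & fr$frame < b[2], , drop = FALSE]
  if (nrow(out) == 0)
    stop("subject ", recording$subject_id, ": window '", wn,
         "' has no frames left after quality control")
  out
}

# Window SD. Sample SD (denominator n-1); a single-frame window has zero
# dispersion by convention.
.wsd <- function(v) {
  if (length(v) < 2) return(0)
  stats::sd(v)
}

#' Personal baseline from the first 10 seconds
#'
#' Subjects sit upright for the first 10 s of the recording; the mean of each
#' of the 15 raw pose quantities over the valid frames of that window is the
#' subject's personal baseline, used to calibrate away body size and camera
#' placement. Only frames that survived quality control contribute.
#'
#' @param recording a QC-passed [pose_recording()].
#' @param min_frames minimum valid baseline frames required (default 5).
#' @return Named numeric vector of length 15 (the baseline mean of each raw
#'   quantity), class `pose_baseline`.
#' @export
compute_baseline <- function(recording, min_frames = 5L) {
  stopifnot(inherits(recording, "pose_recording"))
  fr <- recording$frames
  base <- fr[fr$frame < recording$baseline_window[2], , drop = FALSE]
  if (nrow(base) < min_frames)
    stop("subject ", recording$subject_id, ": only ", nrow(base),
         " valid baseline frames (need >= ", min_frames, ")")
  out <- colMeans(base[.quantities])
  if (!all(is.finite(out)))
    stop("subject ", recording$subject_id, ": baseline contains missing values")
  structure(out, class = "pose_baseline")
}

#' Original pose features: per-window means of the 15 raw quantities
#'
#' @param recording a QC-passed [pose_recording()].
#' @param window 0..3 or `"whole"|"typing"|"gaming"|"watching"`.
#' @return Named numeric vector `RAW_<quantity>_AVG_<w>`, length 15.
#' @export
original_pose_features <- function(recording, window) {
  fr <- window_frames(recording, window)
  v <- colMeans(fr[.quantities])
  names(v) <- paste0("RAW_", .quantities, "_AVG_", .window_suffix(window))
  v
}

#' Offset pose features: baseline-subtracted window means
#'
#' Each frame's raw value minus the subject's baseline, averaged over the
#' window (equivalently, the window mean minus the baseline).
#'
#' @inheritParams original_pose_features
#' @param baseline a [compute_baseline()] result.
#' @return Named numeric vector `OFFSET_<quantity>_AVG_<w>`, length 15.
#' @export
offset_pose_features <- function(recording, baseline, window) {
  fr <- window_frames(recording, window)
  v <- colMeans(sweep(as.matrix(fr[.quantities]), 2, unclass(baseline)))
  names(v) <- paste0("OFFSET_", .quantities, "_AVG_", .window_suffix(window))
  v
}

#' Neck-normalized position features
#'
#' Coordinates re-expressed relative to the neck (origin moved to the neck
#' position in every frame) for the five non-neck keypoints, averaged over
#' the window; in a RAW variant and an OFFSET variant (baseline-relative
#' neck-normalized position subtracted).
#'
#' @inheritParams offset_pose_features
#' @return Named numeric vector of length 20 (`<pt>_<axis>_Mneck_<w>` and
#'   `OFFSET_<pt>_<axis>_Mneck_<w>`).
#' @export
normalized_position_features <- function(recording, baseline, window) {
  fr <- window_frames(recording, window)
  w <- .window_suffix(window)
  b <- unclass(baseline)
  raw <- numeric(0); off <- numeric(0)
  for (pt in .mneck_points) for (ax in c("x", "y")) {
    pcol <- paste0(pt, "_", ax); ncol <- paste0("neck_", ax)
    rel <- fr[[pcol]] - fr[[ncol]]
    raw[paste0(pcol, "_Mneck_", w)] <- mean(rel)
    off[paste0("OFFSET_", pcol, "_Mneck_", w)] <-
      mean(rel - (b[pcol] - b[ncol]))
  }
  c(raw, off)
}

# interval index relative to mu in units of SD; boundary frames go to the
# interval nearer Normal. Returns one of the seven status labels.
.angle_bucket <- function(z, sd) {
  k <- z / sd
  ifelse(k >= -1 & k <= 1, "Normal",
  ifelse(k >= -2 & k < -1, "Mild_Right",
  ifelse(k >= -3 & k < -2, "Moderate_Right",
  ifelse(k < -3,           "Severe_Right",
  ifelse(k > 1 & k <= 2,   "Mild_Left",
  ifelse(k > 2 & k <= 3,   "Moderate_Left", "Severe_Left"))))))
}

#' Head-pose status proportions
#'
#' For each head angle (yaw, pitch, roll) the window's frames are assigned to
#' seven intervals around the subject's baseline mean (mu), cut at 1, 2 and 3
#' window standard deviations: Normal within 1 SD; Mild/Moderate/Severe on
#' the Right (below mu) and Left (above mu). The returned values are the
#' fractions of frames in each interval; the seven fractions for one angle
#' sum to 1. A window with zero angle SD puts every frame in Normal.
#'
#' @inheritParams offset_pose_features
#' @param mu_source centre of the intervals: `"baseline"` (default; the
#'   upright-calibration mean, so the intervals measure departure from the
#'   subject's corrected posture) or `"task"` (the window's own mean).
#' @return Named numeric vector of length 21 (`Yaw_Severe_Right_<w>`, ...).
#' @export
head_pose_status <- function(recording, baseline, window,
                             mu_source = c("baseline", "task")) {
  mu_source <- match.arg(mu_source)
  fr <- window_frames(recording, window)
  w <- .window_suffix(window)
  b <- unclass(baseline)
  out <- numeric(0)
  for (ang in c("yaw", "pitch", "roll")) {
    v <- fr[[ang]]
    if (mu_source == "task") b[ang] <- mean(v)
    sdw <- .wsd(v)
    if (sdw == 0) {
      prop <- c(1, numeric(6))
    } else {
      lab <- .angle_bucket(v - b[ang], sdw)
      prop <- vapply(.angle_status, function(s) mean(lab == s), numeric(1))
    }
    Ang <- c(yaw = "Yaw", pitch = "Pitch", roll = "Roll")[[ang]]
    names(prop) <- paste0(Ang, "_", .angle_status, "_", w)
    out <- c(out, prop)
  }
  out
}

#' Shoulder-imbalance status proportions
#'
#' The per-frame difference d = left-shoulder y minus right-shoulder y is cut
#' into three intervals around the baseline mean difference at 2 window SDs:
#' Normal strictly inside, Imbalance_Right at or below mu - 2 SD, and
#' Imbalance_Left at or above mu + 2 SD (matching the head-pose convention
#' that the negative side is labelled Right). Zero SD puts all frames in
#' Normal.
#'
#' @inheritParams offset_pose_features
#' @return Named numeric vector of length 3, summing to 1.
#' @export
shoulder_imbalance_status <- function(recording, baseline, window) {
  fr <- window_frames(recording, window)
  w <- .window_suffix(window)
  b <- unclass(baseline)
  d <- fr$Lshoulder_y - fr$Rshoulder_y
  mu <- b["Lshoulder_y"] - b["Rshoulder_y"]
  sdw <- .wsd(d)
  if (sdw == 0) {
    prop <- c(1, 0, 0)
  } else {
    right <- d <= mu - 2 * sdw
    left <- d >= mu + 2 * sdw
    prop <- c(mean(!right & !left), mean(right), mean(left))
  }
  names(prop) <- paste0(c("Shoulder_Normal", "Shoulder_Imbalance_Right",
                          "Shoulder_Imbalance_Left"), "_", w)
  prop
}

#' Shrug proportion
#'
#' A frame counts as a shrug when both shoulders are simultaneously raised
#' beyond one standard deviation of their baseline-relative height: with the
#' image origin at the top left, raised means the y-coordinate drops, so a
#' shrug frame has (y - baseline y) below -1 SD for both shoulders, where the
#' SD is each shoulder's window SD of that difference. If either SD is zero
#' the proportion is 0.
#'
#' @inheritParams offset_pose_features
#' @param y_up set TRUE for coordinate conventions where y increases upward
#'   (raised shoulders then mean larger y).
#' @return Named numeric scalar `Shrug_<w>` in \[0,1\].
#' @export
shrug_proportion <- function(recording, baseline, window, y_up = FALSE) {
  fr <- window_frames(recording, window)
  b <- unclass(baseline)
  dl <- fr$Lshoulder_y - b["Lshoulder_y"]
  dr <- fr$Rshoulder_y - b["Rshoulder_y"]
  if (y_up) { dl <- -dl; dr <- -dr }
  sdl <- .wsd(dl); sdr <- .wsd(dr)
  p <- if (sdl == 0 || sdr == 0) 0 else mean(dl < -sdl & dr < -sdr)
  stats::setNames(p, paste0("Shrug_", .window_suffix(window)))
}

#' Variation features
#'
#' Two parts: (a) the window SD of each of the 15 raw quantities, capturing
#' how much the subject moved during the task; (b) four aggregates of the
#' left-minus-right shoulder height difference, each a per-frame expression
#' averaged over the window's kept frames: signed and absolute, with and
#' without baseline calibration.
#'
#' @inheritParams offset_pose_features
#' @return Named numeric vector of length 19 (`<quantity>_SD_<w>`,
#'   `Shoulder_Diff_<w>`, `Offset_Shoulder_Diff_<w>`, `ABS_Shoulder_Diff_<w>`,
#'   `ABS_Offset_Shoulder_Diff_<w>`).
#' @export
variation_features <- function(recording, baseline, window) {
  fr <- window_frames(recording, window)
  w <- .window_suffix(window)
  b <- unclass(baseline)
  sds <- vapply(.quantities, function(q) .wsd(fr[[q]]), numeric(1))
  names(sds) <- paste0(.quantities, "_SD_", w)
  d <- fr$Lshoulder_y - fr$Rshoulder_y
  doff <- (fr$Lshoulder_y - b["Lshoulder_y"]) -
          (fr$Rshoulder_y - b["Rshoulder_y"])
  diffs <- c(mean(d), mean(doff), mean(abs(d)), mean(abs(doff)))
  names(diffs) <- paste0(c("Shoulder_Diff", "Offset_Shoulder_Diff",
                           "ABS_Shoulder_Diff", "ABS_Offset_Shoulder_Diff"),
                         "_", w)
  c(sds, diffs)
}

.window_suffix <- function(window) {
  match(.window_name(window), .window_names) - 1L
}

# All 94 posture features for one window, in canonical order.
window_features <- function(recording, baseline, window) {
  c(original_pose_features(recording, window),
    offset_pose_features(recording, baseline, window),
    head_pose_status(recording, baseline, window),
    shoulder_imbalance_status(recording, baseline, window),
    shrug_proportion(recording, baseline, window),
    normalized_position_features(recording, baseline, window),
    variation_features(recording, baseline, window))
}

#' Assemble the 381-feature vector for one subject
#'
#' Computes the personal baseline and all 94 posture features for each of the
#' four windows (whole recording, typing, gaming, video watching), appends
#' the five clinical covariates, and returns them in canonical schema order.
#' Gender is coded 1 for female, 0 for male.
#'
#' @param recording a QC-passed [pose_recording()].
#' @param clinical one-row data.frame (or list) with `gender`, `age`,
#'   `height_cm`, `weight_kg`, `bmi` for this subject.
#' @return Named numeric vector of length 381 matching [feature_schema()],
#'   with the subject id in attribute `subject_id`.
#' @export
assemble_feature_vector <- function(recording, clinical) {
  baseline <- compute_baseline(recording)
  pose <- unlist(lapply(0:3, function(w)
    window_features(recording, baseline, w)))
  clin <- c(gender = as.numeric(clinical$gender == "female"),
            age = as.numeric(clinical$age),
            height = as.numeric(clinical$height_cm),
            weight = as.numeric(clinical$weight_kg),
            bmi = as.numeric(clinical$bmi))
  v <- c(pose, clin)
  stopifnot(identical(names(v), feature_schema()))
  attr(v, "subject_id") <- recording$subject_id
  v
}

#' Extract the feature matrix for a cohort
#'
#' Runs [quality_control()] (unless `qc = FALSE`, for already-filtered
#' recordings) and [assemble_feature_vector()] for every subject.
#'
#' @param recordings list of [pose_recording()] objects.
#' @param clinical clinical table with one row per subject
#'   (see [read_clinical_table()]).
#' @param qc run frame quality control first (default TRUE).
#' @return List with `features` (data.frame: `subject_id` + 381 schema
#'   columns), `labels` (named character vector, where known), and
#'   `qc_reports` (list of `qc_report`, when `qc` ran).
#' @export
extract_features <- function(recordings, clinical, qc = TRUE) {
  reports <- list()
  rows <- lapply(recordings, function(rec) {
    if (qc) {
      res <- quality_control(rec)
      reports[[rec$subject_id]] <<- res$report
      rec <- res$recording
    }
    cl <- clinical[clinical$subject_id == rec$subject_id, , drop = FALSE]
    if (nrow(cl) != 1)
      stop("clinical table has ", nrow(cl), " rows for subject ",
           rec$subject_id)
    assemble_feature_vector(rec, cl)
  })
  features <- as.data.frame(do.call(rbind, rows))
  features <- cbind(
    subject_id = vapply(rows, attr, character(1), "subject_id"),
    features)
  rownames(features) <- NULL
  labels <- stats::setNames(clinical$label, clinical$subject_id)
  labels <- labels[features$subject_id]
  list(features = features, labels = labels, qc_reports = reports)
}
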