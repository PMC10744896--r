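# Frame-level quality control: drop frames with missing pose estimates, then
# drop frames whose keypoint confidence falls below a per-subject, per-keypoint
# Tukey lower fence (Q1 - 1.5 IQR) of that subject's confidence distribution.

#' Drop frames with missing pose estimates
#'
#' A frame is removed when any of its 15 estimated values (yaw, pitch, roll
#' and the 12 keypoint coordinates) is missing; a missing confidence alone
#' does not remove a frame. Frame order is preserved.
#'
#' @param recording a [pose_recording()].
#' @return List with `recording` (filtered) and `report` (partial
#'   [qc_report]: `n_input`, `n_removed_missing`, `n_kept`).
#' @export
drop_incomplete_frames <- function(recording) {
  stopifnot(inherits(recording, "pose_recording"))
  fr <- recording$frames
  vals <- fr[.quantities]
  incomplete <- rowSums(is.na(vals)) > 0
  if (all(incomplete))
    stop("subject ", recording$subject_id,
         ": all frames have missing pose estimates; subject unusable")
  out <- recording
  out$frames <- fr[!incomplete, , drop = FALSE]
  rownames(out$frames) <- NULL
  list(recording = out,
       report = list(n_input = nrow(fr),
                     n_removed_missing = sum(incomplete),
                     n_kept = sum(!incomplete)))
}

#' Per-keypoint confidence thresholds (Tukey lower fence)
#'
#' For each keypoint, computes the first quartile and interquartile range of
#' that subject's confidence scores (linear-interpolation quartiles,
#' `stats::quantile` type 7) and sets the cutoff at Q1 - 1.5 IQR. Cutoffs are
#' computed from the subject's own frames only, over the whole recording.
#' A negative cutoff simply removes nothing for that keypoint.
#'
#' @param recording a [pose_recording()] (normally after
#'   [drop_incomplete_frames()]).
#' @param min_frames minimum confidence observations required per keypoint.
#' @return `qc_thresholds`: data.frame with one row per keypoint and columns
#'   `keypoint`, `q1`, `iqr`, `cutoff`.
#' @export
compute_confidence_thresholds <- function(recording, min_frames = 4L) {
  stopifnot(inherits(recording, "pose_recording"))
  fr <- recording$frames
  rows <- lapply(.kp_names, function(kp) {
    conf <- fr[[paste0(kp, "_conf")]]
    conf <- conf[!is.na(conf)]
    if (length(conf) < min_frames)
      stop("subject ", recording$subject_id, ": only ", length(conf),
           " confidence values for keypoint ", kp,
           " (need >= ", min_frames, ")")
    q <- unname(stats::quantile(conf, c(0.25, 0.75), type = 7))
    data.frame(keypoint = kp, q1 = q[1], iqr = q[2] - q[1],
               cutoff = q[1] - 1.5 * (q[2] - q[1]))
  })
  structure(do.call(rbind, rows), class = c("qc_thresholds", "data.frame"))
}

#' Remove low-confidence frames
#'
#' A frame is removed iff any keypoint's confidence is strictly below that
#' keypoint's cutoff. Missing confidences never trigger removal (they carry
#' no evidence either way).
#'
#' @param recording a [pose_recording()] after [drop_incomplete_frames()].
#' @param thresholds [compute_confidence_thresholds()] output for the same
#'   subject.
#' @return List with `recording` and a complete `report` ([qc_report]).
#' @export
confidence_filter <- function(recording, thresholds) {
  stopifnot(inherits(recording, "pose_recording"),
            inherits(thresholds, "qc_thresholds"))
  fr <- recording$frames
  low <- rep(FALSE, nrow(fr))
  for (i in seq_len(nrow(thresholds))) {
    conf <- fr[[paste0(thresholds$keypoint[i], "_conf")]]
    low <- low | (!is.na(conf) & conf < thresholds$cutoff[i])
  }
  if (all(low))
    stop("subject ", recording$subject_id,
         ": all frames below confidence cutoff; subject unusable")
  out <- recording
  out$frames <- fr[!low, , drop = FALSE]
  rownames(out$frames) <- NULL
  list(recording = out,
       report = list(n_input = nrow(fr),
                     n_removed_low_confidence = sum(low),
                     n_kept = sum(!low)))
}

#' Run full frame quality control on one subject
#'
#' Applies [drop_incomplete_frames()] then [confidence_filter()] (with
#' thresholds computed on the complete frames) and checks that the baseline
#' window retains at least `min_baseline` valid frames.
#'
#' @inheritParams drop_incomplete_frames
#' @param min_baseline minimum valid frames required in the baseline window.
#' @return List with `recording` (QC-passed frames) and `report`, a
#'   `qc_report`: `n_input`, `n_removed_missing`, `n_removed_low_confidence`,
#'   `n_kept`, `removal_rate`. Counts always satisfy
#'   `n_input = n_removed_missing + n_removed_low_confidence + n_kept`.
#' @export
#' @aliases qc_report
quality_control <- function(recording, min_baseline = 5L) {
  s1 <- drop_incomplete_frames(recording)
  thr <- compute_confidence_thresholds(s1$recording)
  s2 <- confidence_filter(s1$recording, thr)
  rec <- s2$recording
  n_base <- sum(rec$frames$frame < rec$baseline_window[2])
  if (n_base < min_baseline)
    stop("subject ", rec$subject_id, ": only ", n_base,
         " valid frames in the baseline window (need >= ", min_baseline, ")")
  n_in <- s1$report$n_input
  report <- structure(list(
    subject_id = rec$subject_id,
    n_input = n_in,
    n_removed_missing = s1$report$n_removed_missing,
    n_removed_low_confidence = s2$report$n_removed_low_confidence,
    n_kept = s2$report$n_kept,
    removal_rate = (n_in - s2$report$n_kept) / n_in
  ), class = "qc_report")
  list(recording = rec, report = report, thresholds = thr)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %s: %d frames in, %d missing, %d low-confidence, %d kept (removal %.1f%%)\n",
    x$subject_id, x$n_input, x$n_removed_missing,
    x$n_removed_low_confidence, x$n_kept, 100 * x$removal_rate))
  invisible(x)
}
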