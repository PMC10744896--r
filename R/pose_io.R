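# Reading and writing the tabular interchange formats: per-frame pose tables,
# clinical tables, and the 381-column feature matrix.
#
# Pose CSV contract: columns `frame, yaw, pitch, roll` then
# {leye,reye,nose,neck,lshoulder,rshoulder} x {_x,_y,_conf}; one row per frame
# at 1 Hz; empty cells are missing values and are never imputed.

.pose_csv_cols <- function() {
  c("frame", "yaw", "pitch", "roll",
    as.vector(t(outer(.kp_csv, c("_x", "_y", "_conf"), paste0))))
}

# canonical (internal) frame column names, same order as the CSV
.frame_cols <- function() {
  c("frame", "yaw", "pitch", "roll",
    as.vector(t(outer(.kp_names, c("_x", "_y", "_conf"), paste0))))
}

#' Construct a pose recording
#'
#' Bundles a subject's per-frame pose estimates with the task-window layout:
#' the recording nominally spans `n_frames` frames at 1 Hz, split into three
#' equal task windows (typing, gaming, video watching), with the first 10
#' frames forming the upright-sitting baseline window.
#'
#' @param frames data.frame with columns `frame` (0-based index), `yaw`,
#'   `pitch`, `roll` (degrees), and `<kp>_x`, `<kp>_y`, `<kp>_conf` for the
#'   six keypoints Leye, Reye, nose, neck, Lshoulder, Rshoulder. Coordinates
#'   are image-normalized in \[0,1\] with the origin at the top left (y grows
#'   downward); confidences in \[0,1\]. Missing values allowed anywhere.
#' @param subject_id character scalar.
#' @param label `"case"`, `"control"`, or `NA` if unknown.
#' @param n_frames nominal recording length in frames (default: largest frame
#'   index + 1). Must be divisible by 3.
#' @param baseline_n length of the baseline window in frames (default 10).
#' @return An object of class `pose_recording`: a list with `subject_id`,
#'   `label`, `frames`, `n_frames`, `window_bounds` (list of `c(from, to)`
#'   half-open frame-index ranges for windows `whole`, `typing`, `gaming`,
#'   `watching`) and `baseline_window`.
#' @export
pose_recording <- function(frames, subject_id, label = NA_character_,
                           n_frames = NULL, baseline_n = 10L) {
  stopifnot(is.data.frame(frames))
  need <- .frame_cols()
  missing_cols <- setdiff(need, names(frames))
  if (length(missing_cols))
    stop("frames is missing column(s): ", paste(missing_cols, collapse = ", "))
  frames <- frames[need]
  for (cc in need) frames[[cc]] <- as.numeric(frames[[cc]])
  if (anyNA(frames$frame)) stop("frame index must not be missing")
  if (anyDuplicated(frames$frame))
    stop("duplicate frame indices in recording")
  frames <- frames[order(frames$frame), , drop = FALSE]
  rownames(frames) <- NULL

  .validate_frame_ranges(frames)

  if (is.null(n_frames)) n_frames <- as.integer(max(frames$frame)) + 1L
  n_frames <- as.integer(n_frames)
  if (n_frames %% 3L != 0L)
    stop("n_frames must be divisible by 3 (three equal task windows), got ",
         n_frames)
  tl <- n_frames %/% 3L
  if (!is.na(label)) label <- match.arg(label, c("case", "control"))
  structure(list(
    subject_id = as.character(subject_id),
    label = label,
    frames = frames,
    n_frames = n_frames,
    window_bounds = list(whole    = c(0L, n_frames),
                         typing   = c(0L, tl),
                         gaming   = c(tl, 2L * tl),
                         watching = c(2L * tl, n_frames)),
    baseline_window = c(0L, as.integer(baseline_n))
  ), class = "pose_recording")
}

# Range invariants; errors name the offending (1-based) row of the table.
.validate_frame_ranges <- function(frames) {
  chk <- function(col, lo, hi) {
    v <- frames[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad))
      stop(sprintf("row %d: %s = %g out of range [%g, %g]",
                   bad[1], col, v[bad[1]], lo, hi))
  }
  for (a in c("yaw", "pitch", "roll")) chk(a, -180, 180)
  for (kp in .kp_names) {
    chk(paste0(kp, "_x"), 0, 1)
    chk(paste0(kp, "_y"), 0, 1)
    chk(paste0(kp, "_conf"), 0, 1)
  }
  invisible(TRUE)
}

#' @export
print.pose_recording <- function(x, ...) {
  cat(sprintf("<pose_recording> subject %s (%s): %d/%d frames kept\n",
              x$subject_id, ifelse(is.na(x$label), "unlabelled", x$label),
              nrow(x$frames), x$n_frames))
  invisible(x)
}

#' Read a per-frame pose table
#'
#' Reads the delimited pose-estimation output for one subject. Empty cells
#' become missing values (`NA`), never zeros; unknown columns are dropped
#' with a warning; a cell that cannot be parsed as a number, or a value out
#' of its documented range, is a hard error naming the row.
#'
#' @param path CSV file, one row per frame, columns `frame, yaw, pitch, roll`
#'   then `{leye,reye,nose,neck,lshoulder,rshoulder}` x `{_x,_y,_conf}`.
#' @param subject_id subject identifier (default: file name without extension).
#' @param label optional `"case"`/`"control"` label.
#' @param pixel_dims optional `c(width, height)`: if the source emitted pixel
#'   coordinates, they are divided by the image dimensions to recover the
#'   image-normalized \[0,1\] convention used throughout.
#' @param n_frames,baseline_n passed to [pose_recording()].
#' @return A [pose_recording()].
#' @export
read_pose_table <- function(path, subject_id = NULL, label = NA_character_,
                            pixel_dims = NULL, n_frames = NULL,
                            baseline_n = 10L) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  want <- .pose_csv_cols()
  unknown <- setdiff(names(raw), want)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    raw <- raw[intersect(names(raw), want)]
  }
  absent <- setdiff(want, names(raw))
  if ("frame" %in% absent) stop("pose table has no 'frame' column")
  for (cc in absent) raw[[cc]] <- NA_character_
  raw <- raw[want]

  num <- raw
  for (cc in want) {
    v <- raw[[cc]]
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad))
      stop(sprintf("row %d: cannot parse '%s' value '%s' as a number",
                   bad[1], cc, v[bad[1]]))
    num[[cc]] <- parsed
  }
  names(num) <- .frame_cols()

  if (!is.null(pixel_dims)) {
    stopifnot(length(pixel_dims) == 2, all(pixel_dims > 0))
    for (kp in .kp_names) {
      num[[paste0(kp, "_x")]] <- num[[paste0(kp, "_x")]] / pixel_dims[1]
      num[[paste0(kp, "_y")]] <- num[[paste0(kp, "_y")]] / pixel_dims[2]
    }
  }
  pose_recording(num, subject_id = subject_id, label = label,
                 n_frames = n_frames, baseline_n = baseline_n)
}

#' Write a pose recording back to CSV
#'
#' Inverse of [read_pose_table()]; missing values are written as empty cells.
#'
#' @param recording a [pose_recording()].
#' @param path output file.
#' @export
write_pose_table <- function(recording, path) {
  stopifnot(inherits(recording, "pose_recording"))
  out <- recording$frames
  names(out) <- .pose_csv_cols()
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a clinical covariate table
#'
#' @param path CSV with columns `subject_id, label, gender, age, height_cm,
#'   weight_kg, bmi` (additional columns such as `ndi` are carried through).
#'   A missing `bmi` column (or cell) is recomputed as weight/(height/100)^2;
#'   a stated BMI deviating from the recomputed one by more than 0.5 kg/m^2
#'   triggers a warning.
#' @return data.frame, one row per subject.
#' @export
read_clinical_table <- function(path) {
  cl <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  need <- c("subject_id", "label", "gender", "age", "height_cm", "weight_kg")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  bmi_re <- cl$weight_kg / (cl$height_cm / 100)^2
  if (!"bmi" %in% names(cl)) {
    cl$bmi <- bmi_re
  } else {
    fill <- is.na(cl$bmi)
    cl$bmi[fill] <- bmi_re[fill]
    off <- which(!fill & abs(cl$bmi - bmi_re) > 0.5)
    if (length(off))
      warning(sprintf(
        "BMI of subject %s differs from weight/height^2 by more than 0.5",
        cl$subject_id[off[1]]))
  }
  bad <- setdiff(unique(cl$label), c("case", "control"))
  if (length(bad)) stop("unknown label value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(cl$gender), c("female", "male"))
  if (length(bad)) stop("unknown gender value(s): ", paste(bad, collapse = ", "))
  cl
}

#' @rdname read_clinical_table
#' @param clinical data.frame as returned by [read_clinical_table()].
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read the feature matrix
#'
#' One row per subject, `subject_id` first, then the 381 features in the
#' canonical [feature_schema()] order. Writing a matrix whose columns deviate
#' from the schema is a hard error; an empty input yields a header-only file.
#'
#' @param features data.frame: `subject_id` + the 381 schema columns.
#' @param path CSV path.
#' @export
write_feature_matrix <- function(features, path) {
  schema <- feature_schema()
  got <- setdiff(names(features), "subject_id")
  if (!identical(got, schema))
    stop("feature columns do not match the canonical 381-feature schema")
  utils::write.csv(features[c("subject_id", schema)], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  ft <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(ft), c("subject_id", feature_schema())))
    stop("file header does not match the canonical 381-feature schema")
  ft$subject_id <- as.character(ft$subject_id)
  ft
}
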