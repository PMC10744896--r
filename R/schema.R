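# Canonical naming for the pose quantities and the 381-feature schema.

# Keypoints in canonical order. Capitalisation follows the published feature
# names (shoulders/eyes carry an L/R prefix, nose and neck are lower case).
.kp_names <- c("Leye", "Reye", "nose", "neck", "Lshoulder", "Rshoulder")
.kp_csv   <- c("leye", "reye", "nose", "neck", "lshoulder", "rshoulder")

# The 15 per-frame raw quantities: 3 head angles + 6 keypoints x 2 axes.
.quantities <- c("yaw", "pitch", "roll",
                 as.vector(t(outer(.kp_names, c("x", "y"), paste, sep = "_"))))

.conf_cols <- paste0(.kp_names, "_conf")

.angle_status <- c("Normal", "Mild_Right", "Moderate_Right", "Severe_Right",
                   "Mild_Left", "Moderate_Left", "Severe_Left")

.clinical_features <- c("gender", "age", "height", "weight", "bmi")

# Points used for neck-normalized positions (all keypoints except the neck).
.mneck_points <- c("Leye", "Reye", "nose", "Lshoulder", "Rshoulder")

#' Per-window posture feature names
#'
#' The 94 feature names computed for one task window, without the window
#' suffix, in canonical order: 15 original (RAW), 15 offset, 25 status,
#' 20 neck-normalized, 19 variation.
#'
#' @return Character vector of length 94.
#' @keywords internal
window_feature_stems <- function() {
  raw    <- paste0("RAW_", .quantities, "_AVG")
  offset <- paste0("OFFSET_", .quantities, "_AVG")
  status <- c(as.vector(t(outer(c("Yaw", "Pitch", "Roll"), .angle_status,
                                paste, sep = "_"))),
              "Shoulder_Normal", "Shoulder_Imbalance_Right",
              "Shoulder_Imbalance_Left", "Shrug")
  pts    <- as.vector(t(outer(.mneck_points, c("x", "y"), paste, sep = "_")))
  mneck  <- c(paste0(pts, "_Mneck"), paste0("OFFSET_", pts, "_Mneck"))
  vari   <- c(paste0(.quantities, "_SD"),
              "Shoulder_Diff", "Offset_Shoulder_Diff",
              "ABS_Shoulder_Diff", "ABS_Offset_Shoulder_Diff")
  c(raw, offset, status, mneck, vari)
}

#' The canonical 381-feature schema
#'
#' Names of all features extracted per subject: 94 posture features for each
#' of the four windows (`_0` whole recording, `_1` typing, `_2` gaming,
#' `_3` video watching) followed by the 5 clinical covariates
#' (gender, age, height, weight, bmi).
#'
#' @return Character vector of length 381, in the fixed column order used by
#'   [write_feature_matrix()].
#' @examples
#' length(feature_schema())   # 381
#' head(feature_schema())
#' @export
feature_schema <- function() {
  stems <- window_feature_stems()
  c(as.vector(sapply(0:3, function(w) paste0(stems, "_", w))),
    .clinical_features)
}
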