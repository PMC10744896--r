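# Shared fixtures. Expensive objects (the default 60-subject cohort and its
# feature matrix) are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# a recording with every quantity constant; n frames, optional overrides
constant_recording <- function(n = 30L, yaw = 0, pitch = -5, roll = 0,
                               conf = 0.9, gap = 0.01, subject_id = "C1",
                               label = NA_character_) {
  fr <- data.frame(frame = 0:(n - 1L))
  fr$yaw <- yaw; fr$pitch <- pitch; fr$roll <- roll
  pos <- c(Leye_x = 0.55, Leye_y = 0.35, Reye_x = 0.45, Reye_y = 0.35,
           nose_x = 0.50, nose_y = 0.40, neck_x = 0.50, neck_y = 0.55,
           Lshoulder_x = 0.67, Lshoulder_y = 0.60,
           Rshoulder_x = 0.33, Rshoulder_y = 0.60 - gap)
  for (p in names(pos)) fr[[p]] <- pos[[p]]
  for (kp in c("Leye", "Reye", "nose", "neck", "Lshoulder", "Rshoulder"))
    fr[[paste0(kp, "_conf")]] <- conf
  pose_recording(fr, subject_id = subject_id, label = label, n_frames = n)
}

# default planted-effect cohort (n = 60) with extracted features, cached
default_features <- function(seed = 101L) {
  key <- paste0("feat", seed)
  if (is.null(.fixture_cache[[key]])) {
    coh <- generate_cohort(cohort_config(), seed = seed)
    ext <- extract_features(coh$recordings, coh$clinical)
    X <- as.matrix(ext$features[feature_schema()])
    rownames(X) <- ext$features$subject_id
    .fixture_cache[[key]] <- list(X = X, y = ext$labels,
                                  qc = ext$qc_reports,
                                  manifest = coh$manifest)
  }
  .fixture_cache[[key]]
}

# brute-force AUROC oracle: concordant pairs + half ties
auroc_oracle <- function(y, score) {
  pos <- which(y == "case"); neg <- which(y == "control")
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  tot / (length(pos) * length(neg))
}
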