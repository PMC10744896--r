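test_that("baseline is the mean of the first-10-s valid frames", {
  rec <- constant_recording(n = 30)
  rec$frames$yaw <- c(0:9, rep(0, 20))
  b <- compute_baseline(rec)
  expect_equal(unname(b["yaw"]), 4.5)
  expect_equal(unname(b["Lshoulder_y"]), 0.60)

  # a QC-removed baseline frame shifts the mean to the remaining 9 frames
  rec2 <- rec
  rec2$frames <- rec2$frames[-4, ]   # drop frame 3 (yaw = 3)
  expect_equal(unname(compute_baseline(rec2)["yaw"]), sum(c(0:2, 4:9)) / 9)

  rec3 <- constant_recording(n = 30)
  rec3$frames <- rec3$frames[rec3$frames$frame >= 6, ]
  expect_error(compute_baseline(rec3), "baseline frames")
})

test_that("original and offset features are window means and baseline-centred means", {
  rec <- constant_recording(n = 30, yaw = 3)
  raw <- original_pose_features(rec, 1)
  expect_length(raw, 15)
  expect_equal(unname(raw["RAW_yaw_AVG_1"]), 3)

  # two-frame symmetry: yaw {-10, 10} averages to 0
  rec$frames$yaw[11:20] <- rep(c(-10, 10), 5)
  expect_equal(unname(original_pose_features(rec, 2)["RAW_yaw_AVG_2"]), 0)

  b <- compute_baseline(rec)
  off <- offset_pose_features(rec, b, 3)
  expect_true(all(abs(off) < 1e-12))   # window identical to baseline posture

  # linearity: baseline yaw 3, watching mean 5 -> offset 2; and the
  # per-frame-then-average path equals window mean minus baseline
  rec$frames$yaw[21:30] <- 5
  off3 <- offset_pose_features(rec, b, 3)
  expect_equal(unname(off3["OFFSET_yaw_AVG_3"]), 2)
  expect_equal(unname(off3["OFFSET_yaw_AVG_3"]),
               mean(rec$frames$yaw[21:30] - b["yaw"]))
})

test_that("neck-normalized positions measure offsets from the neck", {
  rec <- constant_recording(n = 30)
  rec$frames$nose_x <- rec$frames$neck_x + 0.05
  rec$frames$nose_y <- rec$frames$neck_y - 0.10
  b <- compute_baseline(rec)
  mn <- normalized_position_features(rec, b, 1)
  expect_length(mn, 20)
  expect_equal(unname(mn["nose_x_Mneck_1"]), 0.05)
  expect_equal(unname(mn["nose_y_Mneck_1"]), -0.10)
  expect_equal(unname(mn["OFFSET_nose_x_Mneck_1"]), 0)  # matches baseline

  # a point riding exactly on the neck scores 0
  rec$frames$Leye_x <- rec$frames$neck_x
  rec$frames$Leye_y <- rec$frames$neck_y
  b <- compute_baseline(rec)
  mn <- normalized_position_features(rec, b, 2)
  expect_equal(unname(mn["Leye_x_Mneck_2"]), 0)
  expect_equal(unname(mn["Leye_y_Mneck_2"]), 0)
})

test_that("head-pose status proportions partition the window", {
  rec <- constant_recording(n = 30)
  b <- compute_baseline(rec)
  st <- head_pose_status(rec, b, 1)
  expect_length(st, 21)
  # all angles at the baseline: SD 0 -> everything Normal
  expect_equal(unname(st["Yaw_Normal_1"]), 1)
  expect_equal(sum(st[grep("^Pitch", names(st))]), 1)

  # brute-force oracle: plant 10 of 100 frames far below mu - 3 SD
  rec2 <- constant_recording(n = 300)
  set.seed(42)
  yaw <- rnorm(100, 0, 1)
  low <- sample(100, 10)
  yaw[low] <- -50
  rec2$frames$yaw[101:200] <- yaw
  rec2$frames$yaw[1:10] <- 0
  b2 <- compute_baseline(rec2)
  st2 <- head_pose_status(rec2, b2, 2)
  sdw <- sd(yaw)
  oracle <- mean(yaw - 0 < -3 * sdw)
  expect_equal(unname(st2["Yaw_Severe_Right_2"]), oracle)
  expect_equal(oracle, 0.10)
  expect_equal(sum(st2[grep("^Yaw", names(st2))]), 1, tolerance = 1e-9)
})

test_that("status boundary frames land in the interval nearer Normal", {
  bucket <- neckpose:::.angle_bucket
  sdw <- 2.5
  expect_identical(bucket(c(-1, 1) * sdw, sdw), rep("Normal", 2))
  expect_identical(bucket(-2 * sdw, sdw), "Mild_Right")
  expect_identical(bucket(2 * sdw, sdw), "Mild_Left")
  expect_identical(bucket(-3 * sdw, sdw), "Moderate_Right")
  expect_identical(bucket(3 * sdw, sdw), "Moderate_Left")
  expect_identical(bucket(-3.001 * sdw, sdw), "Severe_Right")
  expect_identical(bucket(3.001 * sdw, sdw), "Severe_Left")
  expect_identical(bucket(-1.5 * sdw, sdw), "Mild_Right")
})

test_that("shoulder-imbalance status uses the 2 SD cut with Right below", {
  rec <- constant_recording(n = 300, gap = 0.01)
  si <- shoulder_imbalance_status(rec, compute_baseline(rec), 1)
  expect_equal(unname(si["Shoulder_Normal_1"]), 1)   # SD 0, level baseline
  expect_equal(sum(si), 1)

  # plant 5 of 100 gaming frames far above mu + 2 SD (left shoulder low)
  set.seed(7)
  d <- rnorm(100, 0.01, 0.002)
  hi <- sample(100, 5)
  d[hi] <- 0.08
  rec$frames$Rshoulder_y[101:200] <- rec$frames$Lshoulder_y[101:200] - d
  si2 <- shoulder_imbalance_status(rec, compute_baseline(rec), 2)
  oracle_left <- mean(d >= 0.01 + 2 * sd(d))
  oracle_right <- mean(d <= 0.01 - 2 * sd(d))
  expect_equal(unname(si2["Shoulder_Imbalance_Left_2"]), oracle_left)
  expect_equal(unname(si2["Shoulder_Imbalance_Right_2"]), oracle_right)
  expect_equal(mean(d >= 0.01 + 2 * sd(d)), 0.05)
  expect_equal(sum(si2), 1)
})

test_that("shrugs need BOTH shoulders raised beyond one SD", {
  fx <- worked_fixture()
  rec <- quality_control(fx$recordings[[1]])$recording
  b <- compute_baseline(rec)
  expect_equal(unname(shrug_proportion(rec, b, 2)), 0.2)  # 2 of 10 frames
  expect_equal(unname(shrug_proportion(rec, b, 1)), 0)    # shoulders static

  # raising only one shoulder is not a shrug
  rec2 <- constant_recording(n = 30)
  rec2$frames$Lshoulder_y[11:20] <- 0.60 - c(rep(0, 8), 0.05, 0.05)
  b2 <- compute_baseline(rec2)
  expect_equal(unname(shrug_proportion(rec2, b2, 2)), 0)

  # y_up flips the raised direction: the fixture's drops are no longer shrugs
  expect_equal(unname(shrug_proportion(rec, b, 2, y_up = TRUE)), 0)
})

test_that("status centre can follow the task mean instead of the baseline", {
  rec <- constant_recording(n = 30)
  rec$frames$yaw[11:20] <- 10 + c(rep(0, 8), 2, -2)  # far from baseline 0
  b <- compute_baseline(rec)
  st_base <- head_pose_status(rec, b, 2)
  st_task <- head_pose_status(rec, b, 2, mu_source = "task")
  # centred on the window mean the pattern is symmetric around Normal
  expect_equal(unname(st_task["Yaw_Normal_2"]), 0.8)
  expect_equal(unname(st_task["Yaw_Moderate_Left_2"]),
               unname(st_task["Yaw_Moderate_Right_2"]))
  # centred on the baseline the whole window sits far to the left
  expect_lt(unname(st_base["Yaw_Normal_2"]), 0.5)
})

test_that("variation features: window SDs and the shoulder-difference family", {
  rec <- constant_recording(n = 30, gap = 0.01)
  b <- compute_baseline(rec)
  v <- variation_features(rec, b, 1)
  expect_length(v, 19)
  expect_true(all(v[grep("_SD_", names(v))] == 0))
  expect_equal(unname(v["Shoulder_Diff_1"]), 0.01)
  expect_equal(unname(v["ABS_Shoulder_Diff_1"]), 0.01)

  # hand example: gaps 0.01, -0.01, 0.03 repeated -> signed mean 0.01,
  # absolute mean 0.05/3
  rec$frames$Rshoulder_y[21:30] <-
    rec$frames$Lshoulder_y[21:30] - rep(c(0.01, -0.01, 0.03), length.out = 10)
  b <- compute_baseline(rec)
  v3 <- variation_features(rec, b, 3)
  gaps <- rep(c(0.01, -0.01, 0.03), length.out = 10)
  expect_equal(unname(v3["Shoulder_Diff_3"]), mean(gaps))
  expect_equal(unname(v3["ABS_Shoulder_Diff_3"]), mean(abs(gaps)))
  expect_gte(v3[["ABS_Shoulder_Diff_3"]], abs(v3[["Shoulder_Diff_3"]]))
})

test_that("offset/status/variation features are translation invariant; Shoulder_Diff scales", {
  coh <- generate_cohort(cohort_config(n_cases = 1, n_controls = 1,
                                       corrupt_frame_rate = 0), seed = 5)
  rec <- coh$recordings[[1]]
  shift <- 0.07
  rec2 <- rec
  for (cc in grep("_[xy]$", names(rec2$frames), value = TRUE))
    rec2$frames[[cc]] <- rec2$frames[[cc]] + shift
  b1 <- compute_baseline(rec); b2 <- compute_baseline(rec2)
  for (w in 0:3) {
    f1 <- c(offset_pose_features(rec, b1, w),
            head_pose_status(rec, b1, w),
            shoulder_imbalance_status(rec, b1, w),
            shrug_proportion(rec, b1, w),
            normalized_position_features(rec, b1, w),
            variation_features(rec, b1, w))
    f2 <- c(offset_pose_features(rec2, b2, w),
            head_pose_status(rec2, b2, w),
            shoulder_imbalance_status(rec2, b2, w),
            shrug_proportion(rec2, b2, w),
            normalized_position_features(rec2, b2, w),
            variation_features(rec2, b2, w))
    expect_equal(f1, f2, tolerance = 1e-9)
  }

  # scale check on y: Shoulder_Diff family scales linearly
  c0 <- 0.5
  rec3 <- rec
  for (cc in grep("_y$", names(rec3$frames), value = TRUE))
    rec3$frames[[cc]] <- rec3$frames[[cc]] * c0
  b3 <- compute_baseline(rec3)
  v1 <- variation_features(rec, b1, 0)
  v3 <- variation_features(rec3, b3, 0)
  for (f in c("Shoulder_Diff_0", "Offset_Shoulder_Diff_0",
              "ABS_Shoulder_Diff_0", "ABS_Offset_Shoulder_Diff_0"))
    expect_equal(v3[[f]], c0 * v1[[f]], tolerance = 1e-9)
})

test_that("the assembled vector has 381 features with exact family counts", {
  fx <- worked_fixture()
  rec <- quality_control(fx$recordings[[1]])$recording
  v <- assemble_feature_vector(rec, fx$clinical[1, ])
  expect_length(v, 381)
  expect_identical(names(v), feature_schema())
  expect_equal(unname(v["gender"]), 1)   # female
  expect_equal(unname(v["bmi"]), 60 / 1.65^2)

  # status family count per window: 3 angles x 7 + 3 shoulder + 1 shrug = 25
  st <- grep("^(Yaw|Pitch|Roll|Shoulder_Normal|Shoulder_Imbalance|Shrug)",
             names(v)[grepl("_2$", names(v))], value = TRUE)
  expect_length(st, 25)

  # every proportion family partitions to 1
  for (w in 0:3) {
    for (ang in c("Yaw", "Pitch", "Roll"))
      expect_equal(sum(v[grep(paste0("^", ang, "_.*_", w, "$"),
                              names(v))]), 1, tolerance = 1e-9)
    expect_equal(sum(v[grep(paste0("^Shoulder_(Normal|Imbalance_Right|Imbalance_Left)_",
                                   w, "$"), names(v))]), 1, tolerance = 1e-9)
  }
})

test_that("whole-window AVG features are frame-count-weighted task combinations", {
  coh <- generate_cohort(cohort_config(n_cases = 1, n_controls = 1),
                         seed = 9)
  rec <- quality_control(coh$recordings[[1]])$recording
  b <- compute_baseline(rec)
  n_w <- vapply(1:3, function(w)
    nrow(neckpose:::window_frames(rec, w)), numeric(1))
  r0 <- original_pose_features(rec, 0)
  parts <- vapply(1:3, function(w)
    original_pose_features(rec, w), numeric(15))
  combined <- as.numeric(parts %*% n_w / sum(n_w))
  expect_equal(unname(r0), combined, tolerance = 1e-9)
})

test_that("an emptied task window is a named hard error", {
  rec <- constant_recording(n = 30)
  rec$frames <- rec$frames[rec$frames$frame < 20, ]
  expect_error(assemble_feature_vector(rec, list(gender = "male", age = 30,
                                                 height_cm = 170,
                                                 weight_kg = 70, bmi = 24.2)),
               "watching")
})
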