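test_that("the joint model matches the 25-joint skeleton contract", {
  j <- kinect_joints()
  expect_length(j, 25)
  expect_false(anyDuplicated(j) > 0)
  a <- active_joints()
  expect_length(a, 21)
  expect_true(all(c("HandTipLeft", "HandTipRight",
                    "ThumbLeft", "ThumbRight") %in% setdiff(j, a)))
  # ordering is part of the contract (feature names depend on it)
  expect_identical(j[1:2], c("SpineBase", "SpineMid"))
  expect_identical(a, setdiff(j, c("HandTipLeft", "HandTipRight",
                                   "ThumbLeft", "ThumbRight")))
  expect_error(active_joints(exclude = "NoSuchJoint"),
               class = "frailmotion_key_error")
})

test_that("recordings round-trip through both dialects", {
  g <- generate_recording("gait", seed = 11)
  rec <- g$recording
  for (dialect in c("csv_long", "json")) {
    path <- withr::local_tempfile(fileext = ".rec")
    write_recording(rec, path, dialect)
    back <- read_recording(path, dialect)
    expect_equal(back$time, rec$time, tolerance = 1e-9)
    expect_equal(back$x, rec$x, tolerance = 1e-9)
    expect_equal(back$y, rec$y, tolerance = 1e-9)
    expect_equal(back$z, rec$z, tolerance = 1e-9)
    expect_identical(attr(back, "dominant_hand"), attr(rec, "dominant_hand"))
    expect_identical(attr(back, "exercise"), "gait")
    rep <- load_report(back)
    expect_equal(rep$n_imputed, 0)
    expect_equal(rep$n_dropped, 0)
  }
})

test_that("reading a json file with the csv dialect is a format error", {
  g <- generate_recording("gait", seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_recording(g$recording, path, "json")
  expect_error(read_recording(path, "csv_long"),
               class = "frailmotion_format_error")
})

test_that("short interior joint dropouts are linearly interpolated", {
  rec <- constant_recording(n = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path, "csv_long")
  lines <- readLines(path)
  # drop Head from the 5th frame only (gap of 1)
  t5 <- sprintf("%.12g", unique(rec$time)[5])
  drop <- grepl(paste0("^", t5, ",Head,"), lines)
  expect_equal(sum(drop), 1)
  writeLines(lines[!drop], path)
  back <- read_recording(path, "csv_long")
  expect_equal(n_frames(back), 10)
  expect_equal(load_report(back)$n_imputed, 1)
  # interpolation over a single uniform-grid gap is the neighbour midpoint
  tr <- joint_track(back, "Head")
  expect_equal(tr$y[5], (tr$y[4] + tr$y[6]) / 2, tolerance = 1e-9)
})

test_that("long dropouts drop frames and schema violations are errors", {
  rec <- constant_recording(n = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path, "csv_long")
  lines <- readLines(path)
  times <- sprintf("%.12g", unique(rec$time)[4:8])     # gap of 5 > max_gap
  drop <- grepl(paste0("^(", paste(times, collapse = "|"), "),Head,"), lines)
  expect_equal(sum(drop), 5)
  writeLines(lines[!drop], path)
  back <- read_recording(path, "csv_long")
  expect_equal(n_frames(back), 7)
  expect_equal(load_report(back)$n_dropped, 5)

  # a 24-joint file (one joint entirely absent) violates the schema
  writeLines(lines[!grepl(",Head,", lines)], path)
  expect_error(read_recording(path, "csv_long"),
               class = "frailmotion_format_error")

  # malformed header names the missing column
  writeLines(c("timestamp,joint,x,y", "0,Head,0,0"), path)
  expect_error(read_recording(path, "csv_long"), "z",
               class = "frailmotion_format_error")

  # fewer than 2 usable frames
  writeLines(lines[grepl(paste0("^(", sprintf("%.12g", unique(rec$time)[1]),
                                "),"), lines) | !grepl("^[0-9]", lines)],
             path)
  expect_error(read_recording(path, "csv_long"),
               class = "frailmotion_empty_recording_error")
})

test_that("joint_track isolates one joint's per-axis series", {
  rec <- constant_recording(n = 15)
  tr <- joint_track(rec, "Head")
  expect_equal(nrow(tr), 15)
  expect_equal(tr$frame, 1:15)
  expect_true(all(apply(tr[c("x", "y", "z")], 2, var) == 0))
  expect_error(joint_track(rec, "Skull"), class = "frailmotion_key_error")

  # an injected vertical oscillation appears only in y of AnkleLeft
  df <- tibble::as_tibble(rec)
  osc <- sin(2 * pi * (0:14) / 15) * 0.1
  df$y[df$joint == "AnkleLeft"] <- df$y[df$joint == "AnkleLeft"] + osc
  rec2 <- as_recording(df, "fix", "sit_to_stand")
  for (j in c("AnkleLeft", "AnkleRight", "Head")) {
    tr <- joint_track(rec2, j)
    expect_equal(var(tr$x), 0)
    expect_equal(var(tr$z), 0)
    if (j == "AnkleLeft") expect_gt(var(tr$y), 0) else expect_equal(var(tr$y), 0)
  }
})

test_that("millimetre files are converted to meters on read", {
  rec <- constant_recording(n = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path, "csv_long")
  lines <- readLines(path)
  body <- !grepl("^(#|timestamp)", lines)
  parts <- read.csv(text = lines[body], header = FALSE)
  parts[, 3:5] <- parts[, 3:5] * 1000
  writeLines(c(sub("units: m", "units: mm", lines[!body]),
               apply(parts, 1, paste, collapse = ",")), path)
  back <- read_recording(path, "csv_long")
  expect_equal(back$x, rec$x, tolerance = 1e-9)
})
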