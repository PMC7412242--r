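test_that("segmentation yields non-overlapping 640-sample windows and drops the remainder", {
  rec <- generate_record(synth_config(duration_s = 60, seed = 1))
  ws <- segment_windows(rec)
  expect_equal(ncol(ws$ppg), 640)
  expect_equal(n_windows(ws), 12)
  # conservation: windows plus remainder account for the whole record
  expect_true(n_windows(ws) * 640 <= length(rec$ppg))
  expect_lt(length(rec$ppg) - n_windows(ws) * 640, 640)
  # windows tile the record contiguously
  expect_equal(ws$source$start_sample, (0:11) * 640 + 1)
  expect_equal(ws$abp[3, ], rec$abp[1281:1920])

  short <- generate_record(synth_config(duration_s = 4.9, seed = 1))
  expect_equal(n_windows(segment_windows(short)), 0)
})

test_that("range filter flags windows with any ABP sample outside the gate", {
  ws <- flat_window_set(10)
  ws$abp[2, 100] <- 260
  ws$abp[5, 1] <- 255
  ws$abp[9, 640] <- 5
  out <- range_filter(ws, 10, 250)
  expect_equal(sum(out$quality_flag == "rejected_range"), 3)
  expect_equal(n_windows(clean_windows(out)), 7)
  expect_equal(attr(out, "counts")[["kept"]], 7)
  expect_error(range_filter(ws, 250, 10), "lo")
})

test_that("quality filter rejects flatline and implausible pulse-pressure windows", {
  ws <- flat_window_set(6)
  ws$abp[1, ] <- 100            # flatline ABP
  ws$ppg[2, ] <- 0.5            # flatline PPG
  ws$abp[3, ] <- ws$abp[3, ] + c(0, 200, rep(0, 638))  # pulse pressure > 150
  out <- quality_filter(ws)
  expect_equal(which(out$quality_flag == "rejected_quality"), c(1L, 2L, 3L))
  expect_equal(n_windows(clean_windows(out)), 3)
})

test_that("filter order does not change flag assignment", {
  ws <- flat_window_set(5)
  ws$abp[1, ] <- 300            # out of range AND flatline
  ws$abp[2, ] <- 100            # flatline only
  ws$abp[3, 7] <- 260           # range only
  a <- quality_filter(range_filter(ws))
  b <- range_filter(quality_filter(ws))
  expect_identical(a$quality_flag, b$quality_flag)
  expect_equal(a$quality_flag[1:3],
               c("rejected_range", "rejected_quality", "rejected_range"))
})

test_that("injected artifacts are rejected at about the configured rate", {
  cfg <- synth_config(duration_s = 250, artifact_fraction = 0.14, seed = 17)
  ws <- segment_cohort(generate_cohort(4, cfg))
  ws <- quality_filter(range_filter(ws))
  frac <- mean(ws$quality_flag != "clean")
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.18)
})

test_that("train/test split follows the floor convention and is reproducible", {
  ws <- flat_window_set(1000)
  sp <- split_windows(ws, 0.85, seed = 5)
  expect_equal(n_windows(sp$train), 850)
  expect_equal(n_windows(sp$test), 150)
  sp2 <- split_windows(ws, 0.85, seed = 5)
  expect_identical(sp$train$source, sp2$train$source)

  # floor convention on a non-exact fraction: 7 * 0.85 = 5.95 -> 5 train
  sp3 <- split_windows(flat_window_set(7), 0.85, seed = 1)
  expect_equal(n_windows(sp3$train), 5)
  expect_equal(n_windows(sp3$test), 2)

  # disjoint by provenance
  key <- function(ws) paste(ws$source$subject_id, ws$source$start_sample)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)

  expect_error(split_windows(ws, 1.2, seed = 1), "train_fraction")
  expect_error(split_windows(flat_window_set(1), 0.85, 1), "at least 2")
})

test_that("PPG normalization is min-max to [0,1] and exactly invertible", {
  ws <- flat_window_set(4)
  ws$ppg[] <- runif(length(ws$ppg), 0.1, 0.9)
  ws$ppg[1, 1] <- 0.1
  ws$ppg[1, 2] <- 0.9
  norm <- fit_normalizer(ws)
  scaled <- normalize_windows(ws$ppg, norm)
  expect_equal(range(scaled), c(0, 1))
  expect_equal((0.5 - norm$ppg_min) / (norm$ppg_max - norm$ppg_min),
               normalize_windows(matrix(0.5), norm)[1, 1])
  expect_equal(normalize_windows(matrix(0.5), norm)[1, 1], 0.5)
  expect_equal(denormalize_ppg(scaled, norm), ws$ppg, tolerance = 1e-14)

  # ABP is left untouched by design
  nws <- normalize_windows(ws, norm)
  expect_identical(nws$abp, ws$abp)

  degenerate <- flat_window_set(2)
  degenerate$ppg[] <- 1
  expect_error(fit_normalizer(degenerate), "degenerate")
})
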