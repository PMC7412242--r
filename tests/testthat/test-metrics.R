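test_that("error metrics match hand-computed worked examples", {
  x <- c(100, 110)
  y <- c(102, 106)
  expect_equal(mae(x, y), 3.0)
  expect_equal(rmse(x, y), sqrt(10))
  expect_equal(mae(x, x), 0)
  expect_equal(rmse(x, x), 0)
  # bias-only: RMSE equals the offset
  expect_equal(rmse(x, x + 7), 7)
  # homogeneity: scaling both series scales MAE
  expect_equal(mae(3 * x, 3 * y), 3 * mae(x, y))
  expect_error(mae(numeric(), numeric()), "at least")
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("pearson correlation is standard product-moment in [-1, 1]", {
  x <- c(1, 3, 7, 2, 9)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, 2 * x + 5), 1)  # affine invariance
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r(1, 2), "at least 2")
})

test_that("metrics agree with brute-force summation oracles on random series", {
  withr::with_seed(101, {
    for (rep in 1:1000) {
      n <- sample(2:30, 1)
      x <- rnorm(n, 100, 20)
      y <- x + rnorm(n, 0, 5)
      # independent elementwise-loop oracles
      s_abs <- 0; s_sq <- 0
      for (i in seq_len(n)) {
        s_abs <- s_abs + abs(x[i] - y[i])
        s_sq <- s_sq + (x[i] - y[i])^2
      }
      expect_equal(mae(x, y), s_abs / n, tolerance = 1e-10)
      expect_equal(rmse(x, y), sqrt(s_sq / n), tolerance = 1e-10)
      num <- sum((x - mean(x)) * (y - mean(y)))
      den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(pearson_r(x, y), num / den, tolerance = 1e-10)
      expect_equal(pearson_r(x, y), stats::cor(x, y), tolerance = 1e-10)
      d <- y - x
      ba <- bland_altman(x, y)
      expect_equal(ba$mean_diff, mean(d), tolerance = 1e-10)
      expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / (n - 1)),
                   tolerance = 1e-10)
      expect_equal(ba$upper_loa, ba$mean_diff + 1.96 * ba$sd_diff,
                   tolerance = 1e-10)
      expect_gte(rmse(x, y) + 1e-12, mae(x, y))  # Jensen
    }
  })
})

test_that("SBP/DBP extraction takes the window max and min", {
  expect_equal(extract_sbp_dbp(c(80, 120, 80)),
               data.frame(sbp = 120, dbp = 80))
  expect_equal(extract_sbp_dbp(rep(100, 640)),
               data.frame(sbp = 100, dbp = 100))
  m <- rbind(c(70, 140, 90), c(60, 65, 64))
  expect_equal(extract_sbp_dbp(m)$sbp, c(140, 65))
  expect_equal(extract_sbp_dbp(m)$dbp, c(70, 60))
  expect_error(extract_sbp_dbp(numeric()), "empty")
})

test_that("noise-free generator windows reproduce annotated beat pressures", {
  cfg <- synth_config(duration_s = 30, noise_sd_ppg = 0, noise_sd_abp = 0,
                      drift_amplitude = 0, seed = 19)
  rec <- generate_record(cfg)
  ws <- segment_windows(rec)
  bp <- extract_sbp_dbp(ws$abp)
  # every window contains at least one complete beat at constant pressure
  expect_equal(bp$sbp, rep(120, n_windows(ws)), tolerance = 1e-12)
  expect_equal(bp$dbp, rep(80, n_windows(ws)), tolerance = 1e-12)
})

test_that("published Bland-Altman limits are reproduced from printed mean/SD", {
  tab <- published_bland_altman()
  for (i in seq_len(nrow(tab))) {
    lim <- loa_limits(tab$mean_diff[i], tab$sd_diff[i])
    expect_equal(lim$lower_loa, tab$lower[i], tolerance = 1e-3)
    expect_equal(lim$upper_loa, tab$upper[i], tolerance = 1e-3)
  }
})

test_that("bland_altman on identical series gives zero limits and the sign flips", {
  x <- c(100, 110, 120)
  ba <- bland_altman(x, x)
  expect_equal(c(ba$mean_diff, ba$sd_diff, ba$lower_loa, ba$upper_loa),
               rep(0, 4))
  y <- x + c(1, 2, 3)
  expect_equal(bland_altman(x, y)$mean_diff,
               -bland_altman(x, y, sign = "reference-estimate")$mean_diff)
})

test_that("evaluation bundle behaves on perfect, noisy and shuffled predictions", {
  withr::with_seed(23, {
    ref <- matrix(90 + 30 * abs(sin(outer(1:30, seq_len(640) / 50))), 30)
    ref <- ref + rnorm(30)  # per-window offsets so SBP/DBP vary
    ev <- evaluate_predictions(ref, ref)
    expect_equal(ev$waveform$r, 1)
    expect_equal(ev$sbp$mae, 0)
    expect_equal(ev$dbp$rmse, 0)

    sigma <- 2.5
    noisy <- ref + matrix(rnorm(length(ref), 0, sigma), nrow(ref))
    ev2 <- evaluate_predictions(noisy, ref)
    expect_equal(ev2$waveform$rmse, sigma, tolerance = 0.05)

    shuffled <- ref[sample(nrow(ref)), ]
    ev3 <- evaluate_predictions(shuffled, ref)
    expect_lt(abs(ev3$sbp$r), 0.5)

    expect_error(evaluate_predictions(ref[, 1:10], ref), "misaligned")
  })
})
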