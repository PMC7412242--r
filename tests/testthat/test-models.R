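test_that("canonical architectures land in the intended parameter bands", {
  ld <- count_params(ldcae_spec())
  ud <- count_params(udcae_spec())
  expect_gte(ld, 40000)
  expect_lte(ld, 80000)
  expect_gte(ud, 200000)
  expect_lte(ud, 400000)
  expect_equal(build_model(ldcae_spec())$n_params, ld)
  expect_equal(build_model(udcae_spec())$n_params, ud)
})

test_that("spec validation enforces family ladders and divisibility", {
  expect_error(dcae_spec(c(8L, 16L), 5L, FALSE, input_len = 641),
               "divisible")
  expect_error(dcae_spec(c(8L, 16L), 4L, FALSE), "odd")
  expect_error(dcae_spec(c(8L, 64L), 3L, TRUE, family = "ldcae"), "16")
  expect_error(dcae_spec(c(32L, 256L), 3L, FALSE, family = "udcae"), "32")
})

test_that("removing skips and shrinking the ladder degrades UDCAE to LDCAE topology", {
  degraded <- dcae_spec(c(16L, 32L, 64L), kernel_size = 11L,
                        skip_connections = FALSE, input_len = 640)
  expect_equal(ppgabp:::layer_dims(degraded),
               ppgabp:::layer_dims(ldcae_spec()))
  expect_equal(count_params(degraded), count_params(ldcae_spec()))
})

test_that("forward pass preserves window length for both families", {
  X <- matrix(0, 2, 640)
  for (spec in list(ldcae_spec(), udcae_spec())) {
    m <- build_model(spec, seed = 1)
    out <- ppgabp:::cpp_dcae_predict(m$spec, m$weights, X)
    expect_equal(dim(out), c(2, 640))
    expect_true(all(is.finite(out)))
  }
})

test_that("training memorizes a single repeated window", {
  rec <- generate_record(synth_config(duration_s = 40, noise_sd_ppg = 0,
                                      noise_sd_abp = 0, seed = 8))
  ws <- segment_windows(rec)[rep(1, 10)]
  split <- split_windows(ws, 0.8, seed = 1)
  m <- train_model(build_model(dcae_spec(c(8L, 16L), 9L, FALSE), seed = 2),
                   split, train_config(epochs = 200, batch_size = 8, seed = 2))
  expect_lt(tail(m$history$train_loss, 1), 2)  # mmHg^2, near-memorized
  expect_equal(nrow(m$history), 200)
})

test_that("prediction is deterministic, denormalized to mmHg, and shape-checked", {
  split <- noise_free_split()
  m <- train_model(build_model(tiny_spec(), seed = 4), split,
                   quick_config(epochs = 6, seed = 4))
  tw <- clean_windows(split$test)
  p1 <- predict(m, tw$ppg)
  p2 <- predict(m, tw$ppg)
  expect_identical(p1, p2)
  expect_equal(dim(p1), dim(tw$ppg))
  expect_gt(mean(p1), 40)  # plausible mmHg scale, not normalized units
  expect_error(predict(m, matrix(0, 2, 100)), "640")
  expect_error(predict(build_model(tiny_spec()), tw$ppg), "not trained")
})

test_that("checkpoint selects the best validation epoch", {
  split <- noise_free_split()
  m <- train_model(build_model(tiny_spec(), seed = 6), split,
                   quick_config(epochs = 10, seed = 6))
  expect_equal(m$best_epoch, which.min(m$history$val_loss))
  expect_lte(min(m$history$val_loss), tail(m$history$val_loss, 1))
})

test_that("skip-connected model converges faster at a fixed small budget", {
  split <- noise_free_split()
  cfg <- train_config(epochs = 8, batch_size = 16, seed = 1)
  ud <- train_model(build_model(udcae_spec(), seed = 1), split, cfg)
  ld <- train_model(build_model(ldcae_spec(), seed = 1), split, cfg)
  expect_lte(min(ud$history$val_loss), min(ld$history$val_loss))
})

test_that("training errors on empty or degenerate input", {
  split <- noise_free_split()
  empty <- split
  empty$train <- split$train[integer()]
  expect_error(train_model(build_model(tiny_spec()), empty), "empty")
  expect_error(train_config(epochs = 0), ">= 1")
})
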