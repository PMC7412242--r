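test_that("fitness equals the mean of SBP and DBP correlations on toy tables", {
  toy <- toy_candidates(seed = 7, n = 25, len = 64, m = 3)
  input <- fitness_input_from_predictions(toy$stack, toy$ref)
  ref_bp <- extract_sbp_dbp(toy$ref)
  for (bits in list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))) {
    sel <- which(bits == 1)
    avg <- apply(toy$stack[, , sel, drop = FALSE], c(1, 2), mean)
    bp <- extract_sbp_dbp(avg)
    manual <- 0.5 * (pearson_r(ref_bp$sbp, bp$sbp) +
                       pearson_r(ref_bp$dbp, bp$dbp))
    expect_equal(ga_fitness(bits, input), manual, tolerance = 1e-12)
  }
  # all-zero chromosome is invalid and gets the worst fitness
  expect_equal(ga_fitness(c(0, 0, 0), input), -1)
})

test_that("perfect predictions give fitness 1; opposed correlations cancel to 0", {
  fx <- make_fixtures(seed = 5)
  input <- fitness_input_from_predictions(fx$pred_tables, fx$ref_abp)
  expect_equal(ga_fitness(c(1, 0, 0), input), 1, tolerance = 1e-12)
  expect_lt(ga_fitness(c(0, 1, 0), input), 1)

  # constant prediction windows [i, i]: SBP tracks the reference (r = 1),
  # DBP anti-tracks it (r = -1), so the average cancels
  n <- 10
  ref <- cbind(1:n, -(1:n))
  pred <- array(cbind(1:n, 1:n), dim = c(n, 2, 1))
  inp <- fitness_input_from_predictions(pred, ref)
  expect_equal(ga_fitness(1, inp), 0, tolerance = 1e-12)
})

test_that("single- and two-member ensembles combine predictions as means", {
  split <- noise_free_split()
  cfg <- quick_config(epochs = 4)
  m1 <- train_model(build_model(tiny_spec(), seed = 1), split, cfg)
  m2 <- train_model(build_model(tiny_spec(), seed = 2), split, cfg)
  tw <- clean_windows(split$test)
  p1 <- predict(m1, tw$ppg)
  p2 <- predict(m2, tw$ppg)
  expect_equal(ensemble_predict(list(m1), tw$ppg), p1)
  expect_equal(ensemble_predict(list(m1, m2), tw$ppg), (p1 + p2) / 2)
  expect_error(ensemble_predict(list(), tw$ppg), "empty")
})

test_that("exhaustive search matches hand enumeration on three candidates", {
  toy <- toy_candidates(seed = 31, n = 20, len = 64, m = 3)
  input <- fitness_input_from_predictions(toy$stack, toy$ref)
  subsets <- list(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,0,1),
                  c(0,1,1), c(1,1,1))
  fits <- vapply(subsets, ga_fitness, 0, input = input)
  best <- exhaustive_best(input)
  expect_equal(best$best_fitness, max(fits), tolerance = 1e-14)
  expect_equal(best$best_bits, subsets[[which.max(fits)]])
  # single candidate -> that candidate
  one <- fitness_input_from_predictions(toy$stack[, , 1, drop = FALSE],
                                        toy$ref)
  expect_equal(exhaustive_best(one)$selected, 1L)
  big <- list(pred_stack = array(0, c(2, 2, 26)))
  expect_error(exhaustive_best(big), "25")
})

test_that("best-ever fitness is non-decreasing and ordering-invariant", {
  toy <- toy_candidates(seed = 13, n = 30, len = 64, m = 6)
  input <- fitness_input_from_predictions(toy$stack, toy$ref)
  res <- evolve_ga(input, ga_config(population_size = 12, generations = 60,
                                    seed = 2))
  expect_true(all(diff(res$trace) >= 0))
  # fitness depends on the selected set, not on candidate ordering
  perm <- c(4, 1, 6, 2, 5, 3)
  permuted <- fitness_input_from_predictions(toy$stack[, , perm], toy$ref)
  bits <- c(1, 0, 1, 0, 0, 1)
  expect_equal(ga_fitness(bits, input),
               ga_fitness(bits[perm], permuted), tolerance = 1e-14)
})

test_that("zero generations scores only the initial random population", {
  toy <- toy_candidates(seed = 3, n = 15, len = 64, m = 4)
  input <- fitness_input_from_predictions(toy$stack, toy$ref)
  res <- evolve_ga(input, ga_config(population_size = 8, generations = 0,
                                    seed = 9))
  expect_length(res$trace, 0)
  pop_fits <- withr::with_seed(9L, {
    pop <- matrix(sample(0:1, 8 * 4, replace = TRUE), nrow = 8)
    apply(pop, 1, ga_fitness, input = input)
  })
  expect_equal(res$best_fitness, max(pop_fits))
  expect_error(ga_config(population_size = 1), "population_size")
})

test_that("a planted exact model is recovered by the search", {
  withr::with_seed(41, {
    n <- 30; len <- 64
    ref <- matrix(100 + 20 * sin(outer(1:n, 1:len / 9)), n) + rnorm(n)
    stack <- array(rnorm(n * len * 5, 100, 15), dim = c(n, len, 5))
    stack[, , 3] <- ref  # the planted optimum
    input <- fitness_input_from_predictions(stack, ref)
    res <- evolve_ga(input, ga_config(population_size = 16,
                                      generations = 120, seed = 1))
    expect_true(3 %in% res$selected)
    expect_gt(res$best_fitness, 0.999)
  })
})
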