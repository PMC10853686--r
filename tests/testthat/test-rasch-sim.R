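test_that("PCM category probabilities match direct enumeration and normalize", {
  # dichotomous item at its difficulty point: (0.5, 0.5)
  expect_equal(pcm_category_probabilities(0, pcm_item(0)), c(0.5, 0.5))
  expect_equal(pcm_category_probabilities(1.3, pcm_item(1.3)), c(0.5, 0.5))

  # 4-category item, theta 0, delta 0, tau (-1, 0, 1): unnormalized terms are
  # exp(0), exp(1), exp(1), exp(0) by direct evaluation of the step sums
  p <- pcm_category_probabilities(0, pcm_item(0, c(-1, 0, 1)))
  expect_equal(p, c(1, exp(1), exp(1), 1) / (2 + 2 * exp(1)), tolerance = 1e-12)

  # normalization holds over random parameters and abilities (property)
  for (seed in 1:20) {
    pars <- withr::with_seed(seed, {
      m <- sample(1:4, 1)
      tau <- rnorm(m); tau <- tau - mean(tau)
      list(item = pcm_item(rnorm(1, 0, 2), tau), theta = rnorm(5, 0, 3))
    })
    P <- pcm_category_probabilities(pars$theta, pars$item)
    expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("pcm_item enforces the threshold centering convention", {
  expect_error(pcm_item(0, c(1, 1)), "sum to zero")
  expect_no_error(pcm_item(0, c(-1, 1)))
})

test_that("response simulation is seed-deterministic and respects limits", {
  items <- make_item_bank(10, seed = 1)
  th <- withr::with_seed(2, rnorm(50))
  a <- simulate_responses(items, th, seed = 42)
  b <- simulate_responses(items, th, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_responses(items, th, seed = 43)))
  expect_true(all(a %in% 0:3))
  expect_equal(dim(a), c(50, 10))

  # limit behavior: ability far above all difficulties -> top category
  top <- simulate_responses(items, rep(10, 200), seed = 1)
  expect_gt(mean(top == 3), 0.999)

  # binomial bound: dichotomous item at theta = delta = 0, 2000 persons,
  # pass rate within 3 binomial SEs of 0.5
  X <- simulate_responses(list(pcm_item(0)), rep(0, 2000), seed = 9)
  expect_lt(abs(mean(X) - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("response matrices round-trip through CSV with blank missing cells", {
  items <- make_item_bank(5, seed = 3)
  X <- simulate_responses(items, withr::with_seed(4, rnorm(20)), seed = 5,
                          missing_rate = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_matrix(X, path)
  expect_true(any(grepl(",,", readLines(path))))  # blank = missing
  back <- read_response_matrix(path)
  expect_equal(unname(back), unname(X))
})

test_that("calibration recovers two-item difficulties and symmetry", {
  items <- lapply(c(-1, 1), pcm_item)
  th <- withr::with_seed(11, rnorm(4000))
  X <- simulate_responses(items, th, seed = 12)
  cal <- calibrate_pcm(X, n_categories = 2)
  expect_true(cal$converged)
  expect_equal(unname(cal$difficulty), c(-1, 1), tolerance = 0.15)
  expect_equal(sum(cal$difficulty), 0, tolerance = 1e-9)

  # perfectly symmetric two-item data -> difficulties symmetric about zero
  Xs <- rbind(matrix(c(1L, 0L), 500, 2, byrow = TRUE),
              matrix(c(0L, 1L), 500, 2, byrow = TRUE),
              matrix(c(1L, 1L), 200, 2, byrow = TRUE),
              matrix(c(0L, 0L), 200, 2, byrow = TRUE))
  cs <- calibrate_pcm(Xs, n_categories = 2)
  expect_equal(unname(cs$difficulty[1]), -unname(cs$difficulty[2]),
               tolerance = 1e-9)
})

test_that("degenerate calibration inputs are flagged or rejected", {
  items <- make_item_bank(4, seed = 6)
  X <- simulate_responses(items, withr::with_seed(7, rnorm(200)), seed = 8)
  X[, 2] <- 0L  # an all-one-category item
  expect_warning(cal <- calibrate_pcm(X, n_categories = 4), "inestimable")
  expect_equal(cal$inestimable, 2L)
  expect_true(is.na(cal$difficulty[2]))
  expect_true(all(!is.na(cal$difficulty[-2])))

  expect_error(calibrate_pcm(matrix(integer(0), 0, 0)), "empty")
})

test_that("calibration recovery: 66 items x 500 persons, MAE below 0.2 logits", {
  n_seeds <- 20
  maes <- vapply(seq_len(n_seeds), function(s) {
    items <- make_item_bank(66, seed = 1000 + s)
    truth <- item_difficulties(items)
    th <- withr::with_seed(2000 + s, rnorm(500))
    X <- simulate_responses(items, th, seed = 3000 + s)
    cal <- calibrate_pcm(X, n_categories = 4)
    mean(abs(cal$difficulty - (truth - mean(truth))))
  }, numeric(1))
  expect_lt(mean(maes), 0.2)
  expect_equal(length(maes), n_seeds)
})

test_that("person ability estimation honors the score equation", {
  # single item passed: no finite MLE
  est <- estimate_person_ability(1L, list(pcm_item(0)))
  expect_true(est$extreme)
  expect_equal(est$theta, Inf)
  est0 <- estimate_person_ability(0L, list(pcm_item(0)))
  expect_true(est0$extreme)
  expect_equal(est0$theta, -Inf)

  # two dichotomous items at (-1, +1), one pass one fail: theta-hat = 0 by
  # symmetry of the score equation (brute-force likelihood grid agrees)
  items2 <- lapply(c(-1, 1), pcm_item)
  est2 <- estimate_person_ability(c(1L, 0L), items2)
  expect_false(est2$extreme)
  expect_equal(est2$theta, 0, tolerance = 1e-6)
  grid <- seq(-3, 3, by = 0.001)
  ll <- vapply(grid, function(t) {
    log(pcm_category_probabilities(t, items2[[1]])[2]) +
      log(pcm_category_probabilities(t, items2[[2]])[1])
  }, numeric(1))
  expect_equal(grid[which.max(ll)], 0, tolerance = 0.01)

  # recovery at theta = 1 over 50 dichotomous items
  items50 <- lapply(seq(-2, 2, length.out = 50), pcm_item)
  X <- simulate_responses(items50, rep(1, 1), seed = 7)
  est50 <- estimate_person_ability(X[1, ], items50)
  expect_equal(est50$theta, 1, tolerance = 0.5)
})

test_that("logit rescaling maps endpoints and preserves order", {
  expect_equal(rescale_logits(c(-2, 0, 2), 0, 100), c(0, 50, 100))
  expect_equal(rescale_logits(c(-1, 3), 10, 20), c(10, 20))
  x <- withr::with_seed(5, rnorm(30))
  y <- rescale_logits(x, 0, 100)
  expect_equal(order(x), order(y))
  expect_error(rescale_logits(rep(1, 5)), "constant")
})

test_that("synthetic difficulty generation follows the equation plus seeded noise", {
  eq <- published_equation()
  tab <- gmfm_ratings()

  # noiseless: exactly the predictions for every bundled item
  d0 <- generate_difficulty_dataset(eq, tab, noise_sd = 0)
  expect_equal(d0$observed_difficulty, predict_difficulty(eq, tab))
  expect_equal(d0$observed_difficulty[tab$item_number == 2], 14.13,
               tolerance = 1e-12)
  expect_equal(d0$observed_difficulty[tab$item_number == 69], 61.88,
               tolerance = 1e-12)

  # determinism and seed sensitivity
  a <- generate_difficulty_dataset(eq, tab, noise_sd = 6.09, seed = 1)
  expect_identical(a, generate_difficulty_dataset(eq, tab, noise_sd = 6.09,
                                                  seed = 1))
  expect_false(identical(a$observed_difficulty,
                         generate_difficulty_dataset(eq, tab, 6.09, 2)$observed_difficulty))

  # law of large numbers: per-item replicate mean converges to the prediction
  n_rep <- 400
  item2 <- vapply(seq_len(n_rep), function(s) {
    generate_difficulty_dataset(eq, tab, 6.09, seed = 90000 + s)$observed_difficulty[1]
  }, numeric(1))
  mc_se <- 6.09 / sqrt(n_rep)
  expect_lt(abs(mean(item2) - 14.13), 3 * mc_se)

  expect_error(generate_difficulty_dataset(eq, tab, noise_sd = -1), "non-negative")
  expect_error(generate_difficulty_dataset(eq, tab, noise_sd = 1), "seed")
})

test_that("calibrated difficulties carry the generating structure through to the regression", {
  # duality: simulate PCM data whose item difficulties are an affine image of
  # the specification-equation predictions, calibrate, rescale, regress on
  # the bundled ratings -- fitted coefficients must correlate positively with
  # the generating ones.
  tab <- gmfm_ratings()
  eq <- published_equation()
  pred <- predict_difficulty(eq, tab)
  delta <- (pred - mean(pred)) / sd(pred) * 1.5
  items <- lapply(seq_along(delta), function(i) pcm_item(delta[i], c(-0.5, 0, 0.5)))
  th <- withr::with_seed(21, rnorm(500))
  X <- simulate_responses(items, th, seed = 22)
  cal <- calibrate_pcm(X, n_categories = 4)
  expect_true(cal$converged)

  observed <- rescale_logits(cal$difficulty, 0, 100)
  fit <- forward_stepwise_fit(unname(observed), tab)
  expect_gt(cor(c(fit$equation$coefficients), c(eq$coefficients)), 0)
  expect_true(all(fit$equation$coefficients[fit$report$step_trace$term] > 0))
  expect_gt(fit$report$adjusted_r2, 0.5)
})
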