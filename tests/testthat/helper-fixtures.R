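# Shared generators for the test suite. All randomness is seeded through
# withr so tests are reproducible and leave the global RNG untouched.

# A bank of 4-category PCM items with difficulties spread over [-2, 2].
make_item_bank <- function(n_items, seed, thresholds = c(-0.7, 0, 0.7)) {
  delta <- withr::with_seed(seed, stats::runif(n_items, -2, 2))
  lapply(seq_len(n_items), function(i) {
    pcm_item(delta[i], thresholds, name = paste0("i", i))
  })
}

item_difficulties <- function(items) {
  vapply(items, function(it) it$difficulty, numeric(1))
}

# Small random regression design for OLS oracle checks.
make_small_design <- function(n, seed) {
  withr::with_seed(seed, {
    X <- cbind(1, matrix(stats::rnorm(n * 3), n, 3))
    beta <- stats::rnorm(4)
    y <- drop(X %*% beta) + stats::rnorm(n, 0, 0.5)
    list(X = X, y = y, beta = beta)
  })
}

# Normal-equations OLS solve: the independent oracle for lm-based fits.
ols_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

ratings_df <- function(bp, mv, sp) {
  data.frame(body_position = bp, movement = mv, support = sp)
}
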