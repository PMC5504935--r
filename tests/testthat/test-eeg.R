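make_raw <- function(samples) raw_eeg(samples)

test_that("the band-pass keeps 10 Hz and rejects DC and 100 Hz", {
  t <- seq(0, 40, by = 1e-3)
  n <- length(t)
  mid <- floor(n / 3):floor(2 * n / 3)
  base <- matrix(0, 30, n)
  base[1, ] <- 1                     # DC
  base[2, ] <- sin(2 * pi * 10 * t)  # in band
  base[3, ] <- sin(2 * pi * 100 * t) # out of band
  filt <- bandpass_filter(make_raw(base))$samples
  expect_lt(max(abs(filt[1, mid])), 0.05)
  expect_gt(max(abs(filt[2, mid])), 0.9)
  expect_lt(max(abs(filt[2, mid])), 1.1)
  expect_lt(max(abs(filt[3, mid])), 0.1)
  expect_error(bandpass_filter(make_raw(matrix(0, 30, 50))),
               class = "too_short")
})

test_that("epoch features are 450-long, mean-free and onset-locked", {
  set.seed(8)
  samples <- matrix(rnorm(30 * 3000), 30)
  samples[3, ] <- 4.2  # constant channel
  raw <- make_raw(samples)
  f <- extract_features(raw, 1000)
  expect_length(f, 450)
  # channel 3 contributes 15 exact zeros after mean removal
  expect_equal(f[(2 * 15 + 1):(3 * 15)], rep(0, 15))
  # shifting recording and onset together leaves features identical
  pad <- matrix(rnorm(30 * 250), 30)
  raw_shift <- make_raw(cbind(pad, samples))
  expect_identical(extract_features(raw_shift, 1250), f)
  # plain subsampling keeps the length contract
  expect_length(extract_features(raw, 1000, decimate = "subsample"), 450)
  expect_error(extract_features(raw, 2500), class = "out_of_range")
  expect_error(extract_features(raw, 0), class = "out_of_range")
})

test_that("the discriminant separates well-separated classes", {
  set.seed(21)
  n <- 200
  xp <- matrix(rnorm(n * 8, 5), n)   # means 10 sd apart
  xm <- matrix(rnorm(n * 8, -5), n)
  x <- rbind(xp, xm); y <- rep(c(1, -1), each = n)
  m <- train_flda(x, y)
  expect_equal(mean(sign(predict(m, x)) == y), 1)
  # 1-D Fisher direction points toward the larger mean
  m1 <- train_flda(matrix(c(rnorm(50, 2), rnorm(50, -2))), rep(c(1, -1), each = 50))
  expect_gt(m1$weights, 0)
  # identical classes: near-zero separation but finite weights via shrinkage
  same <- matrix(rnorm(100 * 4), 100)
  m0 <- train_flda(rbind(same, same), rep(c(1, -1), each = 100))
  expect_true(all(is.finite(m0$weights)))
  expect_lt(abs(mean(predict(m0, same))), 1)
  expect_error(train_flda(x, rep(1, 2 * n)), class = "single_class")
  expect_error(train_flda(x, y[-1]), class = "dim_mismatch")
})

test_that("the discriminant matches the generalized-eigenvector solution", {
  set.seed(31)
  n <- 120
  xp <- matrix(rnorm(n * 6), n) %*% diag(c(3, 1, 2, 1, 1, 2)) +
    matrix(rep(c(1, 2, 0, -1, 0.5, 0), each = n), n)
  xm <- matrix(rnorm(n * 6), n) %*% diag(c(1, 2, 1, 3, 1, 1))
  x <- rbind(xp, xm); y <- rep(c(1, -1), each = n)
  m <- train_flda(x, y, shrinkage = 0)
  # brute force: leading eigenvector of Sw^{-1} Sb
  mup <- colMeans(xp); mum <- colMeans(xm)
  sw <- (crossprod(sweep(xp, 2, mup)) + crossprod(sweep(xm, 2, mum))) / (2 * n - 2)
  sb <- outer(mup - mum, mup - mum)
  ev <- eigen(solve(sw) %*% sb)
  v <- Re(ev$vectors[, 1])
  cosang <- abs(sum(v * m$weights)) /
    sqrt(sum(v^2) * sum(m$weights^2))
  expect_equal(cosang, 1, tolerance = 1e-6)
})

test_that("row/column argmax picks the attended cell", {
  sc <- data.frame(kind = rep(c("row", "column"), each = 3),
                   index = rep(0:2, 2),
                   score = c(2, -1, -1, -1, 3, -1))
  expect_equal(classify_repetition(sc), "O2")
  sc$score <- rep(0, 6)
  expect_equal(classify_repetition(sc), "O1")  # ties to lowest indices
  expect_error(classify_repetition(sc[-1, ]), class = "wrong_count")
  # trial-level aggregation sums over repetitions before the argmax
  two_reps <- rbind(transform(sc, score = c(1, 0, 0, 0, 0, 2)),
                    transform(sc, score = c(1, 0, 0, 0, 0, 1)))
  expect_equal(classify_trial(two_reps), "O3")
})

test_that("online voting takes the majority, scores break 3-way ties", {
  expect_equal(vote_online(c("O1", "O1", "O3")), "O1")
  expect_equal(vote_online(c("O2", "O2", "O2")), "O2")
  fallback <- data.frame(kind = rep(c("row", "column"), each = 3),
                         index = rep(0:2, 2),
                         score = c(0, 5, 0, 0, 4, 0))  # favors row 1, col 1
  expect_equal(vote_online(c("O1", "O5", "O9"), fallback), "O5")
  expect_error(vote_online(c("O1", "O2")), class = "wrong_count")
})

test_that("selection accuracy is a half-up percentage", {
  expect_equal(session_accuracy(c(rep("O1", 17), "O2"), rep("O1", 18)), 94.44)
  expect_equal(session_accuracy(rep("O3", 18), rep("O3", 18)), 100)
  expect_equal(mean_accuracy(c(94.44, 100, 100, 100, 94.44, 100)), 98.15)
  expect_error(session_accuracy(character(0), character(0)),
               class = "empty_results")
})

test_that("models survive the flat text round trip", {
  set.seed(5)
  m <- train_flda(matrix(rnorm(80 * 5), 80), rep(c(1, -1), 40))
  path <- tempfile(fileext = ".txt")
  write_flda(m, path)
  back <- read_flda(path)
  expect_equal(back$weights, m$weights)
  expect_equal(back$bias, m$bias)
  expect_equal(back$shrinkage, m$shrinkage)
})
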