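mk_traj <- function(roll, pitch, yaw, rate = 250) {
  n <- max(length(roll), length(pitch), length(yaw))
  new_euler_trajectory(
    tibble::tibble(t_s = (seq_len(n) - 1) / rate,
                   roll_deg = rep_len(roll, n), pitch_deg = rep_len(pitch, n),
                   yaw_deg = rep_len(yaw, n)),
    rate = rate, frame = "lab")
}

test_that("RMSE of identical and constant-offset trajectories", {
  a <- mk_traj(rnorm(100), rnorm(100), rnorm(100))
  r0 <- rmse_per_angle(a, a)
  expect_equal(c(r0$roll, r0$pitch, r0$yaw), c(0, 0, 0))
  b <- a
  b$pitch_deg <- b$pitch_deg + 3
  r3 <- rmse_per_angle(b, a)
  expect_equal(c(r3$roll, r3$pitch, r3$yaw), c(0, 3, 0), tolerance = 1e-12)
  expect_error(rmse_per_angle(a, a[1:50, ]), "equal length")
})

test_that("RMSE matches the brute-force loop oracle on random pairs", {
  set.seed(99)
  worst <- 0
  for (case in 1:50) {
    n <- sample(50:200, 1)
    a <- mk_traj(runif(n, -180, 180), runif(n, -180, 180), runif(n, -180, 180))
    b <- mk_traj(runif(n, -180, 180), runif(n, -180, 180), runif(n, -180, 180))
    fast <- rmse_per_angle(a, b)
    for (ch in c("roll", "pitch", "yaw")) {
      acc <- 0
      col <- paste0(ch, "_deg")
      for (i in seq_len(n)) {       # naive loop with explicit wrapping
        d <- a[[col]][i] - b[[col]][i]
        while (d > 180) d <- d - 360
        while (d <= -180) d <- d + 360
        acc <- acc + d^2
      }
      worst <- max(worst, abs(fast[[ch]] - sqrt(acc / n)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("RMSE wraps differences across the 180-degree seam", {
  a <- mk_traj(0, 0, rep(-179, 50))
  b <- mk_traj(0, 0, rep(179, 50))
  expect_equal(rmse_per_angle(a, b)$yaw, 2, tolerance = 1e-12)
})

test_that("gimbal fraction counts reference samples near the singularity", {
  ref <- mk_traj(c(rep(0, 60), rep(88, 40)), 0, 0)
  r <- rmse_per_angle(ref, ref)
  expect_equal(r$gimbal_fraction, 0.4)
  r2 <- rmse_per_angle(ref, ref, validation_config(gimbal_gate = 89))
  expect_equal(r2$gimbal_fraction, 0)
})

test_that("z-score outlier exclusion matches the direct computation", {
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
  ## zero spread: everything kept
  ex <- exclude_outliers(c(5, 5, 5, 5))
  expect_equal(ex$kept, c(5, 5, 5, 5))
  expect_length(ex$excluded, 0)
  ## the documented example: 40 excluded iff |z| > 1.96 on the raw set
  v <- c(2, 3, 2.5, 3.5, 40)
  z <- (v - mean(v)) / sd(v)
  ex2 <- exclude_outliers(v)
  expect_identical(ex2$excluded, v[abs(z) > 1.96])
  expect_equal(ex2$mean, mean(v[abs(z) <= 1.96]))
  ## randomized agreement with the oracle
  set.seed(7)
  for (case in 1:200) {
    v <- rnorm(sample(3:30, 1), 10, sample(c(0.1, 1, 5), 1))
    if (stats::runif(1) < 0.3) v[1] <- v[1] + 50
    z <- (v - mean(v)) / sd(v)
    ex <- exclude_outliers(v)
    expect_identical(ex$kept, v[abs(z) <= 1.96])
  }
})

test_that("accuracy categories follow the 5/10 degree boundaries", {
  expect_identical(classify_rmse(c(0, 4.9, 5, 7, 10, 10.01, 40)),
                   c("excellent", "excellent", "good", "good", "good",
                     "unacceptable", "unacceptable"))
  expect_error(classify_rmse(-1), "negative")
  ## boundaries are configuration-visible
  cfg <- validation_config(excellent_max = 2, good_max = 4)
  expect_identical(classify_rmse(3, cfg), "good")
})

test_that("summaries aggregate cells and flag exclusions", {
  ## single recording: mean equals the value, SD 0
  one <- tibble::tibble(placement = "C", movement = "squat", recording = 1,
                        roll = 1.5, pitch = 2.5, yaw = 6)
  rep1 <- summarize_validation(one)
  expect_equal(nrow(rep1), 3L)
  expect_equal(rep1$sd, rep(0, 3))
  expect_identical(rep1$category[rep1$angle == "yaw"], "good")

  ## 22-recording cohort with one corrupted member
  set.seed(12)
  coh <- tidyr::expand_grid(placement = "C", movement = "squat",
                            recording = 1:22)
  coh$roll <- rnorm(22, 2, 0.2); coh$pitch <- rnorm(22, 3, 0.2)
  coh$yaw <- rnorm(22, 4, 0.3)
  coh[22, c("roll", "pitch", "yaw")] <- as.list(c(60, 70, 80))
  rep22 <- summarize_validation(coh)
  expect_true(all(rep22$n_excluded == 1L))
  expect_true(all(rep22$n_included == 21L))
  expect_equal(rep22$rmse_mean[rep22$angle == "roll"], 2, tolerance = 0.2)
  ## category consistent with the kept-set mean
  expect_identical(rep22$category,
                   unname(classify_rmse(rep22$rmse_mean)))
})

test_that("summary means track the noise-implied RMSE on a synthetic cohort", {
  ## per-recording RMSE of N(0, sigma) angle noise concentrates near sigma
  set.seed(5)
  sigma <- 1.5
  n_samp <- 2000
  vals <- replicate(22, sqrt(mean(rnorm(n_samp, 0, sigma)^2)))
  coh <- tibble::tibble(placement = "C", movement = "squat", recording = 1:22,
                        roll = vals, pitch = vals, yaw = vals)
  rep <- summarize_validation(coh)
  mc_err <- 3 * sigma / sqrt(2 * n_samp * 22)
  expect_lt(abs(rep$rmse_mean[1] - sigma), mc_err + 0.01)
})

test_that("added noise never decreases expected RMSE", {
  base <- mk_traj(rnorm(400), rnorm(400), rnorm(400))
  sigmas <- c(0, 0.5, 1, 2, 4)
  mean_rmse <- vapply(sigmas, function(s) {
    mean(vapply(1:5, function(k) {
      set.seed(1000 + 10 * s + k)
      noisy <- base
      noisy$pitch_deg <- noisy$pitch_deg + rnorm(400, 0, s)
      rmse_per_angle(noisy, base)$pitch
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rmse) > 0))
})

test_that("the report grid renders categories and missing cells", {
  rows <- tibble::tibble(
    placement = rep(c("C", "LW"), each = 3),
    movement = "squat", recording = 1,
    angle = rep(c("roll", "pitch", "yaw"), 2),
    rmse = c(1, 2, 3, 6, 11, 2))
  rep <- summarize_validation(rows)
  grid <- margsense:::format_validation_grid(rep)
  expect_length(grid, 3L)   # header + 2 placements
  expect_match(grid[1], "squat/roll")
  expect_match(grid[grepl("^LW", grid)], "11.0 \\(0.0\\) U")
})
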