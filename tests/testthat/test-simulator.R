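test_that("drift-scale mixture allocates 60/40 with R = 10 raters", {
  params <- draw_parameters(5, 10, 3, 5, seed = 61)
  comp <- attr(params, "sigma_component")
  expect_identical(sum(comp == "stable"), 6L)
  expect_identical(sum(comp == "drifting"), 4L)
  # floor rule at R not divisible: R = 7 -> floor(4.2) = 4 stable
  comp7 <- attr(draw_parameters(5, 7, 3, 5, seed = 62), "sigma_component")
  expect_identical(sum(comp7 == "stable"), 4L)
})

test_that("drawn parameters satisfy the model invariants", {
  for (seed in 63:67) {
    p <- draw_parameters(7, 4, 3, 5, seed = seed)
    expect_true(all(p$sigma > 0))
    expect_true(all(p$d[, 1] == 0))
    expect_equal(rowSums(p$d[, -1]), rep(0, 4), tolerance = 1e-12)
  }
})

test_that("abilities are standard normal in distribution", {
  p <- draw_parameters(1e5, 2, 2, 5, seed = 68)
  expect_lt(abs(mean(p$theta)), 0.01)
  expect_lt(abs(var(p$theta) - 1), 0.02)
})

test_that("fully crossed design covers every cell with even time blocks", {
  des <- fully_crossed_design(6, 5, T = 1, seed = 71)
  expect_identical(nrow(des), 30L)
  expect_identical(nrow(unique(des[c("examinee", "rater")])), 30L)
  expect_true(all(des$time == 1L))

  des2 <- fully_crossed_design(134, 3, T = 4, seed = 72)
  for (r in 1:3) {
    sizes <- sort(table(des2$time[des2$rater == r]), decreasing = TRUE)
    expect_identical(as.integer(sizes), c(34L, 34L, 33L, 33L))
  }
})

test_that("systematic link design reproduces the cyclic overlap pattern", {
  des <- systematic_link_design(6, 5, n_raters = 2, T = 1, seed = 73)
  got <- lapply(split(des$rater, des$examinee), sort)
  expect_identical(got, list(`1` = c(1L, 2L), `2` = c(2L, 3L), `3` = c(3L, 4L),
                             `4` = c(4L, 5L), `5` = c(1L, 5L), `6` = c(1L, 2L)))
  # n_raters = R degenerates to the crossed pair set
  all_r <- systematic_link_design(6, 5, n_raters = 5, T = 2, seed = 74)
  crossed <- fully_crossed_design(6, 5, T = 2, seed = 74)
  expect_identical(all_r[c("examinee", "rater")], crossed[c("examinee", "rater")])
})

test_that("link-design rater loads are balanced and the graph is connected", {
  des <- systematic_link_design(100, 10, n_raters = 3, T = 2, seed = 75)
  loads <- table(des$rater)
  expect_true(all(abs(loads - 100 * 3 / 10) <= 3))
  for (J in c(10, 37)) {
    for (R in c(2, 5, 9)) {
      if (J < R) next
      d <- systematic_link_design(J, R, n_raters = 2, T = 1, seed = J + R)
      expect_true(design_connected(d))
    }
  }
})

test_that("simulated scores have one row per assignment and valid categories", {
  truth <- draw_parameters(20, 4, 3, 5, seed = 76)
  des <- systematic_link_design(20, 4, 2, 3, seed = 77)
  dat <- simulate_scores(truth, des, seed = 78)
  expect_identical(nrow(dat), nrow(des))
  expect_true(all(dat$score %in% 1:5))
  expect_identical(dims(dat)$K, 5L)
})

test_that("neutral parameters produce uniform category frequencies", {
  params <- parameter_set(rep(0, 2e4), matrix(0, 5, 1), rep(1, 5),
                          matrix(0, 5, 5))
  des <- fully_crossed_design(2e4, 5, T = 1, seed = 79)
  dat <- simulate_scores(params, des, seed = 80)
  freq <- tabulate(dat$score, 5) / nrow(dat)
  expect_true(all(abs(freq - 0.2) < 0.005))
})

test_that("identical seeds reproduce datasets exactly", {
  t1 <- draw_parameters(15, 4, 3, 5, seed = 81)
  t2 <- draw_parameters(15, 4, 3, 5, seed = 81)
  expect_identical(t1, t2)
  d1 <- simulate_scores(t1, fully_crossed_design(15, 4, 3, seed = 82), seed = 83)
  d2 <- simulate_scores(t2, fully_crossed_design(15, 4, 3, seed = 82), seed = 83)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("drifting-component raters show larger severity steps", {
  set.seed(84)
  step_stable <- numeric(0); step_drift <- numeric(0)
  for (i in seq_len(1000)) {
    p <- draw_parameters(1, 5, 5, 5, seed = 84000 + i)
    comp <- attr(p, "sigma_component")
    steps <- rowMeans(abs(p$beta[, -1, drop = FALSE] -
                            p$beta[, -5, drop = FALSE]))
    step_stable <- c(step_stable, steps[comp == "stable"])
    step_drift <- c(step_drift, steps[comp == "drifting"])
  }
  expect_gt(mean(step_drift), mean(step_stable))
})

test_that("rating data round-trips through CSV with strict validation", {
  dat <- tiny_dataset()
  f <- withr::local_tempfile(fileext = ".csv")
  write_ratings(dat, f)
  back <- read_ratings(f, J = 3, R = 2, T = 2, K = 5)
  expect_identical(as.data.frame(back), as.data.frame(dat))
  expect_identical(readLines(f)[1], "examinee,rater,time,score")

  bad <- dat; bad$score[1] <- 9L
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(bad), f2, row.names = FALSE)
  expect_error(read_ratings(f2, K = 5), "score out of range")
  dup <- rbind(as.data.frame(dat), as.data.frame(dat)[1, ])
  expect_error(rating_data(dup, K = 5), "duplicate")
})

test_that("parameter sets round-trip through JSON", {
  p <- draw_parameters(4, 3, 2, 5, seed = 85)
  f <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, f)
  back <- read_parameters(f)
  expect_equal(back$theta, p$theta, tolerance = 1e-12)
  expect_equal(back$beta, p$beta, tolerance = 1e-12)
  expect_equal(back$sigma, p$sigma, tolerance = 1e-12)
  expect_equal(back$d, p$d, tolerance = 1e-12)
  b <- baseline_parameter_set(rnorm(3), matrix(rnorm(4), 2, 2),
                              constrain_steps(rnorm(3)))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_parameters(b, f2)
  back2 <- read_parameters(f2)
  expect_s3_class(back2, "baseline_parameter_set")
  expect_equal(back2$d, b$d, tolerance = 1e-12)
})
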