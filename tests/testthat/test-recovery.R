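test_that("rmse and bias follow their definitions", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(bias(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1.5, 2.5), c(1, 2)), 0.5)
  expect_equal(bias(c(1.5, 2.5), c(1, 2)), 0.5)
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_equal(bias(c(1, -1), c(0, 0)), 0)
  expect_error(rmse(1:3, 1:2), "mismatch")
  expect_error(bias(1:3, 1:2), "mismatch")
})

fake_report <- function(values, design = "crossed") {
  grid <- expand.grid(J = c(100L, 200L, 500L), R = c(5L, 10L), T = c(3L, 5L))
  grid <- grid[order(grid$J, grid$R, grid$T), ]
  by_condition <- data.frame(grid, family = "beta", rmse = values, bias = 0)
  structure(list(by_condition = by_condition,
                 results = by_condition, grand = NULL,
                 config = list(design = design), variant = "proposed",
                 failures = 0L),
            class = "recovery_report")
}

test_that("paired comparison matches the brute-force t statistic", {
  set.seed(131)
  a_vals <- runif(12, 0.1, 0.3)
  b_vals <- a_vals + rnorm(12, 0.04, 0.02)
  out <- paired_comparison(fake_report(a_vals), fake_report(b_vals))
  d <- a_vals - b_vals
  t_oracle <- mean(d) / (sd(d) / sqrt(12))
  expect_equal(out$t, t_oracle, tolerance = 1e-10)
  expect_equal(out$df, 11)
  expect_equal(out$p_value, 2 * pt(-abs(t_oracle), 11), tolerance = 1e-10)
  expect_equal(out$mean_difference, mean(d), tolerance = 1e-12)
})

test_that("degenerate paired comparisons are flagged", {
  a <- fake_report(rep(0.2, 12) + (1:12) / 100)
  ident <- paired_comparison(a, a)
  expect_equal(ident$mean_difference, 0)
  expect_equal(ident$p_value, 1)
  expect_true(ident$degenerate)

  shifted <- fake_report(a$by_condition$rmse + 0.1)
  out <- paired_comparison(a, shifted)
  expect_equal(out$mean_difference, -0.1, tolerance = 1e-12)
  expect_true(out$degenerate)
  expect_true(is.na(out$p_value))
})

test_that("mismatched grids are rejected", {
  a <- fake_report(rep(0.2, 12))
  b <- a
  b$by_condition$J[1] <- 999L
  expect_error(paired_comparison(a, b), "grids")
})

test_that("the oracle estimator drives every error to zero", {
  cfg <- recovery_config(grid = data.frame(J = 10L, R = 3L, T = 2L),
                         replications = 2L, design = "link2", seed = 132L)
  rp <- run_recovery(cfg, "proposed", estimator = "oracle")
  expect_identical(sort(unique(rp$results$family)),
                   c("beta", "d", "sigma", "theta"))
  expect_true(all(rp$results$rmse == 0))
  expect_true(all(rp$results$bias == 0))
  expect_true(all(rp$grand$rmse == 0))
})

test_that("recovery reports satisfy rmse >= |bias| and are seed-stable", {
  cfg <- recovery_config(grid = data.frame(J = 20L, R = 3L, T = 2L),
                         replications = 2L, design = "crossed", seed = 133L,
                         sampler = sampler_config(chains = 2L,
                                                  iterations = 400L,
                                                  warmup = 200L))
  rp1 <- run_recovery(cfg, "proposed")
  expect_true(all(rp1$results$rmse >= abs(rp1$results$bias)))
  rp2 <- run_recovery(cfg, "proposed")
  drop_time <- function(x) x[setdiff(names(x), "seconds")]
  expect_identical(drop_time(rp1$results), drop_time(rp2$results))
})

test_that("the same master seed gives every variant identical datasets", {
  cfg <- recovery_config(grid = data.frame(J = 8L, R = 3L, T = 2L),
                         replications = 1L, design = "crossed", seed = 134L)
  seeds <- raterdrift:::recovery_seeds(cfg)
  truth1 <- draw_parameters(8, 3, 2, 5, mix = cfg$mix, seed = seeds[1, 1, 1])
  truth2 <- draw_parameters(8, 3, 2, 5, mix = cfg$mix, seed = seeds[1, 1, 1])
  expect_identical(truth1, truth2)
})

test_that("severity recovery degrades as the design gets sparser", {
  base <- sampler_config(chains = 2L, iterations = 700L, warmup = 350L,
                         target_acceptance = 0.9)
  out <- vapply(c("crossed", "link3", "link2"), function(des) {
    cfg <- recovery_config(grid = data.frame(J = 60L, R = 5L, T = 3L),
                           replications = 5L, design = des, seed = 135L,
                           sampler = base)
    rp <- run_recovery(cfg, "proposed")
    rp$grand$rmse[rp$grand$family == "beta"]
  }, numeric(1))
  expect_lt(out["crossed"], out["link3"])
  expect_lt(out["link3"], out["link2"])
})

test_that("prior sensitivity sweep returns trajectories per setting", {
  truth <- draw_parameters(25, 4, 3, 5, seed = 136)
  dat <- simulate_scores(truth, systematic_link_design(25, 4, 2, 3, seed = 137),
                         seed = 138)
  sw <- prior_sensitivity_sweep(dat, mu_values = c(-5, -2),
                                config = sampler_config(chains = 2L,
                                                        iterations = 500L,
                                                        warmup = 250L,
                                                        seed = 139L))
  expect_identical(sort(unique(sw$setting)),
                   sort(c("mu_sigma=-5", "mu_sigma=-2", "no_markov")))
  expect_identical(nrow(sw), 3L * 4L * 3L)
  expect_true(all(is.finite(sw$beta_hat)))
  expect_match(attr(sw, "data_hash"), "^[0-9a-f]{32}$")
})
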