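test_that("vectorized slope engine reproduces stats::lm per replicate", {
  d <- base_design(n_families = 120, depth = 7)
  set.seed(77)
  res <- poolassoc:::simulate_block(d, 5)
  # regenerate the identical draws and fit each replicate with lm
  set.seed(77)
  nm <- 120 * 5
  g <- matrix(stats::rbinom(nm, 4, d$p) / 4, 120, 5)
  y <- d$mu + d$b * g + matrix(stats::rnorm(nm, 0, d$sigma_e), 120, 5)
  s1 <- matrix(stats::rbinom(nm, 7L, as.vector(g)), 120, 5)
  for (j in 1:5) {
    ref <- lm_slope_stats(y[, j], s1[, j] / 7)
    expect_equal(res$b_hat[j], ref$b)
    expect_equal(res$se[j], ref$se)
    expect_equal(res$t_stat[j], ref$t)
    expect_equal(res$p_value[j], ref$p)
  }
})

test_that("engine agrees with a plain simulate-then-fit loop", {
  # independent slow route through the exported one-dataset pipeline
  d <- base_design(n_families = 400, depth = 3, p = 0.5)
  fast <- run_replicates(d, 300, seed = 51)
  slow_b <- vapply(1:300, function(i) {
    ds <- simulate_pool_dataset(400, d$locus_model, depth = 3,
                                seed = 60000 + i)
    estimate_effect(ds)$b_hat
  }, numeric(1))
  se <- sqrt(var(fast$b_hat) / 300 + var(slow_b) / 300)
  expect_lt(abs(mean(fast$b_hat) - mean(slow_b)), 3 * se)
})

test_that("null designs reject at the nominal rate with uniform p-values", {
  d <- base_design(n_families = 500, depth = 7, b = 0)
  reps <- run_replicates(d, 1000, seed = 52)
  rate <- mean(reps$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
  expect_gt(stats::ks.test(reps$p_value, "punif")$p.value, 0.01)
})

test_that("power runs are seed-deterministic", {
  d <- base_design(n_families = 300, depth = 7)
  p1 <- run_power(d, 100, seed = 53)
  p2 <- run_power(d, 100, seed = 53)
  p3 <- run_power(d, 100, seed = 54)
  expect_identical(p1$power, p2$power)
  expect_false(identical(p1$power, p3$power) &&
                 identical(run_replicates(d, 100, 53)$b_hat,
                           run_replicates(d, 100, 54)$b_hat))
  # block size must not change results
  r_a <- run_replicates(d, 100, seed = 53)
  expect_equal(run_power(d, 100, seed = 53, block_size = 100)$n_significant,
               sum(r_a$p_value < 0.05))
})

test_that("power is monotone in sample size, effect, LD and noise", {
  reps <- 500
  pw <- function(...) run_power(base_design(...), reps, seed = 55)$power
  se3 <- 3 * sqrt(2 * 0.25 / reps)  # conservative joint MC bound
  expect_gt(pw(n_families = 4000, depth = 3, p = 0.3),
            pw(n_families = 500, depth = 3, p = 0.3) - se3)
  expect_gt(pw(b = 1), pw(b = 0.5) - se3)
  expect_gt(pw(ld_r = 0.95), pw(ld_r = 0.3) - se3)
  expect_gt(pw(sigma_e = 2), pw(sigma_e = 4) - se3)
})

test_that("marker at r = 1 recovers one-locus power", {
  d1 <- base_design(n_families = 1000, depth = 7, p = 0.3)
  d2 <- base_design(n_families = 1000, depth = 7, p = 0.3, ld_r = 1)
  p1 <- run_power(d1, 600, seed = 56)
  p2 <- run_two_locus_power(d2, 600, seed = 57)
  expect_lt(abs(p1$power - p2$power),
            3 * sqrt(p1$mc_se^2 + p2$mc_se^2) + 1e-9)
  expect_error(run_two_locus_power(d1, 10, 1), "ld_r")
})

test_that("fixed-budget grids validate effort and order designs", {
  # the shipped grid: 4000x3, 2000x7, 1000x15, 500x30
  grid <- list(design_point(4000, 3, 0.5), design_point(2000, 7, 0.5),
               design_point(1000, 15, 0.5), design_point(500, 30, 0.5))
  tab <- fixed_budget_grid(13000, grid, n_reps = 10, seed = 58)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$n_families, c(4000, 2000, 1000, 500))
  expect_true(all(diff(tab$effort) >= 0))
  # singleton grid passes through; off-budget designs are rejected
  expect_equal(nrow(fixed_budget_grid(12000, grid[1], n_reps = 5)), 1L)
  expect_error(fixed_budget_grid(12000, list(design_point(100, 3, 0.5))),
               "tolerance")
  expect_error(fixed_budget_grid(12000, list()), "empty")
})

test_that("error layers stack monotonically and degenerate to layer one", {
  d <- design_point(2000, 7, 0.3, depth_kind = "poisson")
  tab <- error_stacking_study(list(d), n_reps = 400, seed = 59)
  expect_equal(tab$layer, c("binomial", "+seq_error", "+calling"))
  slack <- 3 * sqrt(2 * 0.25 / 400)
  expect_lt(tab$power[2], tab$power[1] + slack)
  expect_lt(tab$power[3], tab$power[2] + slack)
  # with zero per-read error, layers (i) and (ii) are the same study
  tab0 <- error_stacking_study(list(d), n_reps = 50, seed = 60,
                               per_read_error = 0)
  expect_identical(tab0$power[1], tab0$power[2])
})

test_that("shipped presets encode the study grids", {
  expect_length(power_preset("fig2"), 12L)
  expect_length(power_preset("fig3"), 48L)
  fig4 <- power_preset("fig4")
  expect_length(fig4, 12L)
  expect_true(all(vapply(fig4, function(d) d$effort, numeric(1)) >= 12000))
  fig5 <- power_preset("fig5")
  expect_true(all(vapply(fig5, function(d) d$depth_kind, "") == "poisson"))
  t2 <- power_preset("table2")
  expect_length(t2, 24L)
  marker <- Filter(function(d) !is.null(d$ld_r), t2)
  expect_length(marker, 18L)
  expect_setequal(unique(vapply(marker, function(d) d$ld_r, numeric(1))),
                  c(0.95, 0.7, 0.3))
  causal <- Filter(function(d) is.null(d$ld_r), t2)
  expect_true(all(vapply(causal, function(d) d$depth, numeric(1)) == 7))
})
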