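test_that("thermal niche limits reduce dynamics to their closed forms", {
  taxa <- data.frame(mu = 20, sigma = 5, r = 0.3, d_a = 0.2, k_in = 0.1,
                     k_out = 0.25, delta_d = 0.01, delta_r = 0.05, rho = 0.4)
  state <- list(A = 1000, D = 400, R = 100)
  # at the optimum (f = 1) with N << K: no death, no inactivation;
  # growth by (1 + r) plus the resuscitation inflow
  s1 <- step_dynamics(state, 20, taxa, K = 1e9, ext_threshold = 0)
  expect_equal(s1$A, 1000 * (1 + 0.3 * (1 - 1000 / 1e9)) + 0.25 * 400)
  expect_equal(s1$D, 400 - 0.25 * 400 - 0.01 * 400)
  # far outside the niche (f ~ 0): no growth or resuscitation, maximal
  # death and dormancy initiation
  s2 <- step_dynamics(state, 200, taxa, K = 1e9, ext_threshold = 0)
  expect_equal(s2$A, 1000 * (1 - 0.2 - 0.1), tolerance = 1e-6)
  expect_equal(s2$D, 400 + 0.1 * 1000 - 0.01 * 400, tolerance = 1e-6)
  expect_error(step_dynamics(state, 20, taxa, K = 0), "positive")
})

test_that("cells leaving the active pool by inactivation arrive in the dormant pool exactly", {
  set.seed(99)
  for (i in 1:20) {
    taxa <- data.frame(mu = runif(1, 10, 60), sigma = runif(1, 2, 10),
                       r = runif(1, 0, 0.5), d_a = 0, k_in = runif(1, 0, 0.5),
                       k_out = 0, delta_d = 0, delta_r = 0, rho = 0)
    state <- list(A = runif(1, 10, 1e6), D = runif(1, 10, 1e6), R = 0)
    temp <- runif(1, 0, 80)
    f <- exp(-(temp - taxa$mu)^2 / (2 * taxa$sigma^2))
    s <- step_dynamics(state, temp, taxa, K = 1e12, ext_threshold = 0)
    flux <- taxa$k_in * (1 - f) * state$A
    growth <- taxa$r * f * (1 - state$A / 1e12) * state$A
    expect_equal(s$A - state$A - growth, -flux, tolerance = 1e-9)
    expect_equal(s$D - state$D, flux, tolerance = 1e-9)
  }
})

test_that("pools never go negative and small pools go extinct", {
  set.seed(4)
  taxa <- data.frame(mu = rep(30, 5), sigma = 5, r = 0.4, d_a = 0.9,
                     k_in = 0.9, k_out = 0.5, delta_d = 0.5, delta_r = 0.9,
                     rho = 0.5)
  state <- list(A = runif(5, 0, 10), D = runif(5, 0, 10), R = runif(5, 0, 10))
  for (day in 1:50) {
    state <- step_dynamics(state, 80, taxa, K = 100)
    expect_true(all(state$A >= 0, state$D >= 0, state$R >= 0))
  }
  # extreme stress drives these tiny pools below the extinction cutoff
  expect_true(all(state$A == 0))
})

test_that("read sampling reflects the transcription model", {
  taxa <- data.frame(mu = c(14, 14, 14), sigma = 5, r = 0, d_a = 0, k_in = 0,
                     k_out = 0, delta_d = 0, delta_r = 0, rho = 0)
  # taxon 1 active-dominated, taxon 2 dormant-only, taxon 3 relic-only
  state <- list(A = c(1e6, 0, 0), D = c(0, 1e6, 0), R = c(0, 0, 1e6))
  set.seed(2)
  reads <- sample_reads(state, 14, taxa, depth = 30000, c_amp = 10,
                        beta_maint = 0)
  expect_identical(sum(reads$dna), 30000L)
  expect_identical(sum(reads$rna), 30000L)
  # with zero maintenance transcription, dormant and relic taxa yield no RNA
  expect_identical(reads$rna[2], 0L)
  expect_identical(reads$rna[3], 0L)
  expect_gt(reads$dna[2], 0L)
  # an active-dominated taxon has RNA:DNA > 1 in expectation
  state2 <- list(A = c(8e5, 2e5, 0), D = c(0, 8e5, 0), R = c(0, 0, 5e5))
  set.seed(3)
  r2 <- sample_reads(state2, 14, taxa, depth = 50000, c_amp = 10,
                     beta_maint = 0.05)
  expect_gt(r2$rna[1] / r2$dna[1], 1)
  expect_lt(r2$rna[2] / r2$dna[2], 1)
  expect_error(sample_reads(state, 14, taxa, depth = 0), "positive")
})

test_that("the simulator is bit-identical under a fixed seed", {
  cfg <- tiny_sim_config()
  a <- simulate_press_experiment(cfg, seed = 7)
  b <- simulate_press_experiment(cfg, seed = 7)
  expect_identical(unclass(a$dna), unclass(b$dna))
  expect_identical(unclass(a$rna), unclass(b$rna))
  expect_identical(a$truth$trajectories, b$truth$trajectories)
  c_ <- simulate_press_experiment(cfg, seed = 8)
  expect_false(identical(unclass(a$dna), unclass(c_$dna)))
})

test_that("the simulated design matches the experimental layout", {
  sim <- simulate_press_experiment(tiny_sim_config(), seed = 5)
  meta <- sim$metadata
  expect_identical(nrow(meta), 135L)
  expect_identical(length(unique(meta$mesocosm_id)), 15L)
  tab <- table(unique(meta[, c("mesocosm_id", "treatment")])$treatment)
  expect_identical(as.integer(tab[c("control", "disturbance",
                                    "disturbance_immigration")]),
                   c(6L, 5L, 4L))
  expect_setequal(unique(meta$week), c(4, 5, 6, 10, 14, 15, 16, 20, 45))
  # controls stay at ambient; the press peaks at 60 C at weeks 10 and 14
  expect_true(all(meta$temperature_C[meta$treatment == "control"] == 14))
  expect_true(all(meta$temperature_C[meta$treatment != "control" &
                                       meta$week %in% c(10, 14)] == 60))
  # trajectories never go negative
  expect_true(all(sim$truth$trajectories >= 0))
})

test_that("temperature schedule ramps in daily increments within 3-3.5 C", {
  cfg <- sim_config()
  days <- 0:315
  temps <- temperature_schedule(days, cfg)
  expect_true(all(temps[days <= 28] == 14))
  expect_true(all(temps[days >= 42 & days <= 98] == 60))
  expect_true(all(temps[days >= 112] == 14))
  steps <- abs(diff(temps))
  expect_true(all(steps[steps > 0] >= 3 & steps[steps > 0] <= 3.5))
  expect_true(all(temperature_schedule(days, cfg, disturbed = FALSE) == 14))
})

test_that("without a press the disturbed mesocosms are as resistant as controls", {
  rs <- unlist(lapply(1:4, function(s) {
    cfg <- tiny_sim_config(temp_press = 14)
    res <- run_quiet(press_config(sim = cfg, depth = 12000, seed = 300 + s))
    res$stability$value[res$stability$kind == "resistance"]
  }))
  expect_true(mean(abs(rs - 1)) < 0.1)
})

test_that("a zero dispersal fraction makes the immigration treatment a null", {
  diffs <- vapply(1:4, function(s) {
    cfg <- tiny_sim_config(dispersal_fraction = 0)
    res <- run_quiet(press_config(sim = cfg, depth = 12000, seed = 400 + s))
    st <- res$stability[res$stability$kind == "resilience" &
                          res$stability$window == "16-45", ]
    med <- tapply(st$value, st$treatment, stats::median)
    med[["disturbance_immigration"]] - med[["disturbance"]]
  }, numeric(1))
  # no systematic resilience advantage without dispersal
  expect_lt(abs(mean(diffs)), 0.15)
})

test_that("ground-truth labels map archetypes and audit deviations", {
  sim <- simulate_press_experiment(tiny_sim_config(), seed = 11)
  truth <- ground_truth_labels(sim$truth, sim$metadata)
  expect_identical(nrow(truth), nrow(sim$truth$taxa))
  expect_identical(
    unique(truth$category[truth$archetype == "mesophile_sensitive"]),
    "sensitive")
  expect_identical(
    unique(truth$category[truth$archetype == "immigrant_lineage"]),
    "immigrant")
  expect_identical(
    unique(truth$category[truth$archetype == "relic_background"]),
    "unclassified")
  expect_type(truth$deviated, "logical")
  # the planted script is realised for the vast majority of taxa
  expect_lt(mean(truth$deviated), 0.2)
})
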