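# Helpers to wrap a single intensity series as a one-ion time-course table.
one_ion_table <- function(intensity, od, time, ion = "X") {
  df <- data.frame(species = "sp", medium = "fresh", replicate = 1,
                   time_h = time, od = od)
  df[[ion]] <- intensity
  df
}

test_that("caller configuration validates its thresholds", {
  cfg <- caller_config()
  expect_equal(cfg$fc_consumed, 1.37)
  expect_equal(cfg$fc_secreted, 1.20)
  expect_equal(cfg$dilution_corr_threshold, -0.75)
  expect_error(caller_config(fc_secreted = 0.9))
  expect_error(caller_config(p_threshold = 0))
  expect_error(caller_config(r_od_threshold = 1.5))
})

test_that("constructed positive, negative and null series are called", {
  t <- seq(1, 10, length.out = 8)
  od <- logistic4(t, 0.05, 1.5, 1, 4)
  # proportional to OD, 3x increase overall
  sec <- od / od[1] * 100
  calls <- call_dynamics(one_ion_table(sec, od, t))
  expect_equal(calls$direction, "secreted")
  expect_gte(calls$max_fc, 1.20)
  # yield-coupled consumption, 10x decrease
  con <- 100 * (1 - 0.9 * (od - od[1]) / (1.5 - od[1]))
  calls <- call_dynamics(one_ion_table(con, od, t))
  expect_equal(calls$direction, "consumed")
  expect_lte(calls$max_fc, -1.37)
  # constant
  calls <- call_dynamics(one_ion_table(rep(50, 8), od, t))
  expect_equal(calls$direction, "unchanged")
  expect_true(calls$degenerate)
})

test_that("exhausted metabolites pass via the exponential-fit branch", {
  # exponential decay hitting the detection floor at mid-growth: the OD
  # keeps rising after exhaustion, degrading the OD correlation, while the
  # log-linear fit stays strong
  t <- seq(0, 20, length.out = 10)
  od <- logistic4(t, 0.05, 1.5, 0.45, 14)
  x <- 1000 * exp(-0.9 * t)
  tab <- one_ion_table(x, od, t)
  cfg <- caller_config()
  calls <- call_dynamics(tab, cfg)
  expect_lt(abs(calls$r_od), cfg$r_od_threshold)   # OD branch fails
  expect_gt(calls$r2_exp, cfg$r2_fit_threshold)    # exponential branch holds
  expect_equal(calls$direction, "consumed")
  # and the call agrees with the brute-force criterion evaluation
  expect_equal(oracle_call(x, od, t, cfg), "consumed")
})

test_that("caller matches the brute-force oracle on 500 random series", {
  set.seed(2024)
  cfg <- caller_config()
  n_checked <- 0
  for (i in 1:500) {
    n <- sample(5:9, 1)
    t <- sort(runif(n, 0, 24))
    od <- logistic4(t, 0.05, runif(1, 0.5, 2), runif(1, 0.4, 1.5),
                    runif(1, 3, 9)) * exp(rnorm(n, 0, 0.03))
    kind <- sample(c("up", "down", "flat", "noisy", "spike", "exhaust"), 1)
    x <- switch(kind,
      up = 100 * od / od[1] * exp(rnorm(n, 0, 0.1)),
      down = 500 * (1.05 - (od - od[1]) / max(od)) * exp(rnorm(n, 0, 0.1)),
      flat = rep(100, n) * exp(rnorm(n, 0, 0.05)),
      noisy = runif(n, 10, 1000),
      spike = { v <- rep(100, n); v[sample(n, 1)] <- 1000; v },
      exhaust = pmax(1000 * exp(-runif(1, 0.3, 1) * t), 1e-3))
    df <- one_ion_table(x, od, t)
    got <- call_dynamics(df, cfg)$direction
    expect_equal(got, oracle_call(x, od, t, cfg),
                 label = paste0("seed-case ", i, " (", kind, ")"))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 500)
})

test_that("replicates are averaged per time point before testing", {
  t <- seq(1, 10, length.out = 6)
  od <- logistic4(t, 0.05, 1.2, 1, 4)
  # two replicates whose average is exactly proportional to OD
  base <- od * 100
  df1 <- one_ion_table(base * 1.3, od, t); df1$replicate <- 1
  df2 <- one_ion_table(base * 0.7, od, t); df2$replicate <- 2
  tab <- rbind(df1, df2)
  call_avg <- call_dynamics(tab)
  expect_equal(call_avg$direction, "secreted")
  expect_equal(call_avg$r_od, 1, tolerance = 1e-12)
  per_rep <- call_dynamics(tab, caller_config(per_replicate = TRUE))
  expect_equal(nrow(per_rep), 2)
})

test_that("identical inputs give identical calls; thresholds are monotone", {
  spec <- random_community_spec(4, noise_cv = 0.05, seed = 9)
  tab <- simulate_consortium(spec)$table
  fresh <- tab[tab$medium == "fresh", ]
  a <- call_dynamics(fresh)
  b <- call_dynamics(fresh)
  expect_identical(a, b)
  # raising fold-change thresholds can only lose directional calls
  strict <- call_dynamics(fresh, caller_config(fc_secreted = 2.5,
                                               fc_consumed = 2.5))
  relaxed_dir <- a$direction != "unchanged"
  strict_dir <- strict$direction != "unchanged"
  expect_true(all(strict_dir <= relaxed_dir))
})

test_that("noiseless synthetic calls equal the generator's ground truth", {
  spec <- random_community_spec(5, noise_cv = 0, seed = 14)
  sim <- simulate_consortium(spec)
  fresh <- call_dynamics(sim$table[sim$table$medium == "fresh", ])
  got_sec <- fresh[fresh$direction == "secreted", c("species", "metabolite")]
  got_con <- fresh[fresh$direction == "consumed", c("species", "metabolite")]
  key <- function(df) sort(paste(df$species, df$metabolite))
  expect_equal(key(got_sec), key(sim$truth$secreted))
  # fresh-medium cultures can only reveal consumption of metabolites that
  # are present in the fresh medium
  truth_con <- sim$truth$consumed
  truth_con <- truth_con[truth_con$metabolite %in% names(spec$medium), ]
  expect_equal(key(got_con), key(truth_con))
})

test_that("fold-change floor is applied and flagged on zero intensities", {
  t <- seq(1, 10, length.out = 6)
  od <- logistic4(t, 0.05, 1.2, 1, 4)
  x <- c(0, 10, 40, 80, 100, 110)  # zero at t0
  calls <- call_dynamics(one_ion_table(x, od, t))
  expect_true(calls$floored)
  expect_equal(calls$direction, "secreted")
})

test_that("threshold calibration returns exactly 2 on ideal dilutions", {
  tab <- simulate_dilution_series(
    medium_ions = c(a = 1e5, b = 4e4, c = 9e3),
    background_ions = c(bg1 = 800, bg2 = 120),
    dilutions = c(20, 40, 80, 160), replicates = 3, noise_cv = 0)
  cal <- calibrate_thresholds(tab)
  expect_equal(cal$fc_consumed, 2.0)
  expect_equal(cal$fc_secreted, 2.0)
  expect_setequal(cal$kept_ions, c("a", "b", "c"))
})

test_that("background-only dilution series fails the calibration filter", {
  tab <- simulate_dilution_series(
    medium_ions = c(dummy = 1), background_ions = c(bg1 = 500, bg2 = 80),
    dilutions = c(20, 40, 80), replicates = 2, noise_cv = 0)
  tab$dummy <- NULL
  expect_error(calibrate_thresholds(tab), "no ion passes")
})

test_that("background ions are uncorrelated with dilution and filtered out", {
  tab <- simulate_dilution_series(
    medium_ions = c(real = 5e4), background_ions = c(bg = 1000),
    dilutions = c(20, 40, 80, 160), replicates = 3, noise_cv = 0.05,
    seed = 31)
  cal <- calibrate_thresholds(tab)
  expect_true("real" %in% cal$kept_ions)
  expect_false("bg" %in% cal$kept_ions)
})

test_that("calibration requires the configured dilution windows", {
  tab <- simulate_dilution_series(c(a = 1e4), NULL,
                                  dilutions = c(20, 40, 160),
                                  replicates = 2, noise_cv = 0)
  expect_error(calibrate_thresholds(tab), "lacks level")
  expect_error(calibrate_thresholds(tab[tab$dilution %in% c(20, 40), ]),
               "3 dilution levels")
})
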