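test_that("logistic growth curve hits its midpoint and asymptote", {
  p <- c(A = 0.05, K = 1.78, r = 2.5, t0 = 3)
  expect_equal(simulate_growth(p, times = 3)$od, (0.05 + 1.78) / 2)
  expect_equal(simulate_growth(p, times = 100)$od, 1.78, tolerance = 1e-6)
  expect_error(simulate_growth(p, times = c(2, 1)), "increasing")
  expect_error(simulate_growth(c(A = 1, K = 0.5, r = 1, t0 = 1), times = 1),
               "K >= A")
})

test_that("growth noise is seed-deterministic and keeps OD positive", {
  p <- c(A = 0.05, K = 1.5, r = 1, t0 = 4)
  t <- seq(0, 24, by = 2)
  a <- simulate_growth(p, t, noise_cv = 0.05, seed = 7)
  b <- simulate_growth(p, t, noise_cv = 0.05, seed = 7)
  expect_identical(a, b)
  c <- simulate_growth(p, t, noise_cv = 0.05, seed = 8)
  expect_false(identical(a, c))
  expect_true(all(a$od > 0))
  big <- simulate_growth(p, seq(0, 24, length.out = 200), noise_cv = 0.5,
                         seed = 1)
  expect_true(all(big$od > 0))
})

make_pair_spec <- function(noise_cv = 0, y = 0.9, s = 400) {
  community_spec(
    species = c("P", "C"),
    growth = list(P = c(A = 0.05, K = 1.5, r = 1, t0 = 4),
                  C = c(A = 0.05, K = 1.2, r = 0.9, t0 = 5)),
    medium = c(glucose = 1000),
    interactions = list(
      P = list(consume = c(glucose = y), secrete = c(X = s)),
      C = list(consume = c(X = 0.8), secrete = NULL)),
    noise_cv = noise_cv, times = seq(1, 24, length.out = 10),
    replicates = 2, seed = 11)
}

test_that("consumed trajectories follow the yield-coupled form exactly", {
  spec <- make_pair_spec(noise_cv = 0)
  cult <- simulate_culture(spec, "P", "fresh")$table
  one <- cult[cult$replicate == 1, ]
  g <- c(A = 0.05, K = 1.5, r = 1, t0 = 4)
  odn <- logistic4(one$time_h, g["A"], g["K"], g["r"], g["t0"])
  gain <- (odn - odn[1]) / (g[["K"]] - odn[1])
  expect_equal(one$glucose, 1000 * (1 - 0.9 * gain))
  expect_equal(one$X, 400 * (odn - odn[1]))
  # noiseless monotonicity
  expect_true(all(diff(one$glucose) <= 0))
  expect_true(all(diff(one$X) >= 0))
})

test_that("spent medium is an exact 1:1 mixture of fresh and endpoint", {
  spec <- make_pair_spec(noise_cv = 0)
  p_end <- simulate_culture(spec, "P", "fresh")$table
  p_end <- p_end[p_end$replicate == 1, ]
  endpoint_X <- p_end$X[nrow(p_end)]
  endpoint_glc <- p_end$glucose[nrow(p_end)]
  spent <- simulate_culture(spec, "C", "spent", producer = "P")
  # X absent from fresh medium: spent level is half the producer endpoint
  expect_equal(spent$medium0[["X"]], endpoint_X / 2)
  expect_equal(spent$medium0[["glucose"]], (1000 + endpoint_glc) / 2)
})

test_that("consumption fraction is realized against the available amount", {
  # y = 0.9 consumed over the full (asymptotic) biomass gain; at the last
  # sampling time the realized gain is slightly below 1
  spec <- make_pair_spec(noise_cv = 0)
  cult <- simulate_culture(spec, "P", "fresh")$table
  one <- cult[cult$replicate == 1, ]
  final_frac <- one$glucose[nrow(one)] / 1000
  expect_lt(final_frac, 0.11)
  expect_gte(final_frac, 0.10)
})

test_that("community spec validation rejects inconsistent interactions", {
  expect_error(make_pair_spec(y = 1.2), "\\[0, 1\\]")
  expect_error(community_spec(
    species = "A", growth = list(A = c(A = 0.05, K = 1, r = 1, t0 = 3)),
    medium = c(glucose = 10),
    interactions = list(A = list(consume = c(ghost = 0.5), secrete = NULL)),
    noise_cv = 0), "neither in medium nor secreted")
})

test_that("consortium simulation is byte-identical under a fixed seed", {
  spec <- random_community_spec(4, noise_cv = 0.05, seed = 21)
  a <- simulate_consortium(spec)
  b <- simulate_consortium(spec)
  expect_identical(a, b)
  spec2 <- random_community_spec(4, noise_cv = 0.05, seed = 22)
  expect_false(identical(simulate_consortium(spec2)$table, a$table))
})

test_that("ground truth edges link producers to distinct consumers", {
  for (seed in 1:5) {
    spec <- random_community_spec(5, seed = seed)
    tr <- ground_truth(spec)
    expect_true(all(tr$edges$producer != tr$edges$consumer))
    for (i in seq_len(nrow(tr$edges))) {
      e <- tr$edges[i, ]
      expect_true(any(tr$secreted$species == e$producer &
                        tr$secreted$metabolite == e$metabolite))
      expect_true(any(tr$consumed$species == e$consumer &
                        tr$consumed$metabolite == e$metabolite))
    }
  }
})

test_that("dilution series is linear in 1/dilution with constant background", {
  tab <- simulate_dilution_series(c(ion = 8e4), c(bg = 500),
                                  dilutions = c(40, 80), replicates = 1,
                                  noise_cv = 0)
  i40 <- tab$ion[tab$dilution == 40]
  i80 <- tab$ion[tab$dilution == 80]
  expect_equal(i40 / i80, 2)
  expect_equal(unique(tab$bg), 500)
  expect_error(simulate_dilution_series(c(a = 1), NULL, dilutions = 40),
               "two distinct")
  expect_error(simulate_dilution_series(numeric(0), NULL,
                                        dilutions = c(20, 40)), "no ions")
  s1 <- simulate_dilution_series(c(a = 1e4), c(b = 10), c(20, 40, 80),
                                 noise_cv = 0.1, seed = 3)
  s2 <- simulate_dilution_series(c(a = 1e4), c(b = 10), c(20, 40, 80),
                                 noise_cv = 0.1, seed = 3)
  expect_identical(s1, s2)
})
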