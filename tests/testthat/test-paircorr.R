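test_that("pcf of an isolated pair matches the annulus-count oracle", {
  # two points exactly 50 nm apart; only the (40, 50] bin can be hit
  p <- make_pp(c(500, 550), c(500, 500))
  bins <- radial_bins(0, 100, 10)
  curve <- pcf(p, bins, "periodic")
  A <- 1000 * 1000
  expected_pairs <- 2 * 1 * pi * (50^2 - 40^2) / A
  expect_equal(curve$g[5], 2 / expected_pairs)
  expect_equal(curve$g[-5], rep(0, 9))
  expect_error(pcf(make_pp(1, 1), bins), "2 points")
})

test_that("pcf and bpcf agree exactly with O(n^2) brute-force oracles", {
  set.seed(21)
  a <- make_pp(runif(180, 0, 1000), runif(180, 0, 1000))
  b <- make_pp(runif(120, 0, 1000), runif(120, 0, 1000))
  edges <- seq(0, 300, 20)
  bins <- radial_bins(edges = edges)
  expect_equal(pcf(a, bins, "periodic")$g, oracle_pcf(a, edges))
  expect_equal(bpcf(a, b, bins, "periodic")$g, oracle_bpcf(a, b, edges))
  expect_equal(pcf(a, bins, "none")$g, oracle_pcf(a, edges, "none"))
})

test_that("bpcf is symmetric and reduces to pcf for identical patterns", {
  set.seed(22)
  t1 <- gen_thomas(parent_density = 2, offspring_mean = 10, sigma = 25,
                   window = owin_rect(0, 2000, 0, 2000))
  t2 <- gen_poisson(8, owin_rect(0, 2000, 0, 2000))
  bins <- radial_bins(0, 300, 20)
  expect_equal(bpcf(t1, t2, bins, "periodic")$g,
               bpcf(t2, t1, bins, "periodic")$g)
  # same positions in both channels: cross pairs lack only the self pairs,
  # so g12 = g11 * (n-1)/n under the ordered-pair normalizations
  n <- npoints(t1)
  expect_equal(bpcf(t1, t1, bins, "periodic")$g,
               pcf(t1, bins, "periodic")$g * (n - 1) / n)
  expect_error(bpcf(t1, make_pp(1:3, 1:3, owin_rect(0, 10, 0, 10)), bins),
               "window")
})

test_that("pcf is flat at 1 for complete spatial randomness", {
  set.seed(23)
  bins <- radial_bins(0, 500, 10)
  keep <- bins$centers >= 20
  gbar <- replicate(20, {
    p <- gen_poisson(100, owin_rect(0, 5000, 0, 5000))
    mean(pcf(p, bins, "periodic")$g[keep])
  })
  se <- sd(gbar) / sqrt(length(gbar))
  expect_lt(abs(mean(gbar) - 1), 3 * se)
  # translation correction is unbiased too (real-data mode)
  g2 <- replicate(10, {
    p <- gen_poisson(100, owin_rect(0, 5000, 0, 5000))
    mean(pcf(p, bins, "translation")$g[keep])
  })
  expect_lt(abs(mean(g2) - 1), 0.05)
})

test_that("random-labeling envelopes are reproducible and ordered", {
  m <- gen_random_label_mix(0.5, seed = 31)
  bins <- radial_bins(0, 300, 20)
  e1 <- rl_envelope(m$a, m$b, bins, n_sims = 5, seed = 9,
                    edge_correction = "periodic")
  e2 <- rl_envelope(m$a, m$b, bins, n_sims = 5, seed = 9,
                    edge_correction = "periodic")
  expect_identical(e1$lo, e2$lo)
  expect_identical(e1$hi, e2$hi)
  expect_true(all(e1$lo <= e1$mean_sim + 1e-12 &
                  e1$mean_sim <= e1$hi + 1e-12))
  e3 <- rl_envelope(m$a, m$b, bins, n_sims = 1, seed = 9,
                    edge_correction = "periodic")
  expect_equal(e3$lo, e3$hi)
  expect_equal(e3$lo, e3$mean_sim)
  expect_error(rl_envelope(m$a, m$b, bins, n_sims = 0), "n_sims")
})

test_that("EOM is the linear normalization between the two null anchors", {
  bins <- radial_bins(0, 100, 20)
  env <- structure(list(bins = bins, lo = rep(1.5, 5), hi = rep(4, 5),
                        mean_sim = c(3, 2.5, 2, 1.5, 1.02), n_sims = 19),
                   class = "rl_envelope")
  obs_match <- structure(list(bins = bins, g = env$mean_sim,
                              kind = "bivariate"), class = "pcf_curve")
  e <- eom(obs_match, env)
  expect_equal(e$eom[1:4], rep(1, 4))
  expect_true(is.na(e$eom[5]))  # degenerate bin: |mean_sim - 1| < 0.05
  obs_flat <- structure(list(bins = bins, g = rep(1, 5),
                             kind = "bivariate"), class = "pcf_curve")
  expect_equal(eom(obs_flat, env)$eom[1:4], rep(0, 4))
  obs_half <- structure(list(bins = bins, g = (env$mean_sim + 1) / 2,
                             kind = "bivariate"), class = "pcf_curve")
  expect_equal(eom(obs_half, env)$eom[1:4], rep(0.5, 4))
  bad <- structure(list(bins = radial_bins(0, 50, 10), g = rep(1, 5)),
                   class = "pcf_curve")
  expect_error(eom(bad, env), "bins")
})

test_that("g(0-100) averages the qualifying bins", {
  mk <- function(centers, g) structure(
    list(bins = structure(list(edges = c(centers - 25, max(centers) + 25),
                               centers = centers), class = "radial_bins"),
         g = g), class = "pcf_curve")
  expect_equal(mean_g_short(mk(c(25, 75, 125), c(2, 4, 9))), 3)
  expect_equal(mean_g_short(mk(c(25, 75), c(7, 7))), 7)
  expect_error(mean_g_short(mk(c(250, 350), c(1, 1))), "bins")
})

test_that("EOM averaging over cells handles undefined bins per policy", {
  bins <- radial_bins(0, 60, 20)
  mk <- function(v) structure(list(bins = bins, eom = v),
                              class = "eom_curve")
  avg <- eom_average(list(mk(c(0, 0, 0)), mk(c(1, 1, 1))))
  expect_equal(avg$eom, c(0.5, 0.5, 0.5))
  expect_equal(eom_average(list(mk(c(1, 2, 3))))$eom, c(1, 2, 3))
  avg2 <- eom_average(list(mk(c(NA, 0.4, 0.2)), mk(c(0.6, 0.8, NA))))
  expect_equal(avg2$eom, c(0.6, 0.6, 0.2))
  expect_equal(avg2$n_cells, c(1, 2, 1))
  expect_error(eom_average(list()), "no EOM")
})

test_that("mean short-range EOM rises monotonically with the mixing fraction", {
  bins <- radial_bins(0, 200, 20)
  short <- bins$centers < 100
  mean_eom <- function(f, seeds) mean(vapply(seeds, function(s) {
    m <- gen_random_label_mix(f, parent_density = 0.8, offspring_mean = 15,
                              sigma = 30, window = owin_rect(0, 5000, 0, 5000),
                              seed = s)
    env <- rl_envelope(m$a, m$b, bins, edge_correction = "periodic")
    e <- eom(bpcf(m$a, m$b, bins, "periodic"), env)
    mean(e$eom[is.finite(e$eom) & short])
  }, numeric(1)))
  fs <- c(0, 0.25, 0.5, 0.75, 1)
  vals <- vapply(fs, mean_eom, numeric(1), seeds = 101:110)
  expect_true(all(diff(vals) > -0.05))   # monotone within simulation error
  expect_gt(vals[5], vals[1] + 0.5)
})

test_that("the 19-simulation envelope has ~95% one-sided coverage", {
  # random-labeling truth; exceedance checked at one fixed short-range bin
  set.seed(41)
  bins <- radial_bins(edges = c(40, 80))
  n_trials <- 200
  exceed <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    m <- gen_random_label_mix(1, parent_density = 1.5, offspring_mean = 8,
                              sigma = 30, window = owin_rect(0, 3000, 0, 3000))
    obs <- bpcf(m$a, m$b, bins, "periodic")$g[1]
    env <- rl_envelope(m$a, m$b, bins, n_sims = 19,
                       edge_correction = "periodic")
    exceed[t] <- obs > env$hi[1]
  }
  rate <- mean(exceed)
  se <- sqrt(0.05 * 0.95 / n_trials)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-9)
})
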