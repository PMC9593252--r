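test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_poisson(50, seed = 81), gen_poisson(50, seed = 81))
  expect_identical(gen_thomas(seed = 81)$x, gen_thomas(seed = 81)$x)
  m1 <- gen_random_label_mix(0.5, seed = 81)
  m2 <- gen_random_label_mix(0.5, seed = 81)
  expect_identical(m1$a$x, m2$a$x)
  expect_identical(gen_periphery(seed = 81)$b$x,
                   gen_periphery(seed = 81)$b$x)
  expect_identical(gen_blinking_movie(50, 1000, seed = 81)$records,
                   gen_blinking_movie(50, 1000, seed = 81)$records)
  e1 <- gen_domain_enrichment(5, seed = 81)
  e2 <- gen_domain_enrichment(5, seed = 81)
  expect_identical(e1$b$x, e2$b$x)
  d1 <- gen_dynamic_assembly(n_chains = 2, n_windows = 6, seed = 81)
  d2 <- gen_dynamic_assembly(n_chains = 2, n_windows = 6, seed = 81)
  expect_identical(d1[[1]]$states, d2[[1]]$states)
  expect_identical(d1[[2]]$windows_a[[3]]$x, d2[[2]]$windows_a[[3]]$x)
})

test_that("generated counts match the programmed intensities", {
  w <- owin_rect(0, 5000, 0, 5000)  # 25 um^2
  set.seed(82)
  n_pois <- replicate(100, npoints(gen_poisson(40, w)))
  expect_lt(abs(mean(n_pois) - 1000), 3 * sd(n_pois) / sqrt(100))
  n_th <- replicate(100, npoints(gen_thomas(0.8, 10, 30, w)))
  expect_lt(abs(mean(n_th) - 0.8 * 10 * 25), 3 * sd(n_th) / sqrt(100))
  expect_error(gen_poisson(0), "positive")
})

test_that("the Thomas generator matches its closed-form pair correlation", {
  # a window holding ~100 clusters keeps the n(n-1) normalization of the
  # estimator effectively unbiased for this clustered process
  sigma <- 30; kappa <- 0.5
  bins <- radial_bins(0, 200, 10)
  set.seed(83)
  reps <- replicate(30, {
    p <- gen_thomas(kappa, 20, sigma, owin_rect(0, 15000, 0, 15000))
    pcf(p, bins, "periodic")$g
  })
  gbar <- rowMeans(reps)
  # bin-averaged analytic curve (integrate g over each annulus)
  g_true <- vapply(seq_len(length(bins$centers)), function(k) {
    lo <- bins$edges[k]; hi <- bins$edges[k + 1]
    f <- function(r) thomas_pcf(r, kappa, sigma) * 2 * r / (hi^2 - lo^2)
    integrate(f, lo, hi)$value
  }, numeric(1))
  expect_gt(mean_g_short(structure(list(bins = bins, g = gbar),
                                   class = "pcf_curve")), 2)
  at_sigma <- which(bins$edges[-1] >= sigma)[1]
  se <- sd(reps[at_sigma, ]) / sqrt(ncol(reps))
  expect_lt(abs(gbar[at_sigma] - g_true[at_sigma]), 3 * se)
  expect_equal(mean(gbar / g_true), 1, tolerance = 0.05)
})

test_that("high parent density drives the Thomas pattern toward CSR", {
  bins <- radial_bins(0, 500, 10)
  keep <- bins$centers >= 20
  set.seed(84)
  g_dense <- mean(replicate(5, {
    p <- gen_thomas(50, 1, 30, owin_rect(0, 5000, 0, 5000))
    mean(pcf(p, bins, "periodic")$g[keep])
  }))
  g_clustered <- mean(replicate(5, {
    p <- gen_thomas(0.5, 20, 30, owin_rect(0, 5000, 0, 5000))
    mean(pcf(p, bins, "periodic")$g[keep])
  }))
  expect_lt(abs(g_dense - 1), 0.25)
  expect_gt(g_clustered, 2)
})

test_that("random-label mixtures conserve counts and respect bounds", {
  m <- gen_random_label_mix(0.6, seed = 85)
  p <- gen_thomas(seed = 85)  # same parent draw as inside the generator
  expect_error(gen_random_label_mix(1.4), "\\[0, 1\\]")
  expect_gt(npoints(m$a), 0)
  expect_gt(npoints(m$b), 0)
  m2 <- gen_random_label_mix(1, seed = 86)
  tot <- npoints(m2$a) + npoints(m2$b)
  expect_lte(abs(npoints(m2$a) - npoints(m2$b)), 1)  # balanced labeling
  expect_equal(tot, npoints(gen_thomas(seed = 86)))
})

test_that("periphery generator places species B around cluster centers", {
  per <- gen_periphery(n_b = 300, background_fraction = 0, r_inner = 60,
                       r_outer = 120, seed = 87,
                       window = owin_rect(0, 8000, 0, 8000))
  # torus distance from every B point to the nearest cluster center
  w <- 8000
  dmin <- vapply(seq_len(npoints(per$b)), function(i) {
    dx <- abs(per$b$x[i] - per$centers[, 1]); dx <- pmin(dx, w - dx)
    dy <- abs(per$b$y[i] - per$centers[, 2]); dy <- pmin(dy, w - dy)
    min(sqrt(dx^2 + dy^2))
  }, numeric(1))
  expect_true(all(dmin <= 120 + 1e-9))
  expect_error(gen_periphery(r_inner = 100, r_outer = 50), "r_inner")
})

test_that("domain-enrichment generator hits its fold limits", {
  e0 <- gen_domain_enrichment(fold = 0, density_b = 20, seed = 88,
                              window = owin_rect(0, 6000, 0, 6000))
  expect_equal(e0$n_in, 0L)
  e1 <- gen_domain_enrichment(fold = 1, density_b = 30, seed = 89,
                              window = owin_rect(0, 6000, 0, 6000))
  r1 <- inout_density(e1$domains, e1$b)
  # uniform limit: fraction inside tracks the area fraction
  expect_equal(r1$fraction_in, r1$area_fraction, tolerance = 0.5)
  expect_error(gen_domain_enrichment(fold = -1), "non-negative")
})

test_that("noiseless non-blinking movies recover emitters exactly", {
  tab <- gen_blinking_movie(n_emitters = 60, n_frames = 2000,
                            n_bursts_mean = 1, on_frames_mean = 3,
                            off_gap_max = 0, jitter = 0, seed = 90)
  g <- group_localizations(tab, grouping_params(0, 1))
  expect_equal(nrow(g$records), 60L)
  # acquisition metadata flows through to windowing
  expect_length(window_by_frames(tab, 250), 2000 %/% 250)
})

test_that("state-3 windows of the assembly generator are clustered", {
  P <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, byrow = TRUE)  # all state 3
  ch <- gen_dynamic_assembly(P, n_windows = 6, n_chains = 1, seed = 91,
                             state_density = c(10, 60, 80))[[1]]
  expect_true(all(ch$states == 3))
  g3 <- mean(vapply(ch$windows_a, function(wd)
    mean_g_short(pcf(wd, radial_bins(0, 200, 10), "periodic")),
    numeric(1)))
  expect_gt(g3, 1.5)
  expect_error(gen_dynamic_assembly(matrix(1, 3, 3)), "row-stochastic")
})
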