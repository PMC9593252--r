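roi_default <- owin_rect(0, 1500, 0, 1500)

test_that("trajectories carry one feature row per acquisition window", {
  P_stay <- diag(3)
  ch <- gen_dynamic_assembly(matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3,
                                    byrow = TRUE),
                             n_windows = 48, n_chains = 1, seed = 71)[[1]]
  tr <- extract_trajectory(ch$windows_a, ch$windows_b, roi_default,
                           n_sims = 3, seed = 1)
  expect_s3_class(tr, "cluster_trajectory")
  expect_equal(nrow(tr), 48L)
  expect_equal(tr$time, seq(0, 235, by = 5))
  expect_error(extract_trajectory(ch$windows_a, ch$windows_b[1:10],
                                  roi_default), "equal length")
})

test_that("empty windows yield zero density and missing g", {
  empty <- point_pattern(numeric(0), numeric(0), roi_default)
  one <- point_pattern(700, 700, roi_default)
  tr <- extract_trajectory(list(empty, one, one), NULL, roi_default)
  expect_equal(tr$density_a[1], 0)
  expect_true(all(is.na(tr$g_a)))
})

test_that("density rises through a programmed assembly interval", {
  # dispersed state decays into an absorbing mature-cluster state
  P <- matrix(c(0.9, 0, 0.1, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  chains <- gen_dynamic_assembly(P, n_windows = 48, n_chains = 6,
                                 seed = 72, state_density = c(10, 60, 80),
                                 init = c(1, 0, 0))
  firsts <- vapply(chains, function(ch) which(ch$states == 3)[1],
                   numeric(1))
  # absorption: once in state 3, never out
  for (ch in chains) {
    f <- which(ch$states == 3)[1]
    if (!is.na(f)) expect_true(all(ch$states[f:48] == 3))
  }
  k <- which(firsts >= 3 & firsts <= 46)[1]  # deterministic under the seed
  expect_false(is.na(k))
  ch <- chains[[k]]; f <- firsts[k]
  tr <- extract_trajectory(ch$windows_a, ch$windows_b, roi_default,
                           n_sims = 1, seed = 2)
  expect_gt(mean(tr$density_a[f:48]), mean(tr$density_a[1:(f - 1)]))
})

test_that("synchrony matches its closed-form limits", {
  tr <- structure(data.frame(time = 1:5, density_a = c(1, 2, 3, 4, 5),
                             density_b = c(1, 2, 3, 4, 5),
                             g_a = c(5, 4, 3, 2, 1), g_b = c(1, 2, 3, 4, 5),
                             eom_short = NA),
                  class = c("cluster_trajectory", "data.frame"))
  expect_equal(synchrony(tr, "density"), 1)
  expect_equal(synchrony(tr, "g"), -1)
  tr$density_b <- rep(2, 5)
  expect_warning(out <- synchrony(tr, "density"), "zero variance")
  expect_true(is.na(out))
  tr$density_a <- c(NA, NA, NA, 4, 5)
  expect_error(synchrony(tr, "density"), "fewer than 3")
})

test_that("programmed density synchrony of 0.8 is recovered without bias", {
  P2 <- matrix(c(0, 1, 0, 0, 1, 0, 0, 1, 0), 3, byrow = TRUE)  # stays in 2
  set.seed(73)
  est <- replicate(60, {
    ch <- gen_dynamic_assembly(P2, n_windows = 48, n_chains = 1,
                               sync_r = 0.8)[[1]]
    tr <- extract_trajectory(ch$windows_a, ch$windows_b, roi_default,
                             n_sims = 1)
    synchrony(tr, "density")
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.8), max(3 * se, 0.05))
})

test_that("the 3-state mixture recovers well-separated blobs deterministically", {
  set.seed(74)
  blobs <- rbind(cbind(rnorm(120, 10, 2), rnorm(120, 1.0, 0.2)),
                 cbind(rnorm(120, 60, 5), rnorm(120, 1.5, 0.3)),
                 cbind(rnorm(120, 60, 5), rnorm(120, 8.0, 0.8)))
  truth <- rep(1:3, each = 120)
  sm <- fit_state_model(blobs, seed = 1)
  expect_gte(mean(sm$classification == truth), 0.95)
  sm2 <- fit_state_model(blobs, seed = 1)
  expect_identical(sm$means, sm2$means)
  # permuting the input rows leaves the state convention unchanged
  perm <- sample(nrow(blobs))
  sm3 <- fit_state_model(blobs[perm, ], seed = 1)
  expect_gte(mean(sm3$classification == truth[perm]), 0.95)
  expect_equal(sm3$means, sm$means, tolerance = 1e-6)
  # prediction maps back to the generating blob
  expect_gte(mean(predict(sm, blobs) == truth), 0.95)
  expect_error(fit_state_model(blobs[1:10, ]), "at least 30")
  expect_error(fit_state_model(matrix(1, 50, 2)), "degenerate")
})

test_that("state labels follow the low/high density-g convention", {
  set.seed(75)
  blobs <- rbind(cbind(rnorm(100, 60, 5), rnorm(100, 8, 0.8)),   # mature
                 cbind(rnorm(100, 10, 2), rnorm(100, 1, 0.2)),   # dispersed
                 cbind(rnorm(100, 60, 5), rnorm(100, 1.5, 0.3))) # dense
  sm <- fit_state_model(blobs, seed = 1)
  expect_lt(sm$means[1, 1], sm$means[2, 1])  # state 1 lower density
  expect_lt(sm$means[2, 2], sm$means[3, 2])  # state 3 higher g
  expect_equal(sum(sm$weights), 1, tolerance = 1e-8)
})

test_that("transition counting matches exhaustive hand counts", {
  P <- transition_matrix(c(1, 1, 1, 1))
  expect_equal(P[1, ], c(state1 = 1, state2 = 0, state3 = 0))
  expect_equal(attr(P, "uniform_rows"), c(2L, 3L))
  expect_equal(P[2, ], c(state1 = 1, state2 = 1, state3 = 1) / 3)
  P2 <- transition_matrix(c(1, 2, 1, 2, 1))
  expect_equal(unname(P2[1, ]), c(0, 1, 0))
  expect_equal(unname(P2[2, ]), c(1, 0, 0))
  expect_error(transition_matrix(c(1, 4)), "labels")
  expect_error(transition_matrix(list(1L)), "length >= 2")
  # NA labels break pairs rather than being imputed
  P3 <- transition_matrix(c(1, NA, 2, 2))
  expect_equal(unname(attr(P3, "counts")[1, ]), c(0, 0, 0))
  expect_equal(unname(attr(P3, "counts")[2, 2]), 1)
})

test_that("rows are stochastic and the true matrix is recovered at scale", {
  set.seed(76)
  for (k in 1:5) {
    seqs <- replicate(10, sample(1:3, 20, replace = TRUE),
                      simplify = FALSE)
    P <- transition_matrix(seqs)
    expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-12)
  }
  Ptrue <- matrix(c(0.80, 0.15, 0.05,
                    0.30, 0.40, 0.30,
                    0.10, 0.20, 0.70), 3, byrow = TRUE)
  Phat <- transition_matrix(sim_state_sequence(Ptrue, 48, 41, seed = 77))
  expect_lte(sqrt(mean((Phat - Ptrue)^2)), 0.05)
  # the most persistent programmed state dominates the stationary mass
  expect_equal(unname(which.max(attr(Phat, "stationary"))), 1L)
})

test_that("state classification is invariant to consistent feature scaling", {
  set.seed(78)
  blobs <- rbind(cbind(rnorm(100, 10, 2), rnorm(100, 1, 0.2)),
                 cbind(rnorm(100, 60, 5), rnorm(100, 1.5, 0.3)),
                 cbind(rnorm(100, 60, 5), rnorm(100, 8, 0.8)))
  sm <- fit_state_model(blobs, seed = 1)
  scaled <- sweep(blobs, 2, c(1000, 0.01), "*")
  sm_s <- fit_state_model(scaled, seed = 1)
  expect_equal(sm_s$classification, sm$classification)
})

test_that("two-sample comparisons reproduce the textbook t statistic", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)  # pooled-variance hand calc
  expect_equal(res$df, 4)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$sem_x, 1 / sqrt(3))
  expect_error(compare_groups(rep(1, 5), rep(1, 5)), "zero combined")
  expect_error(compare_groups(1, c(2, 3)), "at least 2")
})

test_that("the t test detects a 2-sigma shift almost surely at n = 50", {
  set.seed(79)
  hits <- replicate(400, {
    compare_groups(rnorm(50), rnorm(50, mean = 2))$p_value < 0.05
  })
  expect_gt(mean(hits), 0.99)
})
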