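## Synthetic localization data with known ground truth.
##
## All generators are seed-reproducible and emulate the data regimes the
## analyses assume: complete spatial randomness, Thomas-type nanoclusters,
## bivariate mixtures spanning independence to exact random labeling,
## peripheral (annular) enrichment, domain-enriched two-species fields,
## photoblinking emitters over multi-thousand-frame acquisitions, and
## time-evolving cluster assembly driven by a 3-state Markov chain.
## Defaults use a 10 x 10 um window at densities of tens of molecules/um^2,
## the density scale of two-color PALM membrane data.

default_window <- function() owin_rect(0, 10000, 0, 10000)

wrap_into <- function(v, lo, hi) lo + (v - lo) %% (hi - lo)

#' Homogeneous Poisson (completely random) point pattern
#'
#' Count drawn as Poisson(density x area), positions uniform: the null
#' model against which clustering is measured (flat g(r) = 1).
#'
#' @param density intensity in molecules/um^2 (> 0).
#' @param window observation window in nm.
#' @param seed integer seed.
#' @param label optional channel label.
#' @return A [point_pattern()].
#' @export
gen_poisson <- function(density = 50, window = default_window(),
                        seed = NULL, label = NULL) {
  window <- as_window(window)
  if (density <= 0) stop("density must be positive")
  if (window_area(window) <= 0) stop("window area must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, density * window_area(window) / 1e6)
  point_pattern(runif(n, window[["xmin"]], window[["xmax"]]),
                runif(n, window[["ymin"]], window[["ymax"]]),
                window = window, label = label)
}

#' Thomas-process nanoclustered point pattern
#'
#' Canonical cluster model: Poisson-distributed parents, each with a
#' Poisson number of offspring displaced by an isotropic Gaussian of
#' standard deviation `sigma`; parents are discarded and offspring wrapped
#' periodically so the pattern stays homogeneous. Its pair-correlation
#' function is known in closed form, g(r) = 1 + exp(-r^2 / (4 sigma^2)) /
#' (4 pi sigma^2 kappa) with kappa the parent intensity, which makes the
#' generator usable as an analytic oracle.
#'
#' @param parent_density parent intensity in clusters/um^2.
#' @param offspring_mean mean molecules per cluster.
#' @param sigma cluster spread in nm (typical nanocluster scale 30-60 nm).
#' @inheritParams gen_poisson
#' @return A [point_pattern()]; attribute `"parents"` carries the parent
#'   coordinates (ground truth cluster centers), `"parent_id"` the
#'   generating parent of each point.
#' @export
gen_thomas <- function(parent_density = 0.5, offspring_mean = 20,
                       sigma = 30, window = default_window(),
                       seed = NULL, label = NULL) {
  window <- as_window(window)
  if (parent_density <= 0 || offspring_mean <= 0 || sigma <= 0)
    stop("parent_density, offspring_mean and sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_par <- rpois(1, parent_density * window_area(window) / 1e6)
  n_par <- max(n_par, 1L)
  cx <- runif(n_par, window[["xmin"]], window[["xmax"]])
  cy <- runif(n_par, window[["ymin"]], window[["ymax"]])
  n_off <- rpois(n_par, offspring_mean)
  pid <- rep(seq_len(n_par), n_off)
  x <- wrap_into(cx[pid] + rnorm(length(pid), 0, sigma),
                 window[["xmin"]], window[["xmax"]])
  y <- wrap_into(cy[pid] + rnorm(length(pid), 0, sigma),
                 window[["ymin"]], window[["ymax"]])
  p <- point_pattern(x, y, window = window, label = label)
  attr(p, "parents") <- cbind(x = cx, y = cy)
  attr(p, "parent_id") <- pid
  p
}

#' Closed-form Thomas pair-correlation function
#'
#' @param r distances in nm.
#' @param parent_density parent intensity in clusters/um^2.
#' @param sigma cluster spread in nm.
#' @return g(r) of the Thomas process.
#' @export
thomas_pcf <- function(r, parent_density, sigma) {
  kappa <- parent_density / 1e6  # nm^-2
  1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * sigma^2 * kappa)
}

#' Bivariate clustered pattern with controllable mixing fraction
#'
#' Generates one Thomas parent pattern and assigns species labels per
#' cluster: a fraction `f` of clusters are "mixed" (their points labeled by
#' random labeling, i.e. drawn from a balanced label pool), the rest are
#' single-species clusters (coin flip per cluster). `f = 1` is exact random
#' labeling of the full pattern (perfect mixing, EOM ~ 1); `f = 0` gives
#' two independent sets of single-species clusters (no interaction,
#' EOM ~ 0).
#'
#' @param f mixing fraction in \[0, 1\].
#' @inheritParams gen_thomas
#' @return A list with [point_pattern()]s `a` and `b` and the ground truth
#'   `f`.
#' @export
gen_random_label_mix <- function(f, parent_density = 0.5,
                                 offspring_mean = 20, sigma = 30,
                                 window = default_window(), seed = NULL) {
  if (f < 0 || f > 1) stop("mixing fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- gen_thomas(parent_density, offspring_mean, sigma, window)
  pid <- attr(p, "parent_id")
  n_par <- nrow(attr(p, "parents"))
  mixed_cluster <- runif(n_par) < f
  lab <- integer(length(pid))
  single <- !mixed_cluster[pid]
  if (any(single)) {
    cl_lab <- 1L + rbinom(n_par, 1, 0.5)
    lab[single] <- cl_lab[pid[single]]
  }
  mixed <- which(!single)
  if (length(mixed)) {
    pool <- rep(1:2, length.out = length(mixed))
    lab[mixed] <- sample(pool)
  }
  list(a = point_pattern(p$x[lab == 1], p$y[lab == 1], window = p$window,
                         label = "a"),
       b = point_pattern(p$x[lab == 2], p$y[lab == 2], window = p$window,
                         label = "b"),
       f = f)
}

#' Two-species pattern with peripheral (annular) enrichment
#'
#' Species A forms Thomas nanoclusters; species B points are placed
#' uniformly over annuli around the cluster centers (between `r_inner` and
#' `r_outer`), plus a uniform background fraction. This is the regime in
#' which one species decorates the edges of the other's self-clusters, and
#' it makes the CBC edge-enrichment signature true by construction.
#'
#' @param n_b number of species-B molecules.
#' @param r_inner,r_outer annulus radii in nm (`r_inner < r_outer`).
#' @param background_fraction fraction of B placed uniformly over the
#'   window (1 reduces to an independent pair).
#' @inheritParams gen_thomas
#' @return A list with patterns `a`, `b`, the cluster `centers`, and the
#'   parameters used.
#' @export
gen_periphery <- function(n_b = 500, r_inner = 60, r_outer = 120,
                          background_fraction = 0.2, parent_density = 0.5,
                          offspring_mean = 20, sigma = 30,
                          window = default_window(), seed = NULL) {
  if (r_inner >= r_outer) stop("r_inner must be smaller than r_outer")
  if (background_fraction < 0 || background_fraction > 1)
    stop("background_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  window <- as_window(window)
  a <- gen_thomas(parent_density, offspring_mean, sigma, window,
                  label = "a")
  centers <- attr(a, "parents")
  bg <- runif(n_b) < background_fraction
  n_ann <- sum(!bg)
  k <- sample.int(nrow(centers), n_ann, replace = TRUE)
  rr <- sqrt(runif(n_ann, r_inner^2, r_outer^2))  # uniform over annulus
  th <- runif(n_ann, 0, 2 * pi)
  bx <- c(wrap_into(centers[k, 1] + rr * cos(th),
                    window[["xmin"]], window[["xmax"]]),
          runif(sum(bg), window[["xmin"]], window[["xmax"]]))
  by <- c(wrap_into(centers[k, 2] + rr * sin(th),
                    window[["ymin"]], window[["ymax"]]),
          runif(sum(bg), window[["ymin"]], window[["ymax"]]))
  list(a = a, b = point_pattern(bx, by, window = window, label = "b"),
       centers = centers, r_inner = r_inner, r_outer = r_outer,
       background_fraction = background_fraction)
}

#' Two-species pattern with programmed in-domain fold enrichment
#'
#' Species A forms Thomas nanoclusters whose polygonal domains are built
#' with the domain module; species B is then placed with an intensity
#' `fold` times higher inside the domains than outside. The realized fold
#' (from the actual counts and areas) is recorded as ground truth.
#'
#' @param fold programmed in/out intensity ratio (>= 0).
#' @param density_b overall species-B intensity in molecules/um^2.
#' @param d_th,min_cluster_size,buffer domain-construction parameters
#'   (see [domain_params()]).
#' @inheritParams gen_thomas
#' @return A list with patterns `a`, `b`, the `"domain_set"` used, and
#'   `fold_programmed` / `fold_realized`.
#' @export
gen_domain_enrichment <- function(fold = 10, density_b = 20,
                                  parent_density = 0.3,
                                  offspring_mean = 25, sigma = 40,
                                  d_th = 80, min_cluster_size = 3,
                                  buffer = 40,
                                  window = default_window(), seed = NULL) {
  if (fold < 0) stop("fold must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  window <- as_window(window)
  a <- gen_thomas(parent_density, offspring_mean, sigma, window,
                  label = "a")
  ds <- domain_polygons(find_domains(a, domain_params(d_th,
                                                      min_cluster_size,
                                                      buffer)))
  a_in <- ds$total_domain_area
  a_out <- window_area(window) - a_in
  n_b <- rpois(1, density_b * window_area(window) / 1e6)
  p_in <- fold * a_in / (fold * a_in + a_out)
  n_in <- rbinom(1, n_b, p_in)
  sample_in_domains <- function(m) {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < m) {
      cand <- max(4 * (m - length(xs)), 50)
      cx <- runif(cand, window[["xmin"]], window[["xmax"]])
      cy <- runif(cand, window[["ymin"]], window[["ymax"]])
      inside <- rep(FALSE, cand)
      for (p in ds$polygons)
        inside <- inside | points_in_poly(p, cx, cy)
      xs <- c(xs, cx[inside]); ys <- c(ys, cy[inside])
    }
    cbind(xs[seq_len(m)], ys[seq_len(m)])
  }
  sample_out <- function(m) {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < m) {
      cand <- max(2 * (m - length(xs)), 50)
      cx <- runif(cand, window[["xmin"]], window[["xmax"]])
      cy <- runif(cand, window[["ymin"]], window[["ymax"]])
      inside <- rep(FALSE, cand)
      for (p in ds$polygons)
        inside <- inside | points_in_poly(p, cx, cy)
      xs <- c(xs, cx[!inside]); ys <- c(ys, cy[!inside])
    }
    cbind(xs[seq_len(m)], ys[seq_len(m)])
  }
  pin <- if (n_in > 0 && a_in > 0) sample_in_domains(n_in)
         else matrix(numeric(0), 0, 2)
  pout <- if (n_b - nrow(pin) > 0) sample_out(n_b - nrow(pin))
          else matrix(numeric(0), 0, 2)
  b <- point_pattern(c(pin[, 1], pout[, 1]), c(pin[, 2], pout[, 2]),
                     window = window, label = "b")
  fold_real <- if (a_in > 0 && nrow(pout) > 0)
    (nrow(pin) / a_in) / (nrow(pout) / a_out) else NA_real_
  list(a = a, b = b, domains = ds, fold_programmed = fold,
       fold_realized = fold_real, n_in = nrow(pin))
}

#' Photoblinking emitter movie
#'
#' Each ground-truth molecule sits at a fixed position and emits in one or
#' more on-bursts separated by short dark gaps; every frame appearance is
#' localized with isotropic Gaussian jitter. Ground-truth emitter ids are
#' retained so blinking-correction recovery can be validated. The default
#' acquisition matches live-cell imaging of 12,000 frames at 50 fps.
#'
#' @param n_emitters number of molecules.
#' @param n_frames,fps acquisition length (camera frames) and rate.
#' @param n_bursts_mean mean number of on-bursts per molecule (>= 1 burst
#'   always emitted).
#' @param on_frames_mean mean on-frames per burst (>= 1 frame).
#' @param off_gap_max longest dark gap between consecutive bursts of one
#'   molecule, in frames (gaps drawn uniformly from 1..`off_gap_max`;
#'   0 makes bursts contiguous).
#' @param jitter localization uncertainty (Gaussian sd) in nm.
#' @inheritParams gen_poisson
#' @return A [localization_table()]; records carry a `truth_id` column.
#' @export
gen_blinking_movie <- function(n_emitters = 200, n_frames = 12000,
                               fps = 50, n_bursts_mean = 2,
                               on_frames_mean = 3, off_gap_max = 3,
                               jitter = 20, window = default_window(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  window <- as_window(window)
  ex <- runif(n_emitters, window[["xmin"]], window[["xmax"]])
  ey <- runif(n_emitters, window[["ymin"]], window[["ymax"]])
  frames <- integer(0); ids <- integer(0)
  for (i in seq_len(n_emitters)) {
    nb <- 1L + rpois(1, max(n_bursts_mean - 1, 0))
    f <- sample.int(max(n_frames - 100L, 1L), 1)
    for (b in seq_len(nb)) {
      on <- 1L + rpois(1, max(on_frames_mean - 1, 0))
      fr <- f + seq_len(on) - 1L
      fr <- fr[fr <= n_frames]
      frames <- c(frames, fr); ids <- c(ids, rep(i, length(fr)))
      gap <- if (off_gap_max > 0) sample.int(off_gap_max, 1) else 0L
      f <- f + on + gap
      if (f > n_frames) break
    }
  }
  n <- length(frames)
  x <- pmin(pmax(ex[ids] + rnorm(n, 0, jitter), window[["xmin"]]),
            window[["xmax"]])
  y <- pmin(pmax(ey[ids] + rnorm(n, 0, jitter), window[["ymin"]]),
            window[["ymax"]])
  rec <- data.frame(frame = frames, x = x, y = y,
                    uncertainty = rep(jitter, n), truth_id = ids)
  rec <- rec[order(rec$frame), , drop = FALSE]
  rownames(rec) <- NULL
  localization_table(rec, window = window, fps = fps, n_frames = n_frames)
}

#' Simulate state sequences from a Markov chain
#'
#' @param P row-stochastic transition matrix.
#' @param length_out sequence length (number of time windows, default 48).
#' @param n_chains number of independent chains (default 1).
#' @param seed integer seed.
#' @param init initial distribution (default: stationary distribution of
#'   `P`).
#' @return A list of integer state sequences.
#' @export
sim_state_sequence <- function(P, length_out = 48, n_chains = 1,
                               seed = NULL, init = NULL) {
  P <- as.matrix(P)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix must be row-stochastic")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(P)
  if (is.null(init)) init <- stationary_distribution(P)
  lapply(seq_len(n_chains), function(ch) {
    s <- integer(length_out)
    s[1] <- sample.int(k, 1, prob = init)
    for (t in seq_len(length_out - 1))
      s[t + 1] <- sample.int(k, 1, prob = P[s[t], ])
    s
  })
}

#' Dynamic cluster assembly movie driven by a latent 3-state Markov chain
#'
#' For each cluster ROI, a latent state sequence is drawn from `P`
#' (state 1 = dispersed, 2 = dense unclustered, 3 = dense clustered) and
#' each time window's two-species point patterns are generated with
#' state-dependent density and clustering: Poisson placement in states 1-2,
#' Thomas nanoclusters in state 3. When `sync_r` is set, the two species'
#' intensities are additionally co-driven by a shared Gaussian recruitment
#' signal calibrated so the Pearson correlation between the measured
#' density series equals `sync_r` (accounting for Poisson counting noise).
#'
#' @param P 3x3 row-stochastic transition matrix.
#' @param n_windows windows per chain (default 48, i.e. 4 min of 5-s
#'   windows).
#' @param n_chains number of cluster ROIs (default 41).
#' @param roi ROI rectangle (default 1.5 x 1.5 um).
#' @param state_density per-state mean intensity, molecules/um^2.
#' @param sigma cluster spread in state 3, nm.
#' @param clusters_state3 mean number of nanoclusters in the ROI in
#'   state 3.
#' @param sync_r optional programmed density synchrony in (0, 1).
#' @param shared_sd sd of the shared recruitment signal (molecules/um^2)
#'   used when `sync_r` is set.
#' @param init initial state distribution (default: stationary
#'   distribution of `P`).
#' @param seed integer seed.
#' @return A list of chains; each chain has `windows_a`, `windows_b` (lists
#'   of [point_pattern()]s with 5-s spacing) and the true `states`.
#' @export
gen_dynamic_assembly <- function(P = matrix(c(0.8, 0.1, 0.1,
                                              0.3, 0.4, 0.3,
                                              0.1, 0.1, 0.8),
                                            3, 3, byrow = TRUE),
                                 n_windows = 48, n_chains = 41,
                                 roi = owin_rect(0, 1500, 0, 1500),
                                 state_density = c(10, 60, 60),
                                 sigma = 40, clusters_state3 = 4,
                                 sync_r = NULL, shared_sd = 13,
                                 init = NULL, seed = NULL) {
  P <- as.matrix(P)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix must be row-stochastic")
  if (!is.null(seed)) set.seed(seed)
  roi <- as_window(roi)
  area_um2 <- window_area(roi) / 1e6
  noise_sd <- 0
  if (!is.null(sync_r)) {
    if (sync_r <= 0 || sync_r >= 1) stop("sync_r must lie in (0, 1)")
    # Var(measured density) = tau^2 + sigma_eps^2 + mu/area; the shared
    # signal tau^2 must exceed r * mu / (area * (1 - r)). The calibration
    # is exact when the chain occupies a single state (no state-driven
    # shared variance); mu is the stationary-weighted mean intensity.
    mu <- sum(stationary_distribution(P) * state_density)
    s2 <- shared_sd^2 * (1 - sync_r) / sync_r - mu / area_um2
    if (s2 < 0)
      stop("shared_sd too small for the requested sync_r")
    noise_sd <- sqrt(s2)
  }
  draw_window <- function(state, lam, t0, t1) {
    n <- rpois(1, max(lam, 0) * area_um2)
    if (state == 3 && n > 0) {
      nc <- max(1L, rpois(1, clusters_state3))
      cx <- runif(nc, roi[["xmin"]], roi[["xmax"]])
      cy <- runif(nc, roi[["ymin"]], roi[["ymax"]])
      k <- sample.int(nc, n, replace = TRUE)
      x <- wrap_into(cx[k] + rnorm(n, 0, sigma), roi[["xmin"]],
                     roi[["xmax"]])
      y <- wrap_into(cy[k] + rnorm(n, 0, sigma), roi[["ymin"]],
                     roi[["ymax"]])
    } else {
      x <- runif(n, roi[["xmin"]], roi[["xmax"]])
      y <- runif(n, roi[["ymin"]], roi[["ymax"]])
    }
    point_pattern(x, y, window = roi, t_start = t0, t_end = t1)
  }
  lapply(seq_len(n_chains), function(ch) {
    states <- sim_state_sequence(P, n_windows, init = init)[[1]]
    wa <- vector("list", n_windows); wb <- vector("list", n_windows)
    for (t in seq_len(n_windows)) {
      base <- state_density[states[t]]
      if (!is.null(sync_r)) {
        z <- rnorm(1, 0, shared_sd)
        la <- base + z + rnorm(1, 0, noise_sd)
        lb <- base + z + rnorm(1, 0, noise_sd)
      } else {
        la <- base * exp(rnorm(1, 0, 0.1))
        lb <- base * exp(rnorm(1, 0, 0.1))
      }
      wa[[t]] <- draw_window(states[t], la, (t - 1) * 5, t * 5)
      wb[[t]] <- draw_window(states[t], lb, (t - 1) * 5, t * 5)
    }
    list(windows_a = wa, windows_b = wb, states = states)
  })
}
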