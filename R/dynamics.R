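#' Per-cluster time-resolved feature trajectory
#'
#' For each pair of acquisition windows (one per species), crops both to a
#' region of interest (by convention 1.5 x 1.5 um around a single cluster)
#' and extracts the features of the density-clustering state map: molecular
#' density, short-range self-clustering g(0-100) and, where both species
#' are present, the mean short-range extent of mixing.
#'
#' @param windows_a,windows_b equal-length lists of [point_pattern()]s (see
#'   [window_by_frames()]); `windows_b` may be `NULL` for single-species
#'   trajectories.
#' @param roi the ROI rectangle in nm (an [owin_rect()]).
#' @param bins radial bins for the per-window PCF (default 10-nm bins to
#'   200 nm, appropriate for a 1.5-um ROI).
#' @param r_short upper range in nm of the short-range summaries
#'   (default 100).
#' @param n_sims random-labeling simulations per window for the EOM
#'   (default 19).
#' @param seed integer seed for the EOM envelopes.
#' @param edge_correction edge correction for per-window curves.
#' @return A data.frame of class `"cluster_trajectory"` with columns
#'   `time`, `density_a`, `density_b`, `g_a`, `g_b`, `eom_short`; windows
#'   with fewer than 2 points get `NA` features (density 0 when empty).
#' @export
extract_trajectory <- function(windows_a, windows_b = NULL, roi,
                               bins = radial_bins(0, 200, 10),
                               r_short = 100, n_sims = 19, seed = NULL,
                               edge_correction = "translation") {
  if (!is.null(windows_b) && length(windows_a) != length(windows_b))
    stop("window lists must have equal length")
  if (!is.null(seed)) set.seed(seed)
  n <- length(windows_a)
  g_of <- function(p) {
    if (npoints(p) < 2) return(NA_real_)
    mean_g_short(pcf(p, bins, edge_correction), r_short)
  }
  out <- data.frame(time = rep(NA_real_, n), density_a = NA_real_,
                    density_b = NA_real_, g_a = NA_real_, g_b = NA_real_,
                    eom_short = NA_real_)
  for (k in seq_len(n)) {
    a <- crop_roi(windows_a[[k]], roi)
    out$time[k] <- if (is.null(a$t_start)) k else a$t_start
    out$density_a[k] <- pp_density(a)
    out$g_a[k] <- g_of(a)
    if (!is.null(windows_b)) {
      b <- crop_roi(windows_b[[k]], roi)
      out$density_b[k] <- pp_density(b)
      out$g_b[k] <- g_of(b)
      if (npoints(a) >= 1 && npoints(b) >= 1 && npoints(a) + npoints(b) >= 4) {
        env <- rl_envelope(a, b, bins, n_sims = n_sims,
                           edge_correction = edge_correction)
        ec <- eom(bpcf(a, b, bins, edge_correction), env)
        keep <- is.finite(ec$eom) & ec$bins$centers < r_short
        out$eom_short[k] <- if (any(keep)) mean(ec$eom[keep]) else NA_real_
      }
    }
  }
  class(out) <- c("cluster_trajectory", "data.frame")
  out
}

#' Synchrony of two species' trajectories
#'
#' Pearson correlation between the species-a and species-b series of one
#' trajectory feature over pairwise-complete time points, quantifying how
#' synchronously the two species (dis)assemble.
#'
#' @param traj a `"cluster_trajectory"` from [extract_trajectory()].
#' @param feature `"density"` or `"g"`.
#' @return The Pearson correlation; `NA` (with a warning) when either
#'   series has zero variance.
#' @export
synchrony <- function(traj, feature = c("density", "g")) {
  feature <- match.arg(feature)
  a <- traj[[paste0(if (feature == "density") "density" else "g", "_a")]]
  b <- traj[[paste0(if (feature == "density") "density" else "g", "_b")]]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("fewer than 3 paired defined values")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    warning("zero variance: synchrony undefined")
    return(NA_real_)
  }
  cor(a[ok], b[ok])
}

#' Fit the 3-state Gaussian mixture on the density-clustering map
#'
#' Fits a 3-component Gaussian mixture (full covariances) to pooled
#' (density, g(0-100)) observations, after z-scoring each feature (their
#' raw units differ by orders of magnitude). Components are relabeled to a
#' fixed convention so states are comparable across fits: state 1 =
#' dispersed molecules (low density, low g), state 2 = dense but weakly
#' clustered domains (high density, low g), state 3 = mature clusters
#' (high density, high g).
#'
#' @param x a matrix or data.frame whose first two columns are density
#'   (molecules/um^2) and g(0-100); rows with missing values are dropped.
#' @param seed integer seed (the mixture fit is deterministic given the
#'   data; the seed is set for strict reproducibility of any downstream
#'   randomness).
#' @return An object of class `"state_model"` with component `means`,
#'   `covariances`, `weights` (on the original scale for the means),
#'   the training `classification`, and the standardization used.
#' @seealso [predict.state_model()], [transition_matrix()]
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_state_model <- function(x, seed = 1) {
  x <- as.matrix(as.data.frame(x)[, 1:2])
  colnames(x) <- c("density", "g")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 30) stop("at least 30 observations are required")
  if (all(apply(x, 2, sd) == 0)) stop("degenerate data: all observations identical")
  set.seed(seed)
  ctr <- colMeans(x); scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  z <- scale(x, ctr, scl)
  fit <- Mclust(z, G = 3, modelNames = "VVV", verbose = FALSE)
  if (is.null(fit)) fit <- Mclust(z, G = 3, verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  mu_z <- t(fit$parameters$mean)  # components x features (z scale)
  # state order: highest-g component -> 3; remaining two by density
  perm <- integer(3)
  perm[3] <- which.max(mu_z[, 2])
  rest <- setdiff(1:3, perm[3])
  perm[1] <- rest[which.min(mu_z[rest, 1])]
  perm[2] <- setdiff(rest, perm[1])
  relabel <- match(seq_len(3), perm)  # component -> state
  mu <- sweep(sweep(mu_z[perm, , drop = FALSE], 2, scl, "*"), 2, ctr, "+")
  rownames(mu) <- paste0("state", 1:3)
  covs <- lapply(perm, function(k) {
    S <- fit$parameters$variance$sigma[, , k]
    diag(scl) %*% S %*% diag(scl)
  })
  structure(list(means = mu, covariances = covs,
                 weights = fit$parameters$pro[perm],
                 classification = relabel[fit$classification],
                 center = ctr, scale = scl, mclust_fit = fit,
                 component_to_state = relabel, n = nrow(x), data = x),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("3-state Gaussian mixture on the density-clustering map\n")
  cat(sprintf("  fitted to %d observations\n", x$n))
  tab <- cbind(round(x$means, 3), weight = round(x$weights, 3),
               n = tabulate(x$classification, 3))
  print(tab)
  invisible(x)
}

#' @export
summary.state_model <- function(object, ...) {
  occ <- tabulate(object$classification, 3) / object$n
  cat("3-state Gaussian mixture model\n")
  cat(sprintf("  state 1 (dispersed):      density %8.2f  g %6.2f  occupancy %.2f\n",
              object$means[1, 1], object$means[1, 2], occ[1]))
  cat(sprintf("  state 2 (dense domains):  density %8.2f  g %6.2f  occupancy %.2f\n",
              object$means[2, 1], object$means[2, 2], occ[2]))
  cat(sprintf("  state 3 (mature clusters):density %8.2f  g %6.2f  occupancy %.2f\n",
              object$means[3, 1], object$means[3, 2], occ[3]))
  invisible(list(means = object$means, weights = object$weights,
                 occupancy = occ))
}

#' Classify new observations into cluster states
#'
#' @param object a `"state_model"`.
#' @param newdata matrix/data.frame with density and g(0-100) columns; rows
#'   with missing values get `NA` labels.
#' @param ... unused.
#' @return Integer state labels in 1..3 (attribute `"posterior"` carries
#'   the posterior probabilities of the defined rows).
#' @export
predict.state_model <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, 1:2])
  ok <- stats::complete.cases(nd)
  lab <- rep(NA_integer_, nrow(nd))
  if (any(ok)) {
    z <- scale(nd[ok, , drop = FALSE], object$center, object$scale)
    pr <- stats::predict(object$mclust_fit, newdata = z)
    lab[ok] <- object$component_to_state[pr$classification]
    post <- pr$z[, order(object$component_to_state), drop = FALSE]
    colnames(post) <- paste0("state", 1:3)
    attr(lab, "posterior") <- post
  }
  lab
}

#' @export
plot.state_model <- function(x, col = c("forestgreen", "firebrick",
                                        "royalblue"),
                             xlab = "density [molecules/um^2]",
                             ylab = "g(0-100)", ...) {
  plot(x$data[, 1], x$data[, 2], col = col[x$classification], pch = 16,
       cex = 0.6, xlab = xlab, ylab = ylab, ...)
  points(x$means[, 1], x$means[, 2], pch = 3, cex = 2, lwd = 2, col = col)
  legend("topleft", bty = "n", pch = 16, col = col,
         legend = c("state 1: dispersed", "state 2: dense domains",
                    "state 3: mature clusters"))
  invisible(x)
}

#' Maximum-likelihood Markov transition matrix between cluster states
#'
#' Pools transitions between consecutive time windows (one acquisition
#' window apart, 5 s at the default imaging settings) across all supplied
#' state sequences and normalizes each row. `NA` labels break transition
#' pairs rather than being imputed. States never left get a uniform row,
#' flagged in the `"uniform_rows"` attribute.
#'
#' @param state_sequences an integer vector or list of integer vectors with
#'   labels in 1..`n_states`.
#' @param n_states number of states (default 3).
#' @return An `n_states` x `n_states` row-stochastic matrix; attribute
#'   `"counts"` carries the transition counts and `"stationary"` the
#'   stationary distribution of the estimated chain.
#' @export
transition_matrix <- function(state_sequences, n_states = 3) {
  if (!is.list(state_sequences)) state_sequences <- list(state_sequences)
  counts <- matrix(0, n_states, n_states)
  for (s in state_sequences) {
    s <- as.integer(s)
    if (any(!is.na(s) & (s < 1 | s > n_states)))
      stop("state labels must lie in 1..", n_states)
    if (length(s) < 2) stop("each sequence must have length >= 2")
    from <- s[-length(s)]; to <- s[-1]
    ok <- !is.na(from) & !is.na(to)
    for (i in which(ok)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, 1)
  uniform <- rs == 0
  P[uniform, ] <- 1 / n_states
  dimnames(P) <- dimnames(counts) <-
    list(paste0("state", seq_len(n_states)),
         paste0("state", seq_len(n_states)))
  attr(P, "counts") <- counts
  attr(P, "uniform_rows") <- which(uniform)
  attr(P, "stationary") <- stationary_distribution(P)
  P
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P a row-stochastic transition matrix.
#' @return The left eigenvector of eigenvalue 1, normalized to sum to 1.
#' @export
stationary_distribution <- function(P) {
  ev <- eigen(t(P))
  k <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, k])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(P))
}

#' Two-sample comparison by Student's t test
#'
#' Two-tailed two-sample t test (classic pooled-variance Student test by
#' default; set `var_equal = FALSE` for the Welch correction) with the
#' per-group standard errors of the mean, the summary used to compare
#' densities or EOM values between conditions with significance at
#' p < 0.05.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param var_equal assume equal variances (classic Student test,
#'   default `TRUE`).
#' @return A list with `t`, `p_value`, `df`, `mean_x`, `mean_y`, `sem_x`,
#'   `sem_y`.
#' @export
compare_groups <- function(x, y, var_equal = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each sample must contain at least 2 values")
  if (var(x) + var(y) == 0) stop("zero combined variance: test undefined")
  tt <- t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_x = mean(x), mean_y = mean(y),
       sem_x = sd(x) / sqrt(length(x)), sem_y = sd(y) / sqrt(length(y)))
}
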