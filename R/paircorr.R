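#' Radial distance bins
#'
#' Annulus bins for radial statistics g(r). Bins are the half-open
#' intervals (edge[k], edge[k+1]]; the default is 10-nm-wide bins from 0 to
#' 1000 nm.
#'
#' @param from,to,width bin range and width in nm, or
#' @param edges explicit strictly increasing edge vector starting at >= 0.
#' @return A list of class `"radial_bins"` with `edges` and `centers`.
#' @export
radial_bins <- function(from = 0, to = 1000, width = 10, edges = NULL) {
  if (is.null(edges)) edges <- seq(from, to, by = width)
  edges <- as.numeric(edges)
  if (length(edges) < 2 || any(diff(edges) <= 0) || edges[1] < 0)
    stop("bin edges must be strictly increasing and start at >= 0")
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2),
            class = "radial_bins")
}

same_bins <- function(a, b) {
  length(a$edges) == length(b$edges) && all(abs(a$edges - b$edges) < 1e-9)
}

edge_mode_code <- function(edge_correction) {
  match(match.arg(edge_correction, c("none", "periodic", "translation")),
        c("none", "periodic", "translation")) - 1L
}

pcf_curve <- function(bins, g, kind, n1, n2 = NA_integer_,
                      edge_correction) {
  structure(list(bins = bins, g = g, kind = kind, n1 = n1, n2 = n2,
                 edge_correction = edge_correction),
            class = "pcf_curve")
}

#' Univariate pair-correlation function g(r)
#'
#' Quantifies how molecular density varies with distance from a typical
#' point, normalized by the overall density so that a homogeneous Poisson
#' (completely random) pattern has g(r) = 1 in every bin; g(r) > 1 at short
#' r indicates self-clustering. Per bin, the observed (ordered, self-pairs
#' excluded) pair count is divided by the count expected for a Poisson
#' pattern of the same density in that annulus.
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @param bins a [radial_bins()].
#' @param edge_correction `"translation"` (default; appropriate for real
#'   rectangular fields), `"periodic"` (torus distances; appropriate for
#'   synthetic patterns generated with wrap-around) or `"none"`.
#' @return A `"pcf_curve"` with per-bin `g`.
#' @examples
#' set.seed(1)
#' p <- gen_poisson(density = 50, window = owin_rect(0, 5000, 0, 5000))
#' curve <- pcf(p, radial_bins(0, 500, 10), edge_correction = "periodic")
#' mean(curve$g)  # ~ 1 for a random pattern
#' @export
pcf <- function(pattern, bins = radial_bins(),
                edge_correction = c("translation", "periodic", "none")) {
  edge_correction <- match.arg(edge_correction)
  n <- npoints(pattern)
  if (n < 2) stop("at least 2 points are required to estimate g(r)")
  w <- pattern$window
  wx <- w[["xmax"]] - w[["xmin"]]; wy <- w[["ymax"]] - w[["ymin"]]
  A <- wx * wy
  s <- pair_weights_uni(pattern$x, pattern$y, bins$edges, wx, wy,
                        edge_mode_code(edge_correction))
  area_k <- pi * diff(bins$edges^2)
  g <- if (edge_correction == "translation")
    s * A^2 / (n * (n - 1)) / area_k
  else
    s / (n * (n - 1) * area_k / A)
  pcf_curve(bins, g, "univariate", n1 = n,
            edge_correction = edge_correction)
}

#' Bivariate pair-correlation function g12(r)
#'
#' Density of pattern `b` at distance r from a typical point of pattern
#' `a`, normalized by the density of `b` so that two independent patterns
#' give g12(r) = 1. All ordered cross pairs are counted; coincident pairs
#' (distance exactly 0) fall below the first bin edge.
#'
#' @param a,b [point_pattern()]s sharing one observation window.
#' @inheritParams pcf
#' @return A `"pcf_curve"` with per-bin `g` (kind `"bivariate"`).
#' @export
bpcf <- function(a, b, bins = radial_bins(),
                 edge_correction = c("translation", "periodic", "none")) {
  edge_correction <- match.arg(edge_correction)
  if (!same_window(a, b)) stop("patterns must share one observation window")
  n1 <- npoints(a); n2 <- npoints(b)
  if (n1 < 1 || n2 < 1) stop("both patterns must be non-empty")
  w <- a$window
  wx <- w[["xmax"]] - w[["xmin"]]; wy <- w[["ymax"]] - w[["ymin"]]
  A <- wx * wy
  s <- pair_weights_bi(a$x, a$y, b$x, b$y, bins$edges, wx, wy,
                       edge_mode_code(edge_correction))
  area_k <- pi * diff(bins$edges^2)
  g <- if (edge_correction == "translation")
    s * A^2 / (n1 * n2) / area_k
  else
    s / (n1 * n2 * area_k / A)
  pcf_curve(bins, g, "bivariate", n1 = n1, n2 = n2,
            edge_correction = edge_correction)
}

#' @export
print.pcf_curve <- function(x, ...) {
  cat(sprintf("%s pair-correlation curve, %d bins (%g-%g nm), %s correction\n",
              x$kind, length(x$g), x$bins$edges[1],
              x$bins$edges[length(x$bins$edges)], x$edge_correction))
  cat(sprintf("  g(0-100 nm) = %.3f\n",
              tryCatch(mean_g_short(x), error = function(e) NA_real_)))
  invisible(x)
}

#' @export
plot.pcf_curve <- function(x, envelope = NULL, type = "l",
                           ylab = expression(g(r)), xlab = "r [nm]", ...) {
  plot(x$bins$centers, x$g, type = type, xlab = xlab, ylab = ylab, ...)
  if (!is.null(envelope)) {
    polygon(c(envelope$bins$centers, rev(envelope$bins$centers)),
            c(envelope$lo, rev(envelope$hi)),
            col = adjustcolor("grey60", 0.4), border = NA)
    lines(x$bins$centers, x$g)
  }
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Monte Carlo random-labeling envelope for g12(r)
#'
#' Simulates the random-labeling (perfect mixing) null: the n1 + n2
#' observed positions are kept fixed and the species labels are reshuffled
#' (preserving counts) `n_sims` times; g12(r) is recomputed for each
#' relabeling. The per-bin lowest and highest simulated values form a
#' one-sided ~95% acceptance band when `n_sims = 19`.
#'
#' @param a,b [point_pattern()]s sharing one window.
#' @param bins a [radial_bins()].
#' @param n_sims number of relabelings (default 19).
#' @param seed integer seed for reproducibility.
#' @inheritParams pcf
#' @return A list of class `"rl_envelope"` with per-bin `lo`, `hi`,
#'   `mean_sim`.
#' @export
rl_envelope <- function(a, b, bins = radial_bins(), n_sims = 19, seed = NULL,
                        edge_correction = c("translation", "periodic",
                                            "none")) {
  edge_correction <- match.arg(edge_correction)
  if (n_sims < 1) stop("n_sims must be >= 1")
  if (!same_window(a, b)) stop("patterns must share one observation window")
  n1 <- npoints(a); n2 <- npoints(b)
  if (n1 + n2 < 2) stop("combined pattern must contain at least 2 points")
  if (!is.null(seed)) set.seed(seed)
  px <- c(a$x, b$x); py <- c(a$y, b$y)
  sims <- matrix(NA_real_, nrow = n_sims, ncol = length(bins$centers))
  for (s in seq_len(n_sims)) {
    lab <- sample.int(n1 + n2, n1)
    sa <- point_pattern(px[lab], py[lab], window = a$window)
    sb <- point_pattern(px[-lab], py[-lab], window = a$window)
    sims[s, ] <- bpcf(sa, sb, bins, edge_correction)$g
  }
  structure(list(bins = bins,
                 lo = apply(sims, 2, min),
                 hi = apply(sims, 2, max),
                 mean_sim = colMeans(sims),
                 n_sims = n_sims, seed = seed,
                 edge_correction = edge_correction),
            class = "rl_envelope")
}

#' @export
print.rl_envelope <- function(x, ...) {
  cat(sprintf("Random-labeling envelope: %d simulations, %d bins\n",
              x$n_sims, length(x$lo)))
  invisible(x)
}

#' Extent of mixing (EOM)
#'
#' Normalizes an observed bivariate pair-correlation curve between the two
#' null models: EOM = (g12 - 1) / (RL mean - 1), so a pattern matching the
#' random-labeling expectation (perfect mixing) scores +1 in each bin and a
#' flat g12 = 1 (no interaction between the species) scores 0. Bins where
#' the random-labeling mean is itself within `tol` of 1 carry no mixing
#' information and are reported as `NA`.
#'
#' @param observed a bivariate `"pcf_curve"` from [bpcf()].
#' @param envelope a matching [rl_envelope()].
#' @param tol degeneracy tolerance on |RL mean - 1| (default 0.05).
#' @param clip if `TRUE`, clip values into \[0, 1\]; default reports
#'   unclipped values.
#' @return A list of class `"eom_curve"` with per-bin `eom`.
#' @export
eom <- function(observed, envelope, tol = 0.05, clip = FALSE) {
  if (!same_bins(observed$bins, envelope$bins))
    stop("observed curve and envelope use different bins")
  denom <- envelope$mean_sim - 1
  e <- (observed$g - 1) / denom
  e[abs(denom) < tol] <- NA_real_
  if (clip) e <- pmin(pmax(e, 0), 1)
  structure(list(bins = observed$bins, eom = e, n_cells = NULL),
            class = "eom_curve")
}

#' @export
print.eom_curve <- function(x, ...) {
  ok <- is.finite(x$eom)
  short <- ok & x$bins$centers < 100
  cat(sprintf("EOM curve: %d/%d defined bins; mean EOM(r < 100 nm) = %.3f\n",
              sum(ok), length(x$eom),
              if (any(short)) mean(x$eom[short]) else NA_real_))
  invisible(x)
}

#' @export
plot.eom_curve <- function(x, type = "l", ylab = "EOM", xlab = "r [nm]",
                           ...) {
  plot(x$bins$centers, x$eom, type = type, xlab = xlab, ylab = ylab, ...)
  abline(h = c(0, 1), lty = 3)
  invisible(x)
}

#' Short-range clustering summary g(0-100)
#'
#' Unweighted mean of g over the bins with center in (0, r_max]; with the
#' default r_max = 100 nm this is the g(0-100) summary plotted on the
#' density-clustering state map.
#'
#' @param curve a `"pcf_curve"`.
#' @param r_max upper range in nm (default 100).
#' @return A scalar.
#' @export
mean_g_short <- function(curve, r_max = 100) {
  keep <- curve$bins$centers > 0 & curve$bins$centers <= r_max
  if (!any(keep)) stop("no bins with center in (0, r_max]")
  mean(curve$g[keep])
}

#' Average EOM curves over cells
#'
#' Per-bin mean over the defined values of several EOM curves (e.g. one per
#' cell); bins undefined in some curves are averaged over the remaining
#' ones. The number of contributing curves per bin is retained.
#'
#' @param curves a non-empty list of `"eom_curve"` objects on shared bins.
#' @return An `"eom_curve"` with an `n_cells` per-bin count.
#' @export
eom_average <- function(curves) {
  if (!length(curves)) stop("no EOM curves to average")
  b <- curves[[1]]$bins
  for (cv in curves) if (!same_bins(cv$bins, b))
    stop("EOM curves use different bins")
  m <- do.call(rbind, lapply(curves, function(cv) cv$eom))
  structure(list(bins = b,
                 eom = colMeans(m, na.rm = TRUE),
                 n_cells = colSums(is.finite(m))),
            class = "eom_curve")
}
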