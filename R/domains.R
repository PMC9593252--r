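#' Nanodomain detection parameters
#'
#' @param d_th link-distance threshold in nm (default 80 nm): two molecules
#'   belong to one domain iff they are connected by a chain of links each of
#'   length <= `d_th`. Typical sensitivity checks rerun at 60 and 100 nm.
#' @param min_cluster_size minimum number of molecules for a cluster to be
#'   promoted to a polygonal domain (default 3; monomers and dimers are
#'   still tallied in the size classes).
#' @param buffer morphological dilation in nm applied when building domain
#'   polygons (default `d_th / 2`, so boundaries extend half a link beyond
#'   member molecules).
#' @return A list of class `"domain_params"`.
#' @export
domain_params <- function(d_th = 80, min_cluster_size = 3,
                          buffer = d_th / 2) {
  if (!is.finite(d_th) || d_th <= 0) stop("d_th must be positive")
  if (buffer < 0) stop("buffer must be non-negative")
  structure(list(d_th = d_th,
                 min_cluster_size = as.integer(min_cluster_size),
                 buffer = buffer),
            class = "domain_params")
}

#' Fixed-radius clustering of molecules into nanodomains
#'
#' Range-search clustering: molecules within `d_th` of each other are
#' linked, and clusters are the connected components of the link graph
#' (equivalently, single-linkage clustering cut at height `d_th`). There is
#' no core-point condition, so monomers and dimers are legitimate size
#' classes; the partition is order-invariant.
#'
#' @param pattern a non-empty [point_pattern()].
#' @param params a [domain_params()].
#' @return A `"domain_set"` holding the membership partition and the size
#'   classes (monomers, dimers, 3-, 4-, 5-mers and larger). Polygons are
#'   populated by [domain_polygons()].
#' @export
find_domains <- function(pattern, params = domain_params()) {
  if (npoints(pattern) < 1) stop("pattern must be non-empty")
  n <- npoints(pattern)
  membership <- if (n == 1L) 1L else {
    hc <- hclust(dist(cbind(pattern$x, pattern$y)), method = "single")
    cutree(hc, h = params$d_th)
  }
  sizes <- tabulate(membership)
  size_classes <- c(monomer = sum(sizes == 1), dimer = sum(sizes == 2),
                    `3mer` = sum(sizes == 3), `4mer` = sum(sizes == 4),
                    `5mer` = sum(sizes == 5), `6mer+` = sum(sizes >= 6))
  structure(list(pattern = pattern, membership = membership,
                 sizes = sizes, size_classes = size_classes,
                 params = params, polygons = NULL,
                 total_domain_area = NA_real_),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("Domain set: %d molecules in %d clusters (d_th = %g nm)\n",
              npoints(x$pattern), length(x$sizes), x$params$d_th))
  print(x$size_classes)
  if (!is.null(x$polygons))
    cat(sprintf("  %d polygonal domains, total area %.4g um^2 (%.2f%% of window)\n",
                length(x$polygons), x$total_domain_area / 1e6,
                100 * x$total_domain_area / window_area(x$pattern$window)))
  invisible(x)
}

## ---- polygon geometry helpers -------------------------------------------

shoelace_area <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  abs(sum(px[j] * py - px * py[j])) / 2
}

poly_perimeter <- function(px, py) {
  j <- c(seq_len(length(px))[-1], 1L)
  sum(sqrt((px[j] - px)^2 + (py[j] - py)^2))
}

# Area of the union of equal discs with (near-)collinear centers, sorted
# along their principal direction. Exact for collinear centers because the
# intersection of two discs is contained in the disc of any center between
# them.
disc_union_area <- function(px, py, b) {
  if (b <= 0) return(0)
  k <- length(px)
  if (k == 1L) return(pi * b^2)
  o <- order(px + py * 1e-9, py)
  dirx <- px[o[k]] - px[o[1]]; diry <- py[o[k]] - py[o[1]]
  nrm <- sqrt(dirx^2 + diry^2)
  o <- if (nrm > 0) order(px * dirx + py * diry) else seq_len(k)
  px <- px[o]; py <- py[o]
  lens <- function(d) {
    if (d >= 2 * b) return(0)
    2 * b^2 * acos(d / (2 * b)) - d / 2 * sqrt(4 * b^2 - d^2)
  }
  a <- pi * b^2
  for (i in 2:k) {
    d <- sqrt((px[i] - px[i - 1])^2 + (py[i] - py[i - 1])^2)
    a <- a + pi * b^2 - lens(d)
  }
  a
}

# Distance from points (x, y) to a convex polygon (vertices in order);
# 0 inside or on the boundary.
dist_to_convex_poly <- function(x, y, px, py) {
  n <- length(px)
  j <- c(seq_len(n)[-1], 1L)
  inside <- rep(TRUE, length(x))
  mind <- rep(Inf, length(x))
  # orientation sign of the polygon
  orient <- sign(sum((px[j] - px) * (py[j] + py)))
  for (e in seq_len(n)) {
    ax <- px[e]; ay <- py[e]; bx <- px[j[e]]; by <- py[j[e]]
    ex <- bx - ax; ey <- by - ay
    cross <- ex * (y - ay) - ey * (x - ax)
    inside <- inside & (if (orient <= 0) cross >= -1e-9 else cross <= 1e-9)
    len2 <- ex^2 + ey^2
    t <- if (len2 > 0) pmin(pmax(((x - ax) * ex + (y - ay) * ey) / len2, 0), 1)
         else rep(0, length(x))
    mind <- pmin(mind, sqrt((x - (ax + t * ex))^2 + (y - (ay + t * ey))^2))
  }
  d <- mind
  d[inside] <- 0
  d
}

domain_poly_area <- function(poly) {
  if (poly$type == "hull") {
    b <- poly$buffer
    shoelace_area(poly$px, poly$py) +
      poly_perimeter(poly$px, poly$py) * b + pi * b^2
  } else {
    disc_union_area(poly$px, poly$py, poly$buffer)
  }
}

points_in_poly <- function(poly, x, y) {
  if (poly$type == "hull") {
    dist_to_convex_poly(x, y, poly$px, poly$py) <= poly$buffer + 1e-9
  } else {
    b <- poly$buffer
    inside <- rep(FALSE, length(x))
    for (i in seq_along(poly$px))
      inside <- inside |
        ((x - poly$px[i])^2 + (y - poly$py[i])^2 <= b^2 + 1e-9)
    inside
  }
}

poly_bbox <- function(poly) {
  b <- poly$buffer
  c(min(poly$px) - b, max(poly$px) + b, min(poly$py) - b, max(poly$py) + b)
}

bbox_overlap <- function(a, b) {
  a[1] <= b[2] && b[1] <= a[2] && a[3] <= b[4] && b[3] <= a[4]
}

# Union area of all polygons clipped to the window. Analytic when polygons
# are pairwise disjoint (by bounding box) and inside the window; otherwise
# deterministic midpoint-grid quadrature over the affected bounding boxes.
union_area <- function(polys, window, grid_n = 1500) {
  if (!length(polys)) return(0)
  areas <- vapply(polys, domain_poly_area, numeric(1))
  bb <- lapply(polys, poly_bbox)
  wbb <- c(window[["xmin"]], window[["xmax"]],
           window[["ymin"]], window[["ymax"]])
  clipped <- vapply(bb, function(b)
    b[1] < wbb[1] || b[2] > wbb[2] || b[3] < wbb[3] || b[4] > wbb[4],
    logical(1))
  overlap <- rep(FALSE, length(polys))
  if (length(polys) > 1) {
    for (i in seq_len(length(polys) - 1))
      for (j in (i + 1):length(polys))
        if (bbox_overlap(bb[[i]], bb[[j]]))
          overlap[i] <- overlap[j] <- TRUE
  }
  redo <- clipped | overlap
  total <- sum(areas[!redo])
  if (any(redo)) {
    sub <- polys[redo]
    sbb <- bb[redo]
    x0 <- max(min(vapply(sbb, `[`, numeric(1), 1)), wbb[1])
    x1 <- min(max(vapply(sbb, `[`, numeric(1), 2)), wbb[2])
    y0 <- max(min(vapply(sbb, `[`, numeric(1), 3)), wbb[3])
    y1 <- min(max(vapply(sbb, `[`, numeric(1), 4)), wbb[4])
    res <- max((x1 - x0), (y1 - y0)) / grid_n
    gx <- seq(x0 + res / 2, x1, by = res)
    gy <- seq(y0 + res / 2, y1, by = res)
    covered <- matrix(FALSE, length(gx), length(gy))
    for (p in sub) {
      pb <- poly_bbox(p)
      ix <- which(gx >= pb[1] & gx <= pb[2])
      iy <- which(gy >= pb[3] & gy <= pb[4])
      if (!length(ix) || !length(iy)) next
      gg <- expand.grid(x = gx[ix], y = gy[iy])
      hit <- points_in_poly(p, gg$x, gg$y)
      covered[ix, iy] <- covered[ix, iy] | matrix(hit, length(ix))
    }
    total <- total + sum(covered) * res^2
  }
  min(total, window_area(window))
}

#' Build domain polygons and areas
#'
#' Promotes each cluster of at least `min_cluster_size` molecules to a
#' polygonal domain: clusters with >= 3 non-collinear members become their
#' convex hull dilated by `buffer`; degenerate (collinear or 2-point)
#' clusters become the union of discs of radius `buffer` around the
#' members. Per-domain areas are analytic (hull area + perimeter * buffer +
#' pi * buffer^2 for dilated hulls); the total domain area is the union
#' clipped to the window, computed by deterministic grid quadrature when
#' domains overlap or cross the window boundary.
#'
#' @param domains a `"domain_set"` from [find_domains()].
#' @param params optional [domain_params()] override (defaults to the
#'   parameters used for clustering).
#' @return The `"domain_set"` with `polygons`, per-domain `areas` and
#'   `total_domain_area` (nm^2) populated.
#' @export
domain_polygons <- function(domains, params = NULL) {
  stopifnot(inherits(domains, "domain_set"))
  if (is.null(params)) params <- domains$params
  pat <- domains$pattern
  keep <- which(domains$sizes >= params$min_cluster_size)
  polys <- list()
  for (cl in keep) {
    idx <- which(domains$membership == cl)
    px <- pat$x[idx]; py <- pat$y[idx]
    hull <- NULL
    if (length(idx) >= 3) {
      h <- grDevices::chull(px, py)
      if (length(h) >= 3 && shoelace_area(px[h], py[h]) > 1e-9)
        hull <- h
    }
    polys[[length(polys) + 1L]] <-
      if (!is.null(hull))
        list(type = "hull", px = px[hull], py = py[hull],
             buffer = params$buffer, cluster = cl)
      else
        list(type = "discs", px = px, py = py,
             buffer = params$buffer, cluster = cl)
  }
  domains$polygons <- polys
  domains$areas <- vapply(polys, domain_poly_area, numeric(1))
  domains$total_domain_area <- union_area(polys, pat$window)
  domains$params <- params
  domains
}

#' Inside/outside density enrichment of a second species
#'
#' Assigns each molecule of the second species to the domain polygons of
#' the first (points exactly on a boundary count as inside) and reports the
#' densities inside and outside the domains, their fold ratio, the fraction
#' of second-species molecules inside, and the window area fraction covered
#' by domains.
#'
#' @param domains a `"domain_set"` with polygons populated.
#' @param other a [point_pattern()] of the second species on the same
#'   window.
#' @return A list of class `"enrichment_report"` with `density_in`,
#'   `density_out` (molecules/um^2), `fold`, `fraction_in`, `area_fraction`
#'   and counts.
#' @export
inout_density <- function(domains, other) {
  stopifnot(inherits(domains, "domain_set"))
  if (is.null(domains$polygons))
    stop("polygons not populated; call domain_polygons() first")
  if (!same_window(domains$pattern, other))
    stop("patterns must share one observation window")
  n <- npoints(other)
  inside <- rep(FALSE, n)
  for (p in domains$polygons) {
    bb <- poly_bbox(p)
    cand <- which(!inside & other$x >= bb[1] & other$x <= bb[2] &
                  other$y >= bb[3] & other$y <= bb[4])
    if (length(cand))
      inside[cand] <- points_in_poly(p, other$x[cand], other$y[cand])
  }
  a_in <- domains$total_domain_area
  a_out <- window_area(other$window) - a_in
  n_in <- sum(inside)
  density_in <- if (a_in > 0) n_in / a_in * 1e6 else NA_real_
  density_out <- if (a_out > 0) (n - n_in) / a_out * 1e6 else NA_real_
  if (a_in <= 0) warning("zero domain area: density_in undefined")
  structure(list(density_in = density_in, density_out = density_out,
                 fold = density_in / density_out,
                 fraction_in = if (n > 0) n_in / n else NA_real_,
                 area_fraction = a_in / window_area(other$window),
                 n_in = n_in, n_out = n - n_in,
                 d_th = domains$params$d_th),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("Enrichment (d_th = %g nm): %.4g in vs %.4g out molecules/um^2 (%.2f-fold)\n",
              x$d_th, x$density_in, x$density_out, x$fold))
  cat(sprintf("  %.1f%% of molecules inside domains covering %.2f%% of the window\n",
              100 * x$fraction_in, 100 * x$area_fraction))
  invisible(x)
}

#' Sensitivity of domain enrichment to the link threshold
#'
#' Reruns domain detection, polygon construction (buffer = d_th / 2 by
#' default) and inside/outside enrichment at each link threshold, the
#' standard robustness check at 60/80/100 nm.
#'
#' @param pattern domain-forming species, a [point_pattern()].
#' @param other second species, a [point_pattern()] on the same window.
#' @param d_th_values link thresholds in nm.
#' @param min_cluster_size passed to [domain_params()].
#' @param buffer_rule function mapping d_th to the polygon buffer
#'   (default `d_th / 2`).
#' @return A list of `"enrichment_report"`s, one per threshold.
#' @export
sensitivity_sweep <- function(pattern, other, d_th_values = c(60, 80, 100),
                              min_cluster_size = 3,
                              buffer_rule = function(d) d / 2) {
  if (!length(d_th_values)) stop("at least one threshold is required")
  lapply(d_th_values, function(d) {
    ds <- find_domains(pattern, domain_params(d, min_cluster_size,
                                              buffer_rule(d)))
    inout_density(domain_polygons(ds), other)
  })
}
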