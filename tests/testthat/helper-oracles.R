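# Independent brute-force oracles (explicit double loops, no shared code
# with the package internals) plus small fixture builders.

oracle_pcf <- function(pattern, edges, mode = c("periodic", "none")) {
  mode <- match.arg(mode)
  w <- pattern$window
  wx <- w[["xmax"]] - w[["xmin"]]; wy <- w[["ymax"]] - w[["ymin"]]
  n <- length(pattern$x)
  K <- length(edges) - 1
  counts <- numeric(K)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dx <- abs(pattern$x[i] - pattern$x[j])
    dy <- abs(pattern$y[i] - pattern$y[j])
    if (mode == "periodic") { dx <- min(dx, wx - dx); dy <- min(dy, wy - dy) }
    d <- sqrt(dx^2 + dy^2)
    for (k in seq_len(K)) {
      if (d > edges[k] && d <= edges[k + 1]) counts[k] <- counts[k] + 1
    }
  }
  expected <- n * (n - 1) * pi * (edges[-1]^2 - edges[-(K + 1)]^2) / (wx * wy)
  counts / expected
}

oracle_bpcf <- function(a, b, edges, mode = c("periodic", "none")) {
  mode <- match.arg(mode)
  w <- a$window
  wx <- w[["xmax"]] - w[["xmin"]]; wy <- w[["ymax"]] - w[["ymin"]]
  K <- length(edges) - 1
  counts <- numeric(K)
  for (i in seq_along(a$x)) for (j in seq_along(b$x)) {
    dx <- abs(a$x[i] - b$x[j]); dy <- abs(a$y[i] - b$y[j])
    if (mode == "periodic") { dx <- min(dx, wx - dx); dy <- min(dy, wy - dy) }
    d <- sqrt(dx^2 + dy^2)
    for (k in seq_len(K)) {
      if (d > edges[k] && d <= edges[k + 1]) counts[k] <- counts[k] + 1
    }
  }
  expected <- length(a$x) * length(b$x) *
    pi * (edges[-1]^2 - edges[-(K + 1)]^2) / (wx * wy)
  counts / expected
}

# Connected components of the <= d_th link graph via naive union-find.
oracle_components <- function(x, y, d_th) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= d_th)
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Canonical form of a partition (label by first occurrence) for comparison.
canon_partition <- function(m) match(m, unique(m))

points_in_poly_test <- function(...) ncdyn:::points_in_poly(...)

make_pp <- function(x, y, w = owin_rect(0, 1000, 0, 1000)) {
  point_pattern(x, y, window = w)
}

write_ts_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
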