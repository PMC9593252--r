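#' ThunderSTORM-style CSV dialect
#'
#' Column-name map (and unit scale) for reading localization tables. The
#' default matches ThunderSTORM's export headers; any remap is allowed, e.g.
#' for tables exported in microns set `scale = 1000`.
#'
#' @param frame,x,y,uncertainty,intensity,channel column names in the file.
#'   `uncertainty`, `intensity` and `channel` are optional (set to `NULL` to
#'   skip).
#' @param scale multiplier applied to x/y (and uncertainty) to convert the
#'   file's units to nm.
#' @return A list of class `"csv_dialect"`.
#' @export
csv_dialect <- function(frame = "frame", x = "x [nm]", y = "y [nm]",
                        uncertainty = "uncertainty [nm]",
                        intensity = NULL, channel = NULL, scale = 1) {
  structure(list(frame = frame, x = x, y = y, uncertainty = uncertainty,
                 intensity = intensity, channel = channel, scale = scale),
            class = "csv_dialect")
}

#' Localization table
#'
#' Per-peak localization records (camera frame, position, uncertainty) plus
#' acquisition metadata, as produced by SMLM peak-fitting software before or
#' after photoblinking grouping.
#'
#' @param records a data.frame with columns `frame`, `x`, `y` and optionally
#'   `uncertainty`, `intensity`, `channel` (x, y, uncertainty in nm).
#' @param window observation window in nm; inferred from the data extent
#'   when `NULL`.
#' @param fps acquisition rate, camera frames per second.
#' @param n_frames total camera frames in the acquisition.
#' @return An object of class `"localization_table"`.
#' @export
localization_table <- function(records, window = NULL, fps = NA_real_,
                               n_frames = NA_integer_) {
  stopifnot(is.data.frame(records))
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("localization records lack mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(records) && any(records$frame < 1))
    stop("camera frame indices must be >= 1")
  if (is.null(window)) {
    window <- if (nrow(records))
      owin_rect(min(records$x), max(records$x) + 1e-9,
                min(records$y), max(records$y) + 1e-9)
    else owin_rect(0, 1, 0, 1)
  } else window <- as_window(window)
  if (is.na(n_frames) && nrow(records)) n_frames <- max(records$frame)
  structure(list(records = records, window = window, fps = fps,
                 n_frames = as.integer(n_frames)),
            class = "localization_table")
}

#' @export
print.localization_table <- function(x, ...) {
  cat("Localization table:", nrow(x$records), "records,",
      x$n_frames, "camera frames")
  if (!is.na(x$fps)) cat(" at", x$fps, "fps")
  cat("\n")
  w <- x$window
  cat(sprintf("  window: [%g, %g] x [%g, %g] nm\n",
              w[["xmin"]], w[["xmax"]], w[["ymin"]], w[["ymax"]]))
  invisible(x)
}

#' Read a localization table from CSV
#'
#' Reads a ThunderSTORM-style comma-separated export (header row, nm units
#' by default). Column names and unit scale are configurable through
#' [csv_dialect()].
#'
#' @param path path to the CSV file.
#' @param dialect a [csv_dialect()] mapping file columns to fields.
#' @param window observation window in nm (inferred from data when `NULL`).
#' @param fps,n_frames acquisition metadata (optional).
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, dialect = csv_dialect(), window = NULL,
                               fps = NA_real_, n_frames = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(frame = dialect$frame, x = dialect$x, y = dialect$y)
  miss <- need[!need %in% names(raw)]
  if (length(miss))
    stop("format error: missing column(s) ",
         paste(sprintf("'%s'", miss), collapse = ", "), " in ", path)
  num_col <- function(cn, what, scale = 1) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad))
        stop(sprintf("parse error: non-numeric %s ('%s') at row %d",
                     what, v[bad[1]], bad[1]))
      v <- v2
    }
    v * scale
  }
  rec <- data.frame(
    frame = as.integer(num_col(dialect$frame, "frame index")),
    x = num_col(dialect$x, "x coordinate", dialect$scale),
    y = num_col(dialect$y, "y coordinate", dialect$scale))
  if (!is.null(dialect$uncertainty) && dialect$uncertainty %in% names(raw))
    rec$uncertainty <- num_col(dialect$uncertainty, "uncertainty",
                               dialect$scale)
  if (!is.null(dialect$intensity) && dialect$intensity %in% names(raw))
    rec$intensity <- num_col(dialect$intensity, "intensity")
  if (!is.null(dialect$channel) && dialect$channel %in% names(raw))
    rec$channel <- as.character(raw[[dialect$channel]])
  localization_table(rec, window = window, fps = fps, n_frames = n_frames)
}

#' Write a localization table to CSV
#'
#' Writes the ThunderSTORM-style dialect back out (same headers as the
#' default [csv_dialect()]); extra columns in the records are preserved.
#'
#' @param table a [localization_table()].
#' @param path output file path.
#' @export
write_localizations <- function(table, path) {
  out <- table$records
  names(out)[names(out) == "x"] <- "x [nm]"
  names(out)[names(out) == "y"] <- "y [nm]"
  names(out)[names(out) == "uncertainty"] <- "uncertainty [nm]"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Photoblinking grouping parameters
#'
#' Spatiotemporal thresholds for merging repeated appearances of one
#' blinking fluorophore into a single molecule: a maximum number of dark
#' ("off") frames allowed between appearances and a maximum link distance.
#' The appropriate values are fluorophore-specific and should be calibrated
#' against blinking statistics; the shipped defaults (3 off frames, 50 nm)
#' are a configuration choice, not a measurement.
#'
#' @param max_off_frames maximum tolerated dark gap between linked
#'   appearances, in camera frames (>= 0).
#' @param max_distance maximum link distance in nm (>= 0).
#' @return A list of class `"grouping_params"`.
#' @export
grouping_params <- function(max_off_frames = 3, max_distance = 50) {
  if (!is.finite(max_off_frames) || max_off_frames < 0 ||
      !is.finite(max_distance) || max_distance < 0)
    stop("grouping parameters must be finite and non-negative")
  structure(list(max_off_frames = as.integer(max_off_frames),
                 max_distance = max_distance),
            class = "grouping_params")
}

#' Correct photoblinking over-counting by spatiotemporal grouping
#'
#' Merges localization records that belong to one blinking molecule.
#' Records are linked when their spatial distance is at most `max_distance`
#' and their frame gap at most `max_off_frames + 1`; grouping is the
#' transitive (single-linkage) closure of these links, so it is invariant to
#' record order. Each group is collapsed to one record at the mean member
#' position, carrying the first member frame.
#'
#' @param table a [localization_table()].
#' @param params a [grouping_params()].
#' @return A [localization_table()] with one record per grouped molecule
#'   appearance; a `group_size` column counts merged members.
#' @export
group_localizations <- function(table, params = grouping_params()) {
  stopifnot(inherits(table, "localization_table"))
  rec <- table$records
  n <- nrow(rec)
  if (n == 0L) stop("localization table is empty")
  ord <- order(rec$frame)
  fr <- rec$frame[ord]; x <- rec$x[ord]; y <- rec$y[ord]
  max_gap <- params$max_off_frames + 1L
  d2max <- params$max_distance^2
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  lo <- 1L
  for (i in seq_len(n)) {
    while (fr[i] - fr[lo] > max_gap) lo <- lo + 1L
    if (lo < i) {
      js <- lo:(i - 1L)
      hit <- js[(x[js] - x[i])^2 + (y[js] - y[i])^2 <= d2max]
      for (j in hit) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  grp <- match(root, unique(root))
  agg <- function(v, f) as.vector(tapply(v, grp, f))
  out <- data.frame(frame = as.integer(agg(fr, min)),
                    x = agg(x, mean), y = agg(y, mean))
  if (!is.null(rec$uncertainty))
    out$uncertainty <- agg(rec$uncertainty[ord], mean)
  if (!is.null(rec$channel))
    out$channel <- as.vector(tapply(rec$channel[ord], grp,
                                    function(v) v[1]))
  out$group_size <- as.integer(agg(rep(1L, n), sum))
  out <- out[order(out$frame, out$x), , drop = FALSE]
  rownames(out) <- NULL
  localization_table(out, window = table$window, fps = table$fps,
                     n_frames = table$n_frames)
}

#' Slice an acquisition into fixed-duration point-pattern windows
#'
#' Splits the camera frames into consecutive non-overlapping blocks of
#' `frames_per_window` frames and returns each block as a point pattern,
#' e.g. 250 camera frames at 50 fps give one reconstructed SMLM frame every
#' 5 s. A trailing partial block is dropped.
#'
#' @param table a [localization_table()] with `fps` set.
#' @param frames_per_window camera frames per reconstructed window (>= 1).
#' @return A list of [point_pattern()]s with `t_start`/`t_end` in seconds.
#' @export
window_by_frames <- function(table, frames_per_window) {
  stopifnot(inherits(table, "localization_table"))
  if (frames_per_window < 1) stop("frames_per_window must be >= 1")
  if (is.na(table$fps)) stop("acquisition fps is undefined")
  n_win <- table$n_frames %/% frames_per_window
  if (n_win < 1) stop("acquisition shorter than one window")
  rec <- table$records
  blk <- (rec$frame - 1L) %/% frames_per_window + 1L
  lapply(seq_len(n_win), function(k) {
    keep <- blk == k
    point_pattern(rec$x[keep], rec$y[keep], window = table$window,
                  t_start = (k - 1) * frames_per_window / table$fps,
                  t_end = k * frames_per_window / table$fps)
  })
}

#' Convert a localization table to a point pattern
#'
#' @param table a [localization_table()].
#' @param channel optional channel label to select (requires a `channel`
#'   column).
#' @return A [point_pattern()].
#' @export
as_point_pattern <- function(table, channel = NULL) {
  rec <- table$records
  if (!is.null(channel)) {
    if (is.null(rec$channel)) stop("table has no channel column")
    rec <- rec[rec$channel == channel, , drop = FALSE]
  }
  point_pattern(rec$x, rec$y, window = table$window, label = channel)
}
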