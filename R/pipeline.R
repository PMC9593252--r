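#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with every
#' default filled in. User configurations (R lists or YAML files) only
#' need to state the fields they change; the run manifest records which
#' defaults were filled.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    input = list(a = NULL, b = NULL, dialect = list(scale = 1)),
    window = NULL,                 # c(xmin, xmax, ymin, ymax) nm
    fps = 50, n_frames = NA,
    grouping = list(enabled = TRUE, max_off_frames = 3, max_distance = 50),
    bins = list(from = 0, to = 1000, width = 10),
    edge_correction = "translation",
    n_sims = 19,
    cbc = list(enabled = TRUE, r_min = 20, r_max = 1000, n_rings = 50,
               n_rand = 19, use_nn_weighting = TRUE),
    domains = list(enabled = TRUE, d_th = 80, min_cluster_size = 3,
                   buffer = 40),
    dynamics = list(enabled = FALSE, frames_per_window = 250, rois = NULL),
    seed = 1,
    out_dir = "ncd_out")
}

merge_config <- function(user, defaults = default_config(), path = "") {
  filled <- character(0)
  merged <- defaults
  for (nm in names(defaults)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (is.null(user[[nm]])) {
      filled <- c(filled, key)
    } else if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      sub <- merge_config(user[[nm]], defaults[[nm]], key)
      merged[[nm]] <- sub$config
      filled <- c(filled, sub$filled)
    } else {
      merged[[nm]] <- user[[nm]]
    }
  }
  extra <- setdiff(names(user), names(defaults))
  for (nm in extra) merged[[nm]] <- user[[nm]]
  list(config = merged, filled = filled)
}

#' Run the full nanocluster analysis pipeline
#'
#' Configuration-driven orchestration: read localization tables, correct
#' photoblinking, compute univariate/bivariate pair-correlation curves with
#' the random-labeling envelope and EOM, coordinate-based colocalization,
#' domain enrichment, and (optionally) windowed trajectories with the
#' 3-state model. Writes per-stage CSV/JSON outputs plus a run manifest
#' (configuration with filled defaults flagged, seed, package version,
#' config hash) into the output directory. All stochastic stages draw
#' their seeds deterministically from the root seed, so a rerun of the
#' same configuration reproduces every output byte for byte.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   to a YAML file holding one. `input$a` is required; stages needing the
#'   second channel are skipped with a notice when `input$b` is absent.
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mc <- merge_config(config)
  cfg <- mc$config
  if (is.null(cfg$input$a)) stop("config must name input$a")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  notice <- function(...) message("[ncd] ", sprintf(...))
  stage_seed <- function(k) as.integer(cfg$seed) + 1000L * k

  dia <- do.call(csv_dialect, cfg$input$dialect[names(cfg$input$dialect) %in%
    names(formals(csv_dialect))])
  win <- if (is.null(cfg$window)) NULL else as_window(unlist(cfg$window))
  read_ch <- function(path) {
    t <- read_localizations(path, dia, window = win, fps = cfg$fps,
                            n_frames = cfg$n_frames)
    if (isTRUE(cfg$grouping$enabled))
      t <- group_localizations(t, grouping_params(cfg$grouping$max_off_frames,
                                                  cfg$grouping$max_distance))
    t
  }
  tab_a <- read_ch(cfg$input$a)
  has_b <- !is.null(cfg$input$b)
  tab_b <- if (has_b) read_ch(cfg$input$b) else NULL
  if (has_b && !is.null(win)) tab_b$window <- tab_a$window
  pa <- as_point_pattern(tab_a)
  pb <- if (has_b) point_pattern(tab_b$records$x, tab_b$records$y,
                                 window = tab_a$window) else NULL

  bins <- radial_bins(cfg$bins$from, cfg$bins$to, cfg$bins$width)
  ec <- cfg$edge_correction
  g11 <- pcf(pa, bins, ec)
  curves <- data.frame(r_center = bins$centers, g11 = g11$g)
  env <- eomc <- NULL
  if (has_b) {
    curves$g22 <- pcf(pb, bins, ec)$g
    g12 <- bpcf(pa, pb, bins, ec)
    env <- rl_envelope(pa, pb, bins, n_sims = cfg$n_sims,
                       seed = stage_seed(1), edge_correction = ec)
    eomc <- eom(g12, env)
    curves$g12 <- g12$g
    curves$rl_lo <- env$lo; curves$rl_hi <- env$hi
    curves$rl_mean <- env$mean_sim
    curves$eom <- eomc$eom
  } else {
    notice("channel B absent: bivariate stages (BPCF/EOM/CBC) skipped")
  }
  f <- file.path(cfg$out_dir, "curves.csv")
  write.csv(curves, f, row.names = FALSE); outputs <- c(outputs, f)
  if (has_b) {
    f <- file.path(cfg$out_dir, "eom.csv")
    write.csv(data.frame(r_center = bins$centers, eom = eomc$eom),
              f, row.names = FALSE); outputs <- c(outputs, f)
  }

  cbc_res <- NULL
  if (has_b && isTRUE(cfg$cbc$enabled)) {
    pars <- cbc_params(seq(cfg$cbc$r_min, cfg$cbc$r_max,
                           length.out = cfg$cbc$n_rings),
                       cfg$cbc$use_nn_weighting)
    cbc_res <- cbc_values(pa, pb, pars)
    f <- file.path(cfg$out_dir, "cbc.csv")
    write.csv(data.frame(x = cbc_res$x, y = cbc_res$y,
                         cbc_value = cbc_res$values),
              f, row.names = FALSE); outputs <- c(outputs, f)
  }

  enr <- NULL
  if (isTRUE(cfg$domains$enabled) && has_b) {
    ds <- domain_polygons(find_domains(pa,
            domain_params(cfg$domains$d_th, cfg$domains$min_cluster_size,
                          cfg$domains$buffer)))
    enr <- inout_density(ds, pb)
    f <- file.path(cfg$out_dir, "domains.json")
    jsonlite::write_json(list(
      d_th = enr$d_th, density_in = enr$density_in,
      density_out = enr$density_out, fold = enr$fold,
      fraction_in = enr$fraction_in, area_fraction = enr$area_fraction,
      n_domains = length(ds$polygons),
      size_classes = as.list(ds$size_classes)),
      f, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)
  } else if (isTRUE(cfg$domains$enabled)) {
    notice("channel B absent: domain enrichment skipped")
  }

  traj <- states <- NULL
  if (isTRUE(cfg$dynamics$enabled) && has_b) {
    wa <- window_by_frames(tab_a, cfg$dynamics$frames_per_window)
    wb <- window_by_frames(tab_b, cfg$dynamics$frames_per_window)
    rois <- cfg$dynamics$rois
    traj <- list()
    for (i in seq_along(rois)) {
      r <- as_window(unlist(rois[[i]]))
      traj[[i]] <- extract_trajectory(wa, wb, r, seed = stage_seed(10 + i))
    }
    tall <- do.call(rbind, lapply(seq_along(traj), function(i)
      cbind(roi = i, as.data.frame(traj[[i]]))))
    f <- file.path(cfg$out_dir, "traj.csv")
    write.csv(tall, f, row.names = FALSE); outputs <- c(outputs, f)
    feats <- rbind(
      setNames(tall[, c("density_a", "g_a")], c("density", "g")),
      setNames(tall[, c("density_b", "g_b")], c("density", "g")))
    feats <- feats[stats::complete.cases(feats), ]
    if (nrow(feats) >= 30) {
      sm <- fit_state_model(feats, seed = stage_seed(2))
      seqs <- lapply(traj, function(tr)
        predict(sm, setNames(tr[, c("density_a", "g_a")],
                             c("density", "g"))))
      P <- transition_matrix(seqs)
      states <- list(model_means = sm$means, transition = P)
      f <- file.path(cfg$out_dir, "states.json")
      jsonlite::write_json(list(
        state_means = as.data.frame(sm$means),
        transition_row_major = as.vector(t(P)),
        state_labels = rownames(P),
        stationary = as.vector(attr(P, "stationary"))),
        f, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, f)
    } else notice("too few complete feature observations for a state model")
  }

  cfg_file <- file.path(cfg$out_dir, "config_resolved.yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(
    package = "ncdyn",
    version = as.character(utils::packageVersion("ncdyn")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    defaults_filled = mc$filled,
    outputs = basename(outputs))
  f <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, f)
  invisible(list(config = cfg, curves = curves, envelope = env,
                 eom = eomc, cbc = cbc_res, enrichment = enr,
                 trajectories = traj, states = states,
                 outputs = outputs))
}
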