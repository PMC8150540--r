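#' Experiment configuration
#'
#' A fully serializable description of one monitoring experiment. The
#' defaults reproduce the reference setup: 8 antennas 23 mm apart, five
#' frequencies 600-1400 MHz, a 41 x 35 x 35 node ROI at 3 mm, the
#' nested-ellipsoid phantom 35 mm in front of the array, 45 dB SNR, and
#' truncation-index selection by the slope-change-above-noise rule with
#' a -15 dB differential noise level.
#'
#' @param seed Master seed; every random substream in [run_experiment()]
#'   is derived from it.
#' @param frequencies_hz Acquisition frequencies, Hz.
#' @param reference_frequency_hz Band-reference frequency at which
#'   ground-truth contrasts are evaluated.
#' @param array,grid,phantom,noise,forward,inversion,analysis,output
#'   Named lists overriding individual defaults (see the config fields in
#'   the returned object).
#' @param materials Named list of material overrides (see
#'   [material_library()]).
#' @param scenarios Scenario labels to simulate.
#' @param cache_dir Optional directory for the SVD cache.
#' @return An object of class `experiment_config` (a named list).
#' @export
experiment_config <- function(seed = 1,
                              frequencies_hz = c(600e6, 800e6, 1000e6,
                                                 1200e6, 1400e6),
                              reference_frequency_hz = 1e9,
                              array = list(), grid = list(),
                              phantom = list(), noise = list(),
                              forward = list(), inversion = list(),
                              analysis = list(), output = list(),
                              materials = NULL,
                              scenarios = SCENARIO_LABELS,
                              cache_dir = NULL) {
  merge_d <- function(defaults, user) utils::modifyList(defaults, user)
  cfg <- list(
    seed = as.integer(seed),
    frequencies_hz = frequencies_hz,
    reference_frequency_hz = reference_frequency_hz,
    array = merge_d(list(n_antennas = 8, spacing_mm = 23,
                         polarization = c(1, 0, 0)), array),
    grid = merge_d(list(extent_mm = c(120, 102, 102), spacing_mm = 3,
                        origin_mm = NULL), grid),
    phantom = merge_d(list(outer_semi_axes_mm = c(30, 20, 20),
                           inner_semi_axes_mm = c(17, 6.5, 6.5),
                           center_mm = c(0, 0, 55),
                           shell_thickness_mm = 1.5), phantom),
    noise = merge_d(list(snr_db = 45), noise),
    forward = merge_d(list(refinement = 2, node_cap = 2e6), forward),
    inversion = merge_d(list(nu = NULL,
                             selection = "slope_change_above_noise",
                             differential_noise_db = -15,
                             window = 5, prominence_db = 0.5), inversion),
    analysis = merge_d(list(threshold = 0.5,
                            crop_mm = list(x = c(-60, 60), y = c(-51, 51),
                                           z = c(17, 104))), analysis),
    output = merge_d(list(dir = NULL), output),
    materials = materials,
    scenarios = vapply(scenarios, scenario_id, ""),
    cache_dir = cache_dir)
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @param x A list (e.g. parsed from YAML) or `experiment_config`.
#' @export
as_experiment_config <- function(x) {
  if (inherits(x, "experiment_config")) return(x)
  stopifnot(is.list(x))
  args <- x[intersect(names(x), names(formals(experiment_config)))]
  for (nm in c("frequencies_hz", "scenarios"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  for (nm in intersect(names(args),
                       c("array", "grid", "phantom", "noise", "forward",
                         "inversion", "analysis", "output")))
    args[[nm]] <- lapply(args[[nm]], function(v)
      if (is.list(v) && !is.list(v[[1]])) v else v)
  cfg <- do.call(experiment_config, args)
  cfg
}

#' Read / write experiment configurations as YAML
#'
#' @param path YAML (or JSON) file path.
#' @return `load_config()`: an `experiment_config`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  norm_num <- function(x) {
    if (is.list(x) && !is.null(names(x))) lapply(x, norm_num)
    else if (is.list(x)) unlist(x)
    else x
  }
  as_experiment_config(lapply(raw, norm_num))
}

#' @rdname load_config
#' @param config An `experiment_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_materials <- function(cfg) material_library(cfg$materials)

config_grid <- function(cfg) {
  g <- cfg$grid
  if (is.null(g$origin_mm))
    roi_grid(g$extent_mm, g$spacing_mm)
  else roi_grid(g$extent_mm, g$spacing_mm, g$origin_mm)
}

config_array <- function(cfg, materials) {
  array_geometry(cfg$array$n_antennas, cfg$array$spacing_mm,
                 cfg$array$polarization,
                 background = materials$coupling_medium,
                 check_spacing = !isFALSE(cfg$array$check_spacing))
}

config_phantom <- function(cfg) {
  p <- cfg$phantom
  phantom_spec(p$outer_semi_axes_mm, p$inner_semi_axes_mm, p$center_mm,
               p$shell_thickness_mm)
}

## Deterministic substream seed derivation (kept below 2^31).
derive_seed <- function(seed, index)
  as.integer((as.double(seed) * 1009 + index * 101) %% 2147483647)

#' Crop a contrast image to an analysis window
#'
#' Restricts an image to the given coordinate ranges (mm). By default
#' the display/analysis window excludes the first voxel layers next to
#' the antennas, where the reconstruction carries array artifacts.
#'
#' @param image A [contrast_image()].
#' @param crop Named list with `x`, `y`, `z` ranges (mm); ranges outside
#'   the ROI are clamped with a warning.
#' @return A [contrast_image()] on the cropped sub-grid.
#' @export
crop_image <- function(image,
                       crop = list(x = c(-60, 60), y = c(-51, 51),
                                   z = c(17, 104))) {
  grid <- image$grid
  keep <- list()
  for (d in 1:3) {
    ax <- list(grid$x, grid$y, grid$z)[[d]]
    rng <- crop[[c("x", "y", "z")[d]]]
    if (rng[1] < min(ax) - 1e-9 || rng[2] > max(ax) + 1e-9)
      warning("crop range clamped to the ROI on axis ",
              c("x", "y", "z")[d], call. = FALSE)
    keep[[d]] <- which(ax >= rng[1] - 1e-9 & ax <= rng[2] + 1e-9)
    if (!length(keep[[d]]))
      stop_mw("config error: crop leaves no nodes on axis ",
              c("x", "y", "z")[d])
  }
  vol <- array(image$values, dim = grid$shape)[keep[[1]], keep[[2]],
                                               keep[[3]], drop = FALSE]
  sub <- roi_grid(extent = grid$spacing * (dim(vol) - 1),
                  spacing = grid$spacing,
                  origin = c(grid$x[keep[[1]][1]], grid$y[keep[[2]][1]],
                             grid$z[keep[[3]][1]]))
  contrast_image(as.vector(vol), sub, image$frequency)
}

#' Run the full monitoring experiment
#'
#' Orchestrates the whole chain of the in-silico study: incident dipole
#' fields and kernel on the imaging grid, singular value decomposition
#' (cached — it is scenario-independent), truncation-index selection,
#' per-scenario scattered data on the refined forward grid, calibrated
#' noise injection with a common per-frequency noise floor, the
#' differential data sets, TSVD reconstruction of each, ideal
#' reconstructions, NMSE, signal-level tables and localization reports.
#' Deterministic under the config seed.
#'
#' @param config An [experiment_config()] (or coercible list / YAML path).
#' @param verbose Print per-stage progress.
#' @return An object of class `mwi_experiment`: list with `config`,
#'   `grid`, `svd` (singular values and selection only), `nu`,
#'   `candidates`, `pairs` (per-pair list with `data`, `image`, `ideal`,
#'   `nmse`, `localization`), `levels` (per-scenario norms),
#'   `differential_levels` (per pair, dB re the common reference power)
#'   and `nmse_table`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  if (is.character(config)) config <- load_config(config)
  cfg <- as_experiment_config(config)
  say <- function(...) if (verbose) message(...)
  mats <- config_materials(cfg)
  grid <- config_grid(cfg)
  arr <- config_array(cfg, mats)
  phantom <- config_phantom(cfg)
  cm <- mats$coupling_medium

  say("incident fields on ", grid$n_nodes, " nodes")
  fields <- incident_field_set(arr, grid, cm, cfg$frequencies_hz)
  say("kernel ", length(cfg$frequencies_hz) * arr$n_antennas^2, " x ",
      grid$n_nodes)
  kern <- build_kernel(fields, grid, cm)
  rm(fields)
  say("SVD")
  sv <- compute_svd(kern, cache_dir = cfg$cache_dir)
  rm(kern)

  if (is.null(cfg$inversion$nu)) {
    thr <- threshold_candidates(sv$d,
                                noise_db = cfg$inversion$differential_noise_db,
                                window = cfg$inversion$window,
                                prominence_db = cfg$inversion$prominence_db)
    nu <- thr$selected
    candidates <- thr$candidates
  } else {
    nu <- as.integer(cfg$inversion$nu)
    candidates <- integer()
  }
  say("truncation index nu = ", nu)

  ## Per-scenario scattered data on the refined forward grid, relative to
  ## the empty reference (the dipole surrogate carries no crosstalk, so
  ## the s0 acquisition itself is zero-mean noise).
  scen <- cfg$scenarios
  datasets <- list()
  for (sc in scen) {
    v <- if (sc == "s0") {
      z <- complex(length(cfg$frequencies_hz) * arr$n_antennas^2)
      attr(z, "n_antennas") <- arr$n_antennas
      attr(z, "frequencies") <- cfg$frequencies_hz
      z
    } else fine_grid_forward("s0", sc, arr, grid, cm, cfg$frequencies_hz,
                             mats, phantom,
                             refinement = cfg$forward$refinement,
                             reference_frequency = cfg$reference_frequency_hz,
                             node_cap = cfg$forward$node_cap)
    datasets[[sc]] <- scattering_dataset(as_s_matrices(v),
                                         cfg$frequencies_hz, sc)
  }
  nonzero <- setdiff(scen, "s0")
  refpow <- if (length(nonzero)) {
    rowMeans(vapply(nonzero, function(sc)
      apply(datasets[[sc]]$s, 3, function(m) mean(Mod(m)^2)),
      numeric(length(cfg$frequencies_hz))))
  } else NULL
  noisy <- datasets
  if (is.finite(cfg$noise$snr_db) && !is.null(refpow)) {
    for (i in seq_along(scen))
      noisy[[scen[i]]] <- add_noise(
        datasets[[scen[i]]],
        noise_spec(cfg$noise$snr_db, seed = derive_seed(cfg$seed, i)),
        reference_power = refpow)
  }

  pairs <- scenario_pairs(scen)
  results <- list()
  nmse_tab <- data.frame()
  diff_levels <- data.frame()
  for (r in seq_len(nrow(pairs))) {
    pr <- pairs[r, ]
    say("pair ", pr$label)
    res <- tryCatch({
      dS <- differential_data(noisy[[pr$to]], noisy[[pr$from]])
      img <- tsvd_solve(sv, dS, nu)
      gt <- ground_truth_contrast(pr$from, pr$to, grid,
                                  cfg$reference_frequency_hz, mats,
                                  phantom)
      ideal <- ideal_reconstruction(sv, gt, nu)
      err <- nmse(img, ideal)
      loc <- localization_report(crop_image(img, cfg$analysis$crop_mm),
                                 phantom = phantom,
                                 threshold = cfg$analysis$threshold,
                                 target = pr$target)
      lv <- differential_level_db(as_s_matrices(dS),
                                  sqrt(refpow * arr$n_antennas^2))
      list(label = pr$label, data = dS, image = img, ideal = ideal,
           nmse = err, localization = loc, levels_db = lv)
    }, error = function(e) {
      warning("pair ", pr$label, " failed: ", conditionMessage(e),
              call. = FALSE)
      list(label = pr$label, error = conditionMessage(e))
    })
    results[[pr$label]] <- res
    if (is.null(res$error)) {
      nmse_tab <- rbind(nmse_tab,
                        data.frame(pair = pr$label, nmse = res$nmse))
      diff_levels <- rbind(diff_levels, data.frame(
        pair = pr$label, frequency_hz = cfg$frequencies_hz,
        level_db = res$levels_db))
    }
  }

  out <- structure(list(config = cfg, grid = grid,
                        singular_values = sv$d, nu = nu,
                        candidates = candidates,
                        levels = signal_level_table(datasets),
                        differential_levels = diff_levels,
                        nmse_table = nmse_tab, pairs = results,
                        svd = sv),
                   class = "mwi_experiment")
  if (!is.null(cfg$output$dir)) write_experiment(out, cfg$output$dir)
  out
}

#' @export
print.mwi_experiment <- function(x, ...) {
  cat("<mwi_experiment>", length(x$pairs), "differential data sets; nu =",
      x$nu, "\n")
  if (nrow(x$nmse_table)) {
    cat("NMSE vs ideal reconstruction:\n")
    print(x$nmse_table, row.names = FALSE)
  }
  invisible(x)
}

#' Write the report bundle of an experiment
#'
#' Per-pair NIfTI image volumes and CSVs, Touchstone `.s8p` files of the
#' differential data, the singular spectrum, the signal-level and NMSE
#' tables (CSV) and a JSON summary.
#'
#' @param experiment A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  export_spectrum_csv(experiment$svd, file.path(dir, "spectrum.csv"))
  utils::write.csv(experiment$levels, file.path(dir, "signal_levels.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$differential_levels,
                   file.path(dir, "differential_levels.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$nmse_table, file.path(dir, "nmse.csv"),
                   row.names = FALSE)
  for (nm in names(experiment$pairs)) {
    res <- experiment$pairs[[nm]]
    if (!is.null(res$error)) next
    export_image(res$image,
                 nifti = file.path(dir, paste0("image_", nm, ".nii.gz")))
    write_touchstone(
      scattering_dataset(as_s_matrices(res$data),
                         experiment$config$frequencies_hz, nm),
      file.path(dir, paste0("diff_", nm, ".s",
                            experiment$config$array$n_antennas, "p")))
  }
  summary <- list(nu = experiment$nu, candidates = experiment$candidates,
                  nmse = experiment$nmse_table,
                  localization = lapply(experiment$pairs, function(r)
                    r$localization[setdiff(names(r$localization),
                                           c("bbox_mm"))]))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Ready-made experiment fixtures
#'
#' `"tiny"` is a desk/CI-scale bundle — 4 antennas, 2 frequencies, an
#' 11 x 9 x 9 node grid and a spherical two-region phantom — that runs
#' the whole chain in seconds; `"full"` is the complete reference
#' configuration (8 antennas, 5 frequencies, 41 x 35 x 35 nodes).
#'
#' @param scale `"tiny"` or `"full"`.
#' @param seed Master seed for the returned config.
#' @return An [experiment_config()].
#' @export
make_fixture <- function(scale = c("tiny", "full"), seed = 1) {
  scale <- match.arg(scale)
  if (scale == "full") return(experiment_config(seed = seed))
  experiment_config(
    seed = seed,
    frequencies_hz = c(800e6, 1200e6),
    reference_frequency_hz = 1e9,
    array = list(n_antennas = 4, spacing_mm = 16),
    grid = list(extent_mm = c(30, 24, 24), spacing_mm = 3,
                origin_mm = c(-15, -12, 6)),
    phantom = list(outer_semi_axes_mm = c(8, 8, 8),
                   inner_semi_axes_mm = c(4, 4, 4),
                   center_mm = c(0, 0, 18),
                   shell_thickness_mm = 1.5),
    forward = list(refinement = 2, node_cap = 2e6),
    analysis = list(threshold = 0.5,
                    crop_mm = list(x = c(-15, 15), y = c(-12, 12),
                                   z = c(6, 30))))
}

#' Render cross-sections of a contrast image
#'
#' Per-z x-y slices of the normalized magnitude, color scale 0 to 1,
#' optionally overlaid with the phantom contour in the slices it
#' intersects. The default crop drops the voxel layers next to the
#' antennas where array artifacts dominate.
#'
#' @param image A [contrast_image()].
#' @param phantom Optional [phantom_spec()] for contour overlay.
#' @param crop Named list of `x`, `y`, `z` display ranges, mm.
#' @return A ggplot object (facets over z).
#' @export
render_slices <- function(image, phantom = NULL,
                          crop = list(x = c(-60, 60), y = c(-51, 51),
                                      z = c(17, 104))) {
  cropped <- crop_image(image, crop)
  grid <- cropped$grid
  df <- data.frame(x = grid$nodes[, 1], y = grid$nodes[, 2],
                   z = grid$nodes[, 3],
                   I = cropped$normalized_magnitude)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$I)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "I")
  if (!is.null(phantom)) {
    theta <- seq(0, 2 * pi, length.out = 121)
    rings <- do.call(rbind, lapply(grid$z, function(zz) {
      dz <- (zz - phantom$center[3]) / phantom$outer_semi_axes[3]
      if (abs(dz) >= 1) return(NULL)
      sc <- sqrt(1 - dz^2)
      data.frame(z = zz,
                 x = phantom$center[1] +
                   sc * phantom$outer_semi_axes[1] * cos(theta),
                 y = phantom$center[2] +
                   sc * phantom$outer_semi_axes[2] * sin(theta))
    }))
    if (!is.null(rings) && nrow(rings))
      p <- p + ggplot2::geom_path(data = rings,
                                  ggplot2::aes(x = .data$x, y = .data$y),
                                  inherit.aes = FALSE, color = "white",
                                  linewidth = 0.3)
  }
  p
}
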