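#' Build the region-of-interest node grid
#'
#' The ROI is discretized into a lattice of nodes spanning the extent
#' inclusively, so each axis has `extent/spacing + 1` nodes: the default
#' 120 x 102 x 102 mm extent at 3 mm spacing yields the
#' 41 x 35 x 35 = 50,225 node grid. The linear node index runs x-fastest
#' (`n = i + (j-1)*nx + (k-1)*nx*ny`).
#'
#' @param extent Length-3 numeric, physical span per axis in mm; each
#'   component must be a positive multiple of `spacing`.
#' @param spacing Node spacing (cubic voxel side) in mm.
#' @param origin Length-3 numeric, position of node (1,1,1) in mm. The
#'   default places the ROI symmetrically around the array in x and y,
#'   starting one voxel in front of the antenna tips (z origin at the
#'   tips).
#' @return An object of class `roi_grid` with fields `extent`, `spacing`,
#'   `origin`, `shape`, `n_nodes`, per-axis coordinate vectors `x`, `y`,
#'   `z`, `nodes` (n x 3 coordinate matrix, mm) and `voxel_volume` (mm^3).
#' @examples
#' g <- roi_grid()        # 41 x 35 x 35, 50,225 nodes
#' g$shape
#' @export
roi_grid <- function(extent = c(120, 102, 102), spacing = 3,
                     origin = c(-extent[1] / 2, -extent[2] / 2, spacing)) {
  stopifnot(length(extent) == 3, length(origin) == 3, spacing > 0)
  steps <- extent / spacing
  if (any(extent <= 0) || any(abs(steps - round(steps)) > 1e-9))
    stop_mw("config error: extent components must be positive multiples ",
            "of spacing")
  shape <- as.integer(round(steps)) + 1L
  ax <- lapply(1:3, function(d) origin[d] + spacing * (seq_len(shape[d]) - 1))
  nodes <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  structure(list(extent = extent, spacing = spacing, origin = origin,
                 shape = shape, n_nodes = as.integer(prod(shape)),
                 x = ax[[1]], y = ax[[2]], z = ax[[3]],
                 nodes = nodes, voxel_volume = spacing^3),
            class = "roi_grid")
}

#' @export
print.roi_grid <- function(x, ...) {
  cat("<roi_grid>", paste(x$shape, collapse = " x "), "nodes (",
      x$n_nodes, ") at", x$spacing, "mm spacing\n")
  invisible(x)
}

#' Convert between linear node index and (i, j, k) grid subscripts
#'
#' The mapping is bijective with x fastest.
#'
#' @param grid A [roi_grid()].
#' @param n Linear node index (vectorized).
#' @return `grid_ijk()`: an n x 3 integer matrix; `grid_index()`: integer
#'   vector of linear indices.
#' @export
grid_ijk <- function(grid, n) {
  n0 <- as.integer(n) - 1L
  nx <- grid$shape[1]; ny <- grid$shape[2]
  cbind(i = n0 %% nx + 1L,
        j = (n0 %/% nx) %% ny + 1L,
        k = n0 %/% (nx * ny) + 1L)
}

#' @rdname grid_ijk
#' @param ijk n x 3 integer matrix of grid subscripts.
#' @export
grid_index <- function(grid, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  (ijk[, 1] - 1L) + (ijk[, 2] - 1L) * grid$shape[1] +
    (ijk[, 3] - 1L) * grid$shape[1] * grid$shape[2] + 1L
}

#' Linear antenna array geometry
#'
#' Antenna tips are colinear along x at z = 0 (the z origin sits at the
#' tips), uniformly spaced and centered on x = 0, radiating boresight
#' along +z with linear polarization in the array plane. At construction
#' the spacing is checked against the quarter wavelength in the coupling
#' medium at 1 GHz, the sampling bound the array design satisfies.
#'
#' @param n_antennas Number of elements (default 8).
#' @param spacing Inter-element spacing in mm (default 23).
#' @param polarization Unit 3-vector of the dipole polarization.
#' @param background Coupling-medium [dispersive_material()] used for the
#'   spacing check.
#' @param check_spacing Set `FALSE` to skip the lambda/4 check.
#' @return An object of class `array_geometry` with `tip_positions`
#'   (n x 3, mm), `polarization`, `boresight`, `spacing`, `n_antennas`.
#' @export
array_geometry <- function(n_antennas = 8, spacing = 23,
                           polarization = c(1, 0, 0),
                           background = material_library()$coupling_medium,
                           check_spacing = TRUE) {
  stopifnot(n_antennas >= 2, spacing > 0, length(polarization) == 3)
  polarization <- polarization / sqrt(sum(polarization^2))
  if (check_spacing) {
    lam4_mm <- wavelength_in_medium(background, 1e9) / 4 * 1e3
    if (spacing < lam4_mm)
      stop_mw("config error: array spacing ", spacing,
              " mm is below lambda/4 at 1 GHz in the coupling medium (",
              round(lam4_mm, 2), " mm)")
  }
  xs <- (seq_len(n_antennas) - (n_antennas + 1) / 2) * spacing
  tips <- cbind(x = xs, y = 0, z = 0)
  structure(list(n_antennas = as.integer(n_antennas), spacing = spacing,
                 tip_positions = tips, polarization = polarization,
                 boresight = c(0, 0, 1)),
            class = "array_geometry")
}

#' Nested-ellipsoid ablation phantom specification
#'
#' Two concentric ellipsoids mimic the ablated-zone evolution: the outer
#' one (axes 60 x 40 x 40 mm) bounds the treated region, the inner one
#' (34 x 13 x 13 mm) the zone ablated first. The physical phantom is
#' moulded in 1.5 mm ABS shells just outside each ellipsoid surface. The
#' default center places the front face 35 mm from the antenna tips.
#'
#' @param outer_semi_axes Length-3 semi-axes (mm) of the outer ellipsoid.
#' @param inner_semi_axes Length-3 semi-axes (mm) of the inner ellipsoid,
#'   strictly inside the outer one.
#' @param center Common center, mm.
#' @param shell_thickness ABS shell thickness, mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_semi_axes = c(30, 20, 20),
                         inner_semi_axes = c(17, 6.5, 6.5),
                         center = c(0, 0, 55),
                         shell_thickness = 1.5) {
  stopifnot(length(outer_semi_axes) == 3, length(inner_semi_axes) == 3,
            length(center) == 3)
  if (any(inner_semi_axes >= outer_semi_axes))
    stop_mw("config error: inner ellipsoid must lie strictly inside ",
            "the outer one")
  if (any(outer_semi_axes <= 0) || shell_thickness < 0)
    stop_mw("config error: non-positive phantom dimensions")
  structure(list(outer_semi_axes = outer_semi_axes,
                 inner_semi_axes = inner_semi_axes,
                 center = center, shell_thickness = shell_thickness),
            class = "phantom_spec")
}

#' Validate a scenario label
#'
#' Labels: `s0` (empty reference), and stage `a` (pre-treatment: both
#' ellipsoids liver), `b` (ongoing: inner necrosis), `c` (completed:
#' outer necrosis, inner carbonized); suffix 1 = shell-free, 2 = with the
#' ABS shells.
#'
#' @param label Scenario label string.
#' @return The validated label.
#' @export
scenario_id <- function(label) {
  if (!is.character(label) || length(label) != 1 ||
      !(label %in% SCENARIO_LABELS))
    stop_mw("config error: unknown scenario '", paste(label, collapse = ","),
            "'; expected one of ", paste(SCENARIO_LABELS, collapse = ", "))
  label
}

scenario_stage <- function(label) substr(scenario_id(label), 1, 1)
scenario_with_shell <- function(label) substr(scenario_id(label), 2, 2) == "2"

## Normalized ellipsoid radius rho (<= 1 inside) and approximate distance
## to the surface measured along the radial scaling direction.
ellipsoid_rho <- function(nodes, center, semi) {
  d <- sweep(nodes, 2, center)
  sqrt((d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2)
}

ellipsoid_shell_mask <- function(nodes, center, semi, thickness) {
  rho <- ellipsoid_rho(nodes, center, semi)
  r <- sqrt(rowSums(sweep(nodes, 2, center)^2))
  d_surf <- r * (rho - 1) / pmax(rho, .Machine$double.eps)
  rho > 1 & d_surf <= thickness
}

#' Per-node material assignment for a scenario
#'
#' Labels every grid node with one of `background`, `liver`, `necrosis`,
#' `carbonized`, `abs` according to the treatment stage: stage `a` fills
#' both ellipsoids with liver, stage `b` replaces the inner one with
#' coagulation necrosis, stage `c` has a necrotic outer region with a
#' carbonized core. Suffix-2 scenarios add 1.5 mm ABS shells just outside
#' each ellipsoid surface. `s0` is all coupling medium.
#'
#' @param scenario Scenario label (see [scenario_id()]).
#' @param grid A [roi_grid()].
#' @param phantom A [phantom_spec()].
#' @return Character vector of node labels (length `grid$n_nodes`) with
#'   attributes `scenario` and `phantom`. A phantom extending outside the
#'   ROI triggers a warning (it is clipped).
#' @export
material_map <- function(scenario, grid, phantom = phantom_spec()) {
  scenario <- scenario_id(scenario)
  lab <- rep("background", grid$n_nodes)
  if (scenario == "s0")
    return(structure(lab, scenario = scenario, phantom = phantom))
  reach <- phantom$outer_semi_axes +
    if (scenario_with_shell(scenario)) phantom$shell_thickness else 0
  lo <- phantom$center - reach; hi <- phantom$center + reach
  gmin <- grid$origin; gmax <- grid$origin + grid$extent
  if (any(lo < gmin) || any(hi > gmax))
    warning("phantom extends outside the ROI; it is clipped",
            call. = FALSE)
  stage <- scenario_stage(scenario)
  stage_tab <- list(a = c(outer = "liver", inner = "liver"),
                    b = c(outer = "liver", inner = "necrosis"),
                    c = c(outer = "necrosis", inner = "carbonized"))[[stage]]
  rho_out <- ellipsoid_rho(grid$nodes, phantom$center,
                           phantom$outer_semi_axes)
  rho_in <- ellipsoid_rho(grid$nodes, phantom$center,
                          phantom$inner_semi_axes)
  lab[rho_out <= 1] <- stage_tab[["outer"]]
  if (scenario_with_shell(scenario)) {
    lab[ellipsoid_shell_mask(grid$nodes, phantom$center,
                             phantom$outer_semi_axes,
                             phantom$shell_thickness)] <- "abs"
    lab[rho_out <= 1 &
          ellipsoid_shell_mask(grid$nodes, phantom$center,
                               phantom$inner_semi_axes,
                               phantom$shell_thickness)] <- "abs"
  }
  lab[rho_in <= 1] <- stage_tab[["inner"]]
  structure(lab, scenario = scenario, phantom = phantom)
}

MATERIAL_OF_LABEL <- c(background = "coupling_medium", liver = "liver",
                       necrosis = "necrosis", carbonized = "carbonized",
                       abs = "abs")

#' Complex contrast image container
#'
#' Holds the per-node complex contrast `delta_x` (difference of complex
#' equivalent permittivity, F/m) together with its normalized magnitude
#' `I = |delta_x| / max |delta_x|` (all-zero input yields all-zero `I`),
#' the qualitative output of the imaging chain.
#'
#' @param values Complex vector, one entry per ROI node.
#' @param grid The [roi_grid()] the values live on.
#' @param frequency Frequency (Hz) or band label the contrast refers to.
#' @return An object of class `contrast_image` with fields `values`,
#'   `normalized_magnitude`, `grid`, `frequency`.
#' @export
contrast_image <- function(values, grid, frequency = NA) {
  stopifnot(length(values) == grid$n_nodes)
  m <- Mod(values)
  mx <- max(m)
  structure(list(values = values,
                 normalized_magnitude = if (mx > 0) m / mx else m,
                 grid = grid, frequency = frequency),
            class = "contrast_image")
}

#' @export
print.contrast_image <- function(x, ...) {
  cat("<contrast_image>", x$grid$n_nodes, "nodes;",
      sum(x$normalized_magnitude >= 0.5), "nodes >= half max\n")
  invisible(x)
}

#' Ground-truth differential contrast between two scenarios
#'
#' Per node, `delta_x_GT = eps_eq(state `to`) - eps_eq(state `from`)`
#' evaluated at the given frequency, using the scenario material maps.
#' Identical scenarios yield a valid all-zero contrast.
#'
#' @param from,to Scenario labels (the earlier and later acquisition).
#' @param grid A [roi_grid()].
#' @param frequency Evaluation frequency, Hz (a single band-reference
#'   value; the linearized inversion estimates one contrast vector for
#'   the whole band).
#' @param materials Material library, see [material_library()].
#' @param phantom A [phantom_spec()].
#' @return A [contrast_image()].
#' @export
ground_truth_contrast <- function(from, to, grid, frequency = 1e9,
                                  materials = material_library(),
                                  phantom = phantom_spec()) {
  maps <- lapply(c(from, to), material_map, grid = grid, phantom = phantom)
  eps_of <- function(lab) {
    out <- complex(grid$n_nodes)
    for (lv in unique(lab)) {
      mat <- materials[[MATERIAL_OF_LABEL[[lv]]]]
      if (is.null(mat))
        stop_mw("config error: material library lacks '",
                MATERIAL_OF_LABEL[[lv]], "'")
      out[lab == lv] <- evaluate_permittivity(mat, frequency)$eps_complex
    }
    out
  }
  contrast_image(eps_of(maps[[2]]) - eps_of(maps[[1]]), grid, frequency)
}

#' Enumerate the differential data sets of the monitoring study
#'
#' The ten pairs aX-s0, bX-s0, cX-s0, bX-aX, cX-bX (X = 1 without shells,
#' 2 with ABS shells), restricted to the scenarios supplied.
#'
#' @param scenarios Character vector of scenario labels available.
#' @return A data frame with columns `from`, `to`, `label`, `target`
#'   (`outer` or `inner`, the ellipsoid whose extent the pair is meant to
#'   image).
#' @export
scenario_pairs <- function(scenarios = SCENARIO_LABELS) {
  scenarios <- vapply(scenarios, scenario_id, "")
  pairs <- data.frame(
    from = c("s0", "s0", "s0", "s0", "s0", "s0", "a1", "a2", "b1", "b2"),
    to = c("a1", "a2", "b1", "b2", "c1", "c2", "b1", "b2", "c1", "c2"),
    stringsAsFactors = FALSE)
  pairs$label <- paste0(pairs$to, "-", pairs$from)
  pairs$target <- ifelse(substr(pairs$from, 1, 1) == "a", "inner", "outer")
  pairs[pairs$from %in% scenarios & pairs$to %in% scenarios, ,
        drop = FALSE]
}

#' Export a scenario material map
#'
#' Writes the per-node labels as a CSV (`node`, `i`, `j`, `k`, `x`, `y`,
#' `z`, `label`) and/or a NIfTI label volume (3 mm isotropic, integer
#' codes in the label order background, liver, necrosis, carbonized, abs).
#'
#' @param map Output of [material_map()].
#' @param grid The matching [roi_grid()].
#' @param csv,nifti Output paths (either may be `NULL`).
#' @return Invisibly, the data frame written to CSV.
#' @export
export_material_map <- function(map, grid, csv = NULL, nifti = NULL) {
  ijk <- grid_ijk(grid, seq_len(grid$n_nodes))
  df <- data.frame(node = seq_len(grid$n_nodes), i = ijk[, 1], j = ijk[, 2],
                   k = ijk[, 3], x = grid$nodes[, 1], y = grid$nodes[, 2],
                   z = grid$nodes[, 3], label = as.character(map))
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(nifti)) {
    codes <- match(df$label, names(MATERIAL_OF_LABEL)) - 1L
    vol <- array(codes, dim = grid$shape)
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(grid$spacing, 3)),
                       nifti)
  }
  invisible(df)
}
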