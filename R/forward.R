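#' Complex wavenumber in a lossy medium
#'
#' `k = omega * sqrt(mu0 * eps_eq)` on the branch with `Im(k) <= 0`, so
#' that under the `exp(+j*omega*t)` convention the factor `exp(-1i*k*R)`
#' decays with distance in a passive medium.
#'
#' @inheritParams evaluate_permittivity
#' @return Complex wavenumber, rad/m (vectorized over frequency).
#' @export
wavenumber <- function(material, frequency) {
  eps <- evaluate_permittivity(material, frequency)$eps_complex
  k <- 2 * pi * frequency * sqrt(MU0 * eps)
  ifelse(Im(k) > 0, -k, k)
}

## Field of an elementary electric dipole (unit moment, orientation u) at
## source position pos_mm, evaluated at nodes_mm, in a homogeneous lossy
## medium. Full near + far terms (1/R, 1/R^2, 1/R^3).
dipole_field <- function(pos_mm, nodes_mm, polarization, background,
                         frequency, min_dist_mm = 0) {
  d <- sweep(nodes_mm, 2, pos_mm) * 1e-3          # m
  r <- sqrt(rowSums(d^2))
  if (min(r) * 1e3 < min_dist_mm - 1e-9)
    stop_mw("geometry error: a grid node lies within ", min_dist_mm,
            " mm of the source point")
  if (any(r == 0))
    stop_mw("geometry error: grid node coincides with the source point")
  nhat <- d / r
  u <- polarization
  ndotu <- as.vector(nhat %*% u)
  eps <- evaluate_permittivity(background, frequency)$eps_complex
  k <- wavenumber(background, frequency)
  pre <- exp(-1i * k * r) / (4 * pi * eps)
  far <- k^2 / r
  near <- 1 / r^3 + 1i * k / r^2
  E <- matrix(0i, nrow(nodes_mm), 3)
  for (cc in 1:3)
    E[, cc] <- pre * (far * (u[cc] - nhat[, cc] * ndotu) +
                        near * (3 * nhat[, cc] * ndotu - u[cc]))
  E
}

#' Incident field of one array element over the ROI
#'
#' Closed-form field of an elementary electric dipole placed at the
#' antenna tip with the array polarization, radiating in the homogeneous
#' lossy background. This analytic surrogate replaces a full-wave antenna
#' simulation; absolute signal levels are therefore not comparable with a
#' physical Vivaldi array, while the differential imaging chain is.
#'
#' @param array An [array_geometry()].
#' @param antenna Transmitter index `p`.
#' @param grid A [roi_grid()] (no node may lie within one voxel of the
#'   source point).
#' @param background Coupling-medium [dispersive_material()].
#' @param frequency Frequency, Hz (scalar).
#' @return `grid$n_nodes` x 3 complex matrix of E-field components (V/m
#'   per unit dipole moment).
#' @export
incident_field <- function(array, antenna, grid, background, frequency) {
  stopifnot(inherits(array, "array_geometry"),
            antenna >= 1, antenna <= array$n_antennas)
  dipole_field(array$tip_positions[antenna, ], grid$nodes,
               array$polarization, background, frequency,
               min_dist_mm = grid$spacing)
}

#' Incident fields for every antenna and frequency
#'
#' @inheritParams incident_field
#' @param frequencies Vector of frequencies, Hz.
#' @return An object of class `incident_field_set`: list with `fields`
#'   (one `n_nodes x 3 x n_antennas` complex array per frequency),
#'   `frequencies`, `grid`, `array`, `background`.
#' @export
incident_field_set <- function(array, grid, background, frequencies) {
  fields <- lapply(frequencies, function(f) {
    E <- array(0i, dim = c(grid$n_nodes, 3, array$n_antennas))
    for (p in seq_len(array$n_antennas))
      E[, , p] <- incident_field(array, p, grid, background, f)
    E
  })
  structure(list(fields = fields, frequencies = frequencies, grid = grid,
                 array = array, background = background),
            class = "incident_field_set")
}

#' Multistatic scattering dataset
#'
#' Per-frequency P x P complex S-matrices for one scenario. The diagonal
#' holds the reflection parameters, the off-diagonal entries the
#' transmission parameters; for reciprocal media the matrices are
#' symmetric.
#'
#' @param s `P x P x n_freq` complex array.
#' @param frequencies Frequencies, Hz.
#' @param scenario Scenario label or `NA`.
#' @param noise_meta Optional [noise_spec()] recorded after corruption.
#' @return An object of class `scattering_dataset`.
#' @export
scattering_dataset <- function(s, frequencies, scenario = NA,
                               noise_meta = NULL) {
  stopifnot(length(dim(s)) == 3, dim(s)[1] == dim(s)[2],
            dim(s)[3] == length(frequencies))
  structure(list(s = s, frequencies = frequencies, scenario = scenario,
                 noise_meta = noise_meta),
            class = "scattering_dataset")
}

#' @export
print.scattering_dataset <- function(x, ...) {
  cat("<scattering_dataset>", dim(x$s)[1], "ports x",
      length(x$frequencies), "frequencies; scenario:", x$scenario, "\n")
  invisible(x)
}

#' Reshape between the stacked data vector and per-frequency S-matrices
#'
#' The data-vector ordering is frequency-major, then transmitter `p`
#' major over receiver `q` (row-major on each P x P matrix), matching the
#' kernel row ordering; with 5 frequencies and 8 antennas the vector has
#' 320 entries. The two functions are exact inverses.
#'
#' @param s `P x P x n_freq` complex array (or a [scattering_dataset()]).
#' @return `as_data_vector()`: complex vector of length `n_freq * P^2`
#'   with attributes `n_antennas` and `frequencies`.
#' @export
as_data_vector <- function(s) {
  freqs <- NULL
  if (inherits(s, "scattering_dataset")) {
    freqs <- s$frequencies; s <- s$s
  }
  v <- as.vector(aperm(s, c(2, 1, 3)))
  attr(v, "n_antennas") <- dim(s)[1]
  attr(v, "frequencies") <- freqs
  v
}

#' @rdname as_data_vector
#' @param v Complex data vector in the documented ordering.
#' @param n_antennas,frequencies Shape information (taken from the vector
#'   attributes when absent).
#' @export
as_s_matrices <- function(v, n_antennas = attr(v, "n_antennas"),
                          frequencies = attr(v, "frequencies")) {
  p <- n_antennas
  nf <- length(v) / p^2
  if (nf != round(nf))
    stop_mw("contract error: data vector length is not a multiple of P^2")
  aperm(array(v, dim = c(p, p, nf)), c(2, 1, 3))
}

#' Differential scattering data between two acquisitions
#'
#' Entrywise `S(meas) - S(ref)` reshaped to the documented data-vector
#' ordering (frequency-major, transmitter-major over receiver).
#'
#' @param meas,ref [scattering_dataset()]s on the same array and
#'   frequency list.
#' @return Complex data vector (length `n_freq * P^2`).
#' @export
differential_data <- function(meas, ref) {
  stopifnot(inherits(meas, "scattering_dataset"),
            inherits(ref, "scattering_dataset"))
  if (length(meas$frequencies) != length(ref$frequencies) ||
      any(abs(meas$frequencies - ref$frequencies) >
            1e-6 * meas$frequencies))
    stop_mw("contract error: frequency lists differ between datasets")
  if (!all(dim(meas$s) == dim(ref$s)))
    stop_mw("contract error: dataset dimensions differ")
  v <- as_data_vector(meas$s - ref$s)
  attr(v, "frequencies") <- meas$frequencies
  v
}

#' Noise specification for simulated acquisitions
#'
#' Additive i.i.d. circular complex Gaussian noise, calibrated so that the
#' per-frequency noise power equals the per-frequency signal power times
#' `10^(-snr_db/10)`. The default 45 dB reflects the noise floor and
#' dynamic range of commercial vector network analyzers.
#'
#' @param snr_db Signal-to-noise ratio, dB (`Inf` disables noise).
#' @param seed Integer seed; identical spec and seed reproduce the noise
#'   realization bit for bit.
#' @param per_frequency Calibrate the noise power per frequency (default)
#'   rather than over the whole sweep.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr_db = 45, seed = NULL, per_frequency = TRUE) {
  stopifnot(is.numeric(snr_db), length(snr_db) == 1, !is.na(snr_db))
  structure(list(snr_db = snr_db, seed = seed,
                 per_frequency = isTRUE(per_frequency)),
            class = "noise_spec")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add calibrated complex Gaussian noise to a scattering dataset
#'
#' Each complex entry receives independent circular complex Gaussian
#' noise. The per-entry noise power is the per-entry signal power (mean
#' squared magnitude over the calibration scope) times
#' `10^(-snr_db/10)`. An external `reference_power` (per-frequency mean
#' squared magnitude per entry) can stand in for the dataset's own power,
#' e.g. to impose a common noise floor across acquisitions including an
#' empty-reference one.
#'
#' @param data A [scattering_dataset()] or a complex data vector.
#' @param spec A [noise_spec()].
#' @param reference_power Optional numeric, per-frequency per-entry signal
#'   power used for calibration instead of the data's own power.
#' @return Noisy copy of `data` (same class); datasets carry `spec` in
#'   `noise_meta`.
#' @export
add_noise <- function(data, spec = noise_spec(), reference_power = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  if (is.infinite(spec$snr_db)) return(data)
  is_ds <- inherits(data, "scattering_dataset")
  s <- if (is_ds) data$s else data
  dm <- if (is_ds) dim(s) else c(length(s), 1, 1)
  arr <- array(s, dim = if (is_ds) dm else c(dm[1], 1, 1))
  nf <- dim(arr)[3]
  pow <- if (!is.null(reference_power)) rep_len(reference_power, nf)
  else apply(arr, 3, function(m) mean(Mod(m)^2))
  if (!spec$per_frequency) pow <- rep(mean(pow), nf)
  if (any(pow <= 0))
    stop_mw("calibration error: zero signal power with finite SNR and ",
            "no reference_power")
  noisy <- with_seed(spec$seed, {
    for (fi in seq_len(nf)) {
      npow <- pow[fi] * 10^(-spec$snr_db / 10)
      nentry <- length(arr[, , fi])
      arr[, , fi] <- arr[, , fi] + sqrt(npow / 2) *
        (stats::rnorm(nentry) + 1i * stats::rnorm(nentry))
    }
    arr
  })
  if (is_ds)
    scattering_dataset(noisy, data$frequencies, data$scenario,
                       noise_meta = spec)
  else {
    out <- as.vector(noisy)
    attributes(out) <- attributes(data)
    out
  }
}

#' Differential Born data on a refined forward grid
#'
#' Computes Born-approximation differential data for a scenario pair on a
#' grid `refinement` times finer than the imaging grid, by direct
#' summation over the contrast support. With `refinement = 1` this
#' reproduces the coarse kernel product exactly; with the default
#' `refinement = 2` (1.5 mm forward grid) the "measured" data come from a
#' discretization independent of the inversion kernel, mitigating the
#' inverse crime.
#'
#' @param from,to Scenario labels of the pair.
#' @param array An [array_geometry()].
#' @param grid The imaging [roi_grid()]; the forward grid shares its
#'   extent and origin with spacing `grid$spacing / refinement`.
#' @param background Coupling-medium material.
#' @param frequencies Frequencies, Hz.
#' @param materials Material library.
#' @param phantom A [phantom_spec()].
#' @param refinement Integer grid refinement factor (>= 1).
#' @param reference_frequency Frequency at which the ground-truth contrast
#'   is evaluated (default 1 GHz band center).
#' @param node_cap Memory guard: maximum refined node count.
#' @return Complex data vector (length `n_freq * P^2`) in the documented
#'   ordering, with `frequencies` attribute.
#' @export
fine_grid_forward <- function(from, to, array, grid, background,
                              frequencies,
                              materials = material_library(),
                              phantom = phantom_spec(),
                              refinement = 2, reference_frequency = 1e9,
                              node_cap = 2e6) {
  stopifnot(refinement >= 1, refinement == round(refinement))
  fine <- roi_grid(grid$extent, grid$spacing / refinement, grid$origin)
  if (fine$n_nodes > node_cap)
    stop_mw("memory guard: refined grid has ", fine$n_nodes,
            " nodes, above node_cap = ", node_cap)
  gt <- ground_truth_contrast(from, to, fine, reference_frequency,
                              materials, phantom)
  p <- array$n_antennas
  nf <- length(frequencies)
  out <- complex(nf * p^2)
  supp <- which(gt$values != 0)
  if (length(supp)) {
    xs <- gt$values[supp]
    nodes <- fine$nodes[supp, , drop = FALSE]
    dv <- (fine$spacing * 1e-3)^3
    for (fi in seq_len(nf)) {
      f <- frequencies[fi]
      eps_cm <- evaluate_permittivity(background, f)$eps_complex
      coef <- -1i / (4 * (2 * pi * f) * eps_cm) * dv
      E <- lapply(seq_len(p), function(a)
        dipole_field(array$tip_positions[a, ], nodes, array$polarization,
                     background, f, min_dist_mm = fine$spacing))
      for (pp in seq_len(p)) for (qq in pp:p) {
        dot <- E[[pp]][, 1] * E[[qq]][, 1] + E[[pp]][, 2] * E[[qq]][, 2] +
          E[[pp]][, 3] * E[[qq]][, 3]
        val <- coef * sum(dot * xs)
        out[(fi - 1) * p^2 + (pp - 1) * p + qq] <- val
        out[(fi - 1) * p^2 + (qq - 1) * p + pp] <- val
      }
    }
  }
  attr(out, "n_antennas") <- p
  attr(out, "frequencies") <- frequencies
  out
}
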