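#' L2 (Frobenius) norm of an S-matrix
#'
#' `sqrt(sum_ij |S_ij|^2)`, the signal-level measure used to compare
#' acquisitions.
#'
#' @param S Complex matrix.
#' @return Nonnegative scalar.
#' @export
s_matrix_norm <- function(S) sqrt(sum(Mod(S)^2))

#' Per-frequency differential signal level in dB
#'
#' `20 * log10(||dS(f)|| / ||S_ref(f)||)`: the norm of each differential
#' scattering matrix normalized to a reference acquisition and expressed
#' in dB (identical numbers to `10*log10` of the energy ratio).
#'
#' @param dS Differential data: a [scattering_dataset()], a
#'   `P x P x n_freq` array, or a stacked data vector with attributes.
#' @param ref Reference: a [scattering_dataset()] with matching
#'   frequencies, or a numeric vector of per-frequency reference norms.
#' @return Numeric vector of per-frequency levels, dB.
#' @export
differential_level_db <- function(dS, ref) {
  arr <- if (inherits(dS, "scattering_dataset")) dS$s
  else if (is.array(dS) && length(dim(dS)) == 3) dS
  else as_s_matrices(dS)
  dnorm <- apply(arr, 3, s_matrix_norm)
  rnorm <- if (inherits(ref, "scattering_dataset"))
    apply(ref$s, 3, s_matrix_norm) else ref
  if (length(rnorm) != length(dnorm))
    stop_mw("contract error: frequency counts differ")
  if (any(rnorm <= 0))
    stop_mw("reference norm is zero; differential level undefined")
  20 * log10(dnorm / rnorm)
}

#' Average several dB levels in linear power
#'
#' `10 * log10(mean(10^(levels/10)))`.
#'
#' @param levels_db Numeric vector of dB levels.
#' @return Scalar dB.
#' @export
average_level_db <- function(levels_db)
  10 * log10(mean(10^(levels_db / 10)))

#' Noise level relative to the differential signal
#'
#' With measurement noise `snr_db` below the total signal and a
#' differential signal sitting `diff_level_db` (negative dB) relative to
#' the same total signal, the noise relative to the differential signal
#' is `-snr_db - diff_level_db`: e.g. 45 dB SNR with a -30 dB average
#' differential level gives a -15 dB differential noise level.
#'
#' @param snr_db Measurement signal-to-noise ratio, dB (positive).
#' @param diff_level_db Differential signal level relative to the total
#'   signal, dB (typically negative).
#' @return Noise-to-differential-signal level, dB.
#' @export
noise_on_differential_db <- function(snr_db, diff_level_db)
  -snr_db - diff_level_db

#' Normalized mean square error between a reconstruction and its ideal
#'
#' `NMSE = sum_voxels |I_ID - I|^2 / sum_voxels |I_ID|^2` over the
#' normalized magnitudes. Both inputs are defensively re-normalized to
#' unit maximum by default.
#'
#' @param I Reconstructed image: a [contrast_image()] or numeric vector.
#' @param I_id Ideal reconstruction (same form); must not be all zero.
#' @param renormalize Re-normalize both inputs to unit maximum first.
#' @return Nonnegative scalar; 0 iff the images are identical.
#' @export
nmse <- function(I, I_id, renormalize = TRUE) {
  as_mag <- function(x)
    if (inherits(x, "contrast_image")) x$normalized_magnitude else
      as.numeric(x)
  a <- as_mag(I); b <- as_mag(I_id)
  if (length(a) != length(b))
    stop_mw("contract error: image lengths differ")
  if (all(b == 0)) stop_mw("NMSE undefined: ideal image is all zero")
  if (renormalize) {
    if (max(a) > 0) a <- a / max(a)
    b <- b / max(b)
  }
  sum((b - a)^2) / sum(b^2)
}

## Connected component (6-connectivity) containing the seed voxel.
connected_component <- function(mask, seed_ijk) {
  shape <- dim(mask)
  visited <- array(FALSE, shape)
  frontier <- matrix(seed_ijk, ncol = 3)
  visited[frontier] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (nrow(frontier)) {
    nxt <- do.call(rbind, lapply(seq_len(6), function(o)
      sweep(frontier, 2, offs[o, ], `+`)))
    keep <- nxt[, 1] >= 1 & nxt[, 1] <= shape[1] &
      nxt[, 2] >= 1 & nxt[, 2] <= shape[2] &
      nxt[, 3] >= 1 & nxt[, 3] <= shape[3]
    nxt <- nxt[keep, , drop = FALSE]
    if (nrow(nxt)) {
      ok <- mask[nxt] & !visited[nxt]
      nxt <- unique(nxt[ok, , drop = FALSE])
    }
    if (nrow(nxt)) visited[nxt] <- TRUE
    frontier <- nxt
  }
  which(visited, arr.ind = TRUE)
}

#' Localization summary of a reconstructed image
#'
#' Thresholds the image magnitude, takes the connected supra-threshold
#' region containing the brightest voxel, and reports its bounding box,
#' extent, centroid and — when a phantom is supplied — the offset of the
#' region's near face (smallest z) from the phantom's near face along
#' the boresight. Negative offsets mean the target appears closer to the
#' array than it is, the bias the one-sided acquisition produces.
#'
#' @param image A [contrast_image()], or a numeric magnitude vector (not
#'   re-normalized, so an all-noise image below threshold reports no
#'   detection).
#' @param grid The [roi_grid()] (taken from the image when omitted).
#' @param phantom Optional [phantom_spec()].
#' @param threshold Detection threshold on the magnitude, in (0, 1).
#' @param target Which ellipsoid the pair is meant to image (`"outer"`
#'   or `"inner"`), setting the reference near face and extent.
#' @return A list with `detected`, and when detected: `bbox_mm` (2 x 3),
#'   `extent_mm`, `centroid_mm`, `n_voxels`, and with a phantom
#'   `z_near_offset_mm`, `bias_toward_array_mm` (= -offset) and
#'   `z_center_offset_mm` (centroid minus phantom near face).
#' @export
localization_report <- function(image, grid = NULL, phantom = NULL,
                                threshold = 0.5, target = "outer") {
  stopifnot(threshold > 0, threshold < 1)
  if (inherits(image, "contrast_image")) {
    grid <- image$grid
    mag <- image$normalized_magnitude
  } else mag <- as.numeric(image)
  if (is.null(grid)) stop_mw("contract error: grid required")
  vol <- array(mag, dim = grid$shape)
  mask <- vol >= threshold
  if (!any(mask)) return(list(detected = FALSE))
  seed <- which(vol == max(vol), arr.ind = FALSE)[1]
  comp <- connected_component(mask, grid_ijk(grid, seed))
  coords <- cbind(grid$x[comp[, 1]], grid$y[comp[, 2]], grid$z[comp[, 3]])
  w <- vol[comp]
  bbox <- rbind(min = apply(coords, 2, min), max = apply(coords, 2, max))
  colnames(bbox) <- c("x", "y", "z")
  out <- list(detected = TRUE, bbox_mm = bbox,
              extent_mm = bbox[2, ] - bbox[1, ],
              centroid_mm = colSums(coords * w) / sum(w),
              n_voxels = nrow(comp))
  if (!is.null(phantom)) {
    semi <- if (identical(target, "inner")) phantom$inner_semi_axes else
      phantom$outer_semi_axes
    near_z <- phantom$center[3] - semi[3]
    out$target_extent_mm <- 2 * semi
    out$z_near_offset_mm <- unname(bbox[1, "z"] - near_z)
    out$bias_toward_array_mm <- -out$z_near_offset_mm
    out$z_center_offset_mm <- unname(out$centroid_mm[3] - near_z)
  }
  out
}

#' Tabulate signal levels for a set of acquisitions
#'
#' Per-scenario, per-frequency S-matrix norms, the machinery behind the
#' signal-level comparison of acquisitions.
#'
#' @param datasets Named list of [scattering_dataset()]s.
#' @return Data frame with columns `scenario`, `frequency_hz`, `norm`.
#' @export
signal_level_table <- function(datasets) {
  do.call(rbind, lapply(names(datasets), function(nm) {
    ds <- datasets[[nm]]
    data.frame(scenario = nm, frequency_hz = ds$frequencies,
               norm = apply(ds$s, 3, s_matrix_norm))
  }))
}
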