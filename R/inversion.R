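#' Assemble the linearized scattering kernel
#'
#' Row `m = (f, p, q)`, column `n` (ROI node):
#' `K_mn = -1i / (4 * omega_f * eps_eqCM) * (E_i(r_n, p) . E_i(r_n, q)) * dV`
#' with the non-conjugated (bilinear) dot product of the two incident
#' 3-vector fields — the data equation derived from reciprocity is
#' bilinear, not sesquilinear — and the voxel volume `dV` making the
#' matrix a Riemann-sum discretization of the scattering integral. Rows
#' for `(p, q)` and `(q, p)` are identical. Row ordering is
#' frequency-major, then transmitter-major, matching [as_data_vector()].
#'
#' @param fields An [incident_field_set()] covering all antennas and
#'   frequencies on the imaging grid.
#' @param grid The imaging [roi_grid()].
#' @param background Coupling-medium [dispersive_material()].
#' @return An object of class `mwi_kernel`: list with `matrix`
#'   (`n_freq * P^2` x `n_nodes` complex), `row_index` (data frame `m`,
#'   `frequency`, `p`, `q`), `frequencies`, `grid`, `background`.
#' @export
build_kernel <- function(fields, grid, background) {
  stopifnot(inherits(fields, "incident_field_set"))
  if (!is.null(fields$grid) && fields$grid$n_nodes != grid$n_nodes)
    stop_mw("contract error: field set and grid node counts differ")
  p <- dim(fields$fields[[1]])[3]
  nf <- length(fields$frequencies)
  n <- grid$n_nodes
  if (any(vapply(fields$fields, function(E) dim(E)[1], 0) != n))
    stop_mw("contract error: field set does not cover all grid nodes")
  dv <- (grid$spacing * 1e-3)^3
  K <- matrix(0i, nf * p^2, n)
  for (fi in seq_len(nf)) {
    f <- fields$frequencies[fi]
    eps_cm <- evaluate_permittivity(background, f)$eps_complex
    coef <- -1i / (4 * (2 * pi * f) * eps_cm) * dv
    E <- fields$fields[[fi]]
    for (pp in seq_len(p)) for (qq in pp:p) {
      row <- coef * (E[, 1, pp] * E[, 1, qq] + E[, 2, pp] * E[, 2, qq] +
                       E[, 3, pp] * E[, 3, qq])
      K[(fi - 1) * p^2 + (pp - 1) * p + qq, ] <- row
      if (qq != pp) K[(fi - 1) * p^2 + (qq - 1) * p + pp, ] <- row
    }
  }
  ridx <- expand.grid(q = seq_len(p), p = seq_len(p),
                      fi = seq_len(nf))[, c(3, 2, 1)]
  row_index <- data.frame(m = seq_len(nf * p^2),
                          frequency = fields$frequencies[ridx$fi],
                          p = ridx$p, q = ridx$q)
  structure(list(matrix = K, row_index = row_index,
                 frequencies = fields$frequencies, grid = grid,
                 background = background),
            class = "mwi_kernel")
}

#' @export
print.mwi_kernel <- function(x, ...) {
  cat("<mwi_kernel>", nrow(x$matrix), "x", ncol(x$matrix),
      "complex;", length(x$frequencies), "frequencies\n")
  invisible(x)
}

#' Born-approximation forward data
#'
#' The linearized data equation `delta_S = K %*% delta_x`: multiplying
#' the kernel by a contrast vector yields the stacked differential data
#' vector.
#'
#' @param kernel An [build_kernel()] result.
#' @param contrast A [contrast_image()] on the kernel grid (or a complex
#'   vector of matching length).
#' @return Complex data vector with `frequencies` attribute.
#' @export
born_forward <- function(kernel, contrast) {
  x <- if (inherits(contrast, "contrast_image")) contrast$values else
    contrast
  if (length(x) != ncol(kernel$matrix))
    stop_mw("contract error: contrast length ", length(x),
            " does not match kernel columns ", ncol(kernel$matrix))
  v <- as.vector(kernel$matrix %*% x)
  attr(v, "n_antennas") <- as.integer(sqrt(nrow(kernel$matrix) /
                                             length(kernel$frequencies)))
  attr(v, "frequencies") <- kernel$frequencies
  v
}

#' Singular value decomposition of the kernel
#'
#' Thin SVD `K = U Sigma V^H` (LAPACK, complex). The factors depend only
#' on geometry, background and frequencies — never on the scenario — so
#' they can be cached and reused across the whole monitoring session;
#' with `cache_dir` set they are stored on disk keyed by a hash of the
#' kernel configuration.
#'
#' @param kernel An [build_kernel()] result.
#' @param cache_dir Optional directory for the factor cache.
#' @return An object of class `kernel_svd`: list with `u` (M x M), `d`
#'   (singular values, nonincreasing), `v` (N x M), `rank` (count of
#'   singular values above `max(dim) * eps * d[1]`), `grid`,
#'   `frequencies`.
#' @export
compute_svd <- function(kernel, cache_dir = NULL) {
  key <- NULL
  if (!is.null(cache_dir)) {
    key <- rlang::hash(list(kernel$grid$extent, kernel$grid$spacing,
                            kernel$grid$origin, kernel$frequencies,
                            kernel$row_index, kernel$background,
                            dim(kernel$matrix)))
    cf <- file.path(cache_dir, paste0("svd-", key, ".rds"))
    if (file.exists(cf)) return(readRDS(cf))
  }
  sv <- La.svd(kernel$matrix)
  out <- structure(list(u = sv$u, d = sv$d, v = Conj(t(sv$vt)),
                        rank = sum(sv$d > max(dim(kernel$matrix)) *
                                     .Machine$double.eps * sv$d[1]),
                        grid = kernel$grid,
                        frequencies = kernel$frequencies),
                   class = "kernel_svd")
  if (!is.null(key)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(out, cf)
  }
  out
}

#' @export
print.kernel_svd <- function(x, ...) {
  cat("<kernel_svd>", length(x$d), "singular values, numerical rank",
      x$rank, "; sigma1 =", format(x$d[1]), "\n")
  invisible(x)
}

#' Detect slope-change candidates on the singular value curve and select
#' the TSVD truncation index
#'
#' Works on the dB-normalized spectrum `20*log10(sigma_i / sigma_1)`.
#' Around each index the local slope is estimated over a window on both
#' sides; indices where the slope change exceeds `prominence_db` (dB per
#' index) mark knees of the curve, the classical truncation candidates.
#' The selected threshold is the largest candidate whose normalized
#' singular value still sits at or above the expected noise level on the
#' differential signal (default -15 dB): truncating there keeps every
#' subspace whose gain is above the noise while discarding the
#' noise-dominated tail. When no candidate qualifies, the index where the
#' curve crosses the noise level is used, with a warning.
#'
#' @param sigma Nonincreasing singular values (>= 8 of them).
#' @param noise_db Expected noise-to-differential-signal level, dB.
#' @param window Half-width (indices) of the slope-estimation window.
#' @param prominence_db Minimum slope change (dB/index) for a knee.
#' @return A list with `candidates` (integer indices), `selected` (the
#'   chosen truncation index `nu`), `sigma_db` (normalized curve) and
#'   `fallback` (logical).
#' @export
threshold_candidates <- function(sigma, noise_db = -15, window = 5,
                                 prominence_db = 0.5) {
  n <- length(sigma)
  if (n < 8) stop_mw("contract error: need at least 8 singular values")
  if (any(diff(sigma) > 1e-12 * sigma[1]))
    stop_mw("contract error: singular values must be nonincreasing")
  s_db <- 20 * log10(pmax(sigma, .Machine$double.xmin) / sigma[1])
  w <- max(2L, as.integer(window))
  change <- rep(0, n)
  idx <- (w + 1):(n - w)
  if (length(idx)) {
    left <- (s_db[idx] - s_db[idx - w]) / w
    right <- (s_db[idx + w] - s_db[idx]) / w
    change[idx] <- abs(right - left)
  }
  above <- which(change > prominence_db)
  candidates <- integer()
  if (length(above)) {
    runs <- split(above, cumsum(c(1, diff(above) > 1)))
    candidates <- vapply(runs, function(r) r[which.max(change[r])], 0L)
    candidates <- sort(unname(candidates))
  }
  ok <- candidates[s_db[candidates] >= noise_db]
  if (length(ok)) {
    selected <- max(ok)
    fallback <- FALSE
  } else {
    selected <- max(which(s_db >= noise_db))
    fallback <- TRUE
    warning("no slope-change candidate above the noise level; ",
            "falling back to the noise-crossing index ", selected,
            call. = FALSE)
  }
  list(candidates = candidates, selected = as.integer(selected),
       sigma_db = s_db, fallback = fallback)
}

#' TSVD inversion of differential data
#'
#' `delta_x = V Sigma_nu^{-1} U^H delta_S`, i.e. the truncated expansion
#' `sum_{i<=nu} (u_i^H delta_S / sigma_i) v_i`. The truncation index
#' `nu` is the regularization parameter trading accuracy for stability.
#'
#' @param svd A [compute_svd()] result.
#' @param data Complex data vector (length = kernel rows).
#' @param nu Truncation index, `1 <= nu <= rank`.
#' @return A [contrast_image()] on the kernel grid.
#' @export
tsvd_solve <- function(svd, data, nu) {
  stopifnot(inherits(svd, "kernel_svd"))
  if (length(data) != nrow(svd$u))
    stop_mw("contract error: data length ", length(data),
            " does not match kernel rows ", nrow(svd$u))
  nu <- as.integer(nu)
  if (nu < 1 || nu > length(svd$d))
    stop_mw("config error: nu must lie in [1, ", length(svd$d), "]")
  if (svd$d[nu] <= max(dim(svd$v)) * .Machine$double.eps * svd$d[1])
    stop_mw("rank error: sigma_nu is numerically zero at nu = ", nu)
  coef <- as.vector(Conj(t(svd$u[, seq_len(nu), drop = FALSE])) %*%
                      as.vector(data)) / svd$d[seq_len(nu)]
  x <- as.vector(svd$v[, seq_len(nu), drop = FALSE] %*% coef)
  contrast_image(x, svd$grid, frequency = NA)
}

#' Ideal TSVD reconstruction of a known contrast
#'
#' The projection `delta_x_ID = V_nu V_nu^H delta_x_GT` of the ground
#' truth onto the first `nu` right singular vectors — the best image the
#' truncated linear scheme can produce, used as the benchmark in the
#' NMSE evaluation.
#'
#' @param svd A [compute_svd()] result.
#' @param ground_truth A [contrast_image()] (or complex vector) on the
#'   kernel grid.
#' @param nu Truncation index.
#' @return A [contrast_image()].
#' @export
ideal_reconstruction <- function(svd, ground_truth, nu) {
  x <- if (inherits(ground_truth, "contrast_image")) ground_truth$values
  else ground_truth
  if (length(x) != nrow(svd$v))
    stop_mw("contract error: ground truth is not on the kernel grid")
  nu <- as.integer(nu)
  if (nu < 1 || nu > length(svd$d))
    stop_mw("config error: nu must lie in [1, ", length(svd$d), "]")
  vn <- svd$v[, seq_len(nu), drop = FALSE]
  contrast_image(as.vector(vn %*% (Conj(t(vn)) %*% x)), svd$grid)
}

#' Export the singular spectrum as CSV
#'
#' Columns `index`, `sigma`, `sigma_db` (normalized to the largest).
#'
#' @param svd A [compute_svd()] result (or numeric vector of singular
#'   values).
#' @param path CSV output path.
#' @return Invisibly, the data frame written.
#' @export
export_spectrum_csv <- function(svd, path) {
  d <- if (inherits(svd, "kernel_svd")) svd$d else svd
  df <- data.frame(index = seq_along(d), sigma = d,
                   sigma_db = 20 * log10(d / d[1]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export a contrast image as NIfTI and/or CSV
#'
#' The NIfTI volume holds the normalized magnitude on the ROI lattice
#' (isotropic `grid$spacing` mm voxels); the CSV holds node index,
#' subscripts, coordinates, real/imaginary contrast and normalized
#' magnitude.
#'
#' @param image A [contrast_image()].
#' @param nifti,csv Output paths (either may be `NULL`).
#' @return Invisibly, the CSV data frame.
#' @export
export_image <- function(image, nifti = NULL, csv = NULL) {
  grid <- image$grid
  if (!is.null(nifti)) {
    vol <- array(image$normalized_magnitude, dim = grid$shape)
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(grid$spacing, 3)),
                       nifti)
  }
  ijk <- grid_ijk(grid, seq_len(grid$n_nodes))
  df <- data.frame(node = seq_len(grid$n_nodes), i = ijk[, 1],
                   j = ijk[, 2], k = ijk[, 3],
                   x = grid$nodes[, 1], y = grid$nodes[, 2],
                   z = grid$nodes[, 3],
                   re = Re(image$values), im = Im(image$values),
                   intensity = image$normalized_magnitude)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  invisible(df)
}
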