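#' Define a dispersive material
#'
#' A material is described either by frequency-independent relative
#' permittivity and conductivity (`model = "constant"`), by a table of
#' measured `(frequency, eps_r, sigma)` rows interpolated linearly
#' (`model = "table"`), or by a multi-pole Debye or Cole-Cole relaxation
#' model. Table evaluation outside the tabulated range is an error, never
#' an extrapolation.
#'
#' All complex permittivities follow the engineering `exp(+j*omega*t)` time
#' convention, under which passive media have a non-positive imaginary
#' part: `eps_eq = eps_r*eps0 - 1i*sigma/omega`.
#'
#' @param name Material label.
#' @param model One of `"constant"`, `"table"`, `"debye"`, `"cole_cole"`.
#' @param eps_r Real relative permittivity (constant model), `>= 1`.
#' @param sigma Conductivity in S/m (constant model), `>= 0`.
#' @param model_params For `debye`/`cole_cole`: a list with `eps_inf`,
#'   `delta_eps` (vector of pole amplitudes), `tau` (vector of relaxation
#'   times, s), optional `alpha` (Cole-Cole broadening per pole, in
#'   `[0, 1)`) and `sigma_s` (static conductivity, S/m).
#' @param table A data frame with columns `frequency_hz`, `eps_r`,
#'   `sigma_s_per_m`; frequencies strictly increasing.
#' @return An object of class `dispersive_material`.
#' @examples
#' cm <- dispersive_material("coupling_medium", "constant",
#'                           eps_r = 23, sigma = 0.07)
#' evaluate_permittivity(cm, 1e9)
#' @export
dispersive_material <- function(name,
                                model = c("constant", "table", "debye",
                                          "cole_cole"),
                                eps_r = NULL, sigma = NULL,
                                model_params = NULL, table = NULL) {
  model <- match.arg(model)
  if (model == "constant") {
    if (is.null(eps_r) || is.null(sigma))
      stop_mw("config error: constant material '", name,
              "' needs eps_r and sigma")
    if (eps_r < 1) stop_mw("config error: eps_r must be >= 1")
    if (sigma < 0) stop_mw("config error: sigma must be >= 0")
  } else if (model == "table") {
    req <- c("frequency_hz", "eps_r", "sigma_s_per_m")
    if (is.null(table) || !all(req %in% names(table)))
      stop_mw("config error: table material '", name,
              "' needs columns ", paste(req, collapse = ", "))
    table <- as.data.frame(table)[req]
    if (nrow(table) < 2 || any(diff(table$frequency_hz) <= 0))
      stop_mw("config error: table frequencies must be strictly increasing")
    if (any(table$eps_r < 1) || any(table$sigma_s_per_m < 0))
      stop_mw("config error: table rows must have eps_r >= 1, sigma >= 0")
  } else {
    if (is.null(model_params) ||
        !all(c("eps_inf", "delta_eps", "tau") %in% names(model_params)))
      stop_mw("config error: ", model, " material '", name,
              "' needs model_params with eps_inf, delta_eps, tau")
    if (length(model_params$delta_eps) != length(model_params$tau))
      stop_mw("config error: delta_eps and tau lengths differ")
  }
  structure(list(name = name, model = model, eps_r = eps_r, sigma = sigma,
                 model_params = model_params, table = table),
            class = "dispersive_material")
}

#' @export
print.dispersive_material <- function(x, ...) {
  cat("<dispersive_material>", x$name, "- model:", x$model, "\n")
  if (x$model == "constant")
    cat("  eps_r =", x$eps_r, ", sigma =", x$sigma, "S/m\n")
  if (x$model == "table")
    cat("  table over", min(x$table$frequency_hz) / 1e6, "-",
        max(x$table$frequency_hz) / 1e6, "MHz (",
        nrow(x$table), "rows )\n")
  invisible(x)
}

#' Evaluate the complex equivalent permittivity of a material
#'
#' Returns `eps_eq(f) = eps_r(f)*eps0 - 1i*sigma(f)/omega` (F/m) under the
#' `exp(+j*omega*t)` convention, together with the real relative
#' permittivity and conductivity at each requested frequency.
#'
#' @param material A [dispersive_material()].
#' @param frequency Frequency in Hz (vectorized).
#' @return An object of class `complex_permittivity`: a list with
#'   `frequency`, `eps_r`, `sigma`, `eps_complex` (F/m) and the time
#'   `convention` flag.
#' @export
evaluate_permittivity <- function(material, frequency) {
  stopifnot(inherits(material, "dispersive_material"))
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop_mw("config error: frequency must be finite and positive")
  omega <- 2 * pi * frequency
  if (material$model == "constant") {
    eps_r <- rep_len(material$eps_r, length(frequency))
    sigma <- rep_len(material$sigma, length(frequency))
  } else if (material$model == "table") {
    tb <- material$table
    rng <- range(tb$frequency_hz)
    if (any(frequency < rng[1] | frequency > rng[2]))
      stop_mw("range error: frequency outside table range [",
              rng[1], ", ", rng[2], "] Hz for material '",
              material$name, "'")
    eps_r <- stats::approx(tb$frequency_hz, tb$eps_r, xout = frequency)$y
    sigma <- stats::approx(tb$frequency_hz, tb$sigma_s_per_m,
                           xout = frequency)$y
  } else {
    mp <- material$model_params
    alpha <- mp$alpha %||% rep(0, length(mp$tau))
    expo <- if (material$model == "debye") rep(1, length(mp$tau)) else
      1 - alpha
    eps_rc <- rep(mp$eps_inf + 0i, length(omega))
    for (i in seq_along(mp$tau))
      eps_rc <- eps_rc + mp$delta_eps[i] /
        (1 + (1i * omega * mp$tau[i])^expo[i])
    sigma_s <- mp$sigma_s %||% 0
    eps_r <- Re(eps_rc)
    sigma <- -omega * EPS0 * Im(eps_rc) + sigma_s
  }
  if (any(eps_r < 1) || any(sigma < 0))
    stop_mw("config error: material '", material$name,
            "' evaluates to eps_r < 1 or sigma < 0")
  structure(list(frequency = frequency, eps_r = eps_r, sigma = sigma,
                 eps_complex = eps_r * EPS0 - 1i * sigma / omega,
                 convention = "exp(+jwt)"),
            class = "complex_permittivity")
}

#' Wavelength in a material
#'
#' `lambda = c0 / (f * Re(sqrt(eps_r_complex)))`, where `eps_r_complex`
#' is the complex relative permittivity; for low-loss media this reduces
#' to `c0 / (f * sqrt(eps_r))`.
#'
#' @inheritParams evaluate_permittivity
#' @return Wavelength in metres (vectorized over frequency).
#' @export
wavelength_in_medium <- function(material, frequency) {
  perm <- evaluate_permittivity(material, frequency)
  n_eff <- Re(sqrt(perm$eps_complex / EPS0))
  C0 / (frequency * n_eff)
}

#' Built-in material library for the ablation-monitoring setup
#'
#' The coupling medium (eps_r 23, sigma 0.07 S/m), pre-ablation liver and
#' coagulation-necrosis tissue (band-limited linear dispersion defaults
#' over 600-1400 MHz, editable placeholders standing in for measured
#' dispersion data), carbonized tissue (single-frequency literature value
#' treated as frequency-constant) and ABS shell plastic.
#'
#' @param overrides Optional named list of [dispersive_material()] objects
#'   (or lists coercible via [as_material()]) replacing defaults by name.
#' @return Named list of `dispersive_material` objects with names
#'   `coupling_medium`, `liver`, `necrosis`, `carbonized`, `abs`.
#' @export
material_library <- function(overrides = NULL) {
  lib <- list(
    coupling_medium = dispersive_material("coupling_medium", "constant",
                                          eps_r = 23, sigma = 0.07),
    liver = dispersive_material(
      "liver", "table",
      table = data.frame(frequency_hz = c(600e6, 1400e6),
                         eps_r = c(50, 46),
                         sigma_s_per_m = c(0.65, 1.0))),
    necrosis = dispersive_material(
      "necrosis", "table",
      table = data.frame(frequency_hz = c(600e6, 1400e6),
                         eps_r = c(42, 38),
                         sigma_s_per_m = c(0.55, 0.85))),
    carbonized = dispersive_material("carbonized", "constant",
                                     eps_r = 8.33, sigma = 0.39),
    abs = dispersive_material("abs", "constant",
                              eps_r = 3, sigma = 4e-3))
  if (!is.null(overrides)) {
    for (nm in names(overrides)) lib[[nm]] <- as_material(overrides[[nm]], nm)
  }
  lib
}

#' Coerce a plain list (e.g. from a YAML config) to a dispersive material
#'
#' @param x A `dispersive_material` or a list with a `model` field and the
#'   matching parameters (`eps_r`/`sigma`, `table` rows, or `model_params`).
#' @param name Label used when `x` carries none.
#' @return A [dispersive_material()].
#' @export
as_material <- function(x, name = x$name) {
  if (inherits(x, "dispersive_material")) return(x)
  if (!is.list(x) || is.null(x$model))
    stop_mw("config error: cannot interpret material '", name, "'")
  tb <- x$table
  if (!is.null(tb) && !is.data.frame(tb))
    tb <- as.data.frame(lapply(as.data.frame(do.call(rbind, tb)), unlist))
  dispersive_material(name %||% "material", model = x$model,
                      eps_r = x$eps_r, sigma = x$sigma,
                      model_params = x$model_params, table = tb)
}

#' Read a table-model material from CSV
#'
#' Expects columns `frequency_hz`, `eps_r`, `sigma_s_per_m`.
#'
#' @param path CSV file path.
#' @param name Material label.
#' @return A [dispersive_material()] with `model = "table"`.
#' @export
read_material_table <- function(path, name) {
  dispersive_material(name, "table",
                      table = utils::read.csv(path, strip.white = TRUE))
}
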