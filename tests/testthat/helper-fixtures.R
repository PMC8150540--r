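## Shared desk-scale fixture: geometry, incident fields, kernel and SVD of
## the 4-antenna / 2-frequency / 11x9x9 bundle, built once per test run.
.tiny <- new.env(parent = emptyenv())

tiny_bundle <- function() {
  if (!is.null(.tiny$svd)) return(as.list(.tiny))
  cfg <- make_fixture("tiny")
  mats <- material_library(cfg$materials)
  grid <- roi_grid(cfg$grid$extent_mm, cfg$grid$spacing_mm,
                   cfg$grid$origin_mm)
  arr <- array_geometry(cfg$array$n_antennas, cfg$array$spacing_mm,
                        background = mats$coupling_medium)
  phantom <- phantom_spec(cfg$phantom$outer_semi_axes_mm,
                          cfg$phantom$inner_semi_axes_mm,
                          cfg$phantom$center_mm,
                          cfg$phantom$shell_thickness_mm)
  cm <- mats$coupling_medium
  fields <- incident_field_set(arr, grid, cm, cfg$frequencies_hz)
  kernel <- build_kernel(fields, grid, cm)
  svd <- compute_svd(kernel)
  for (nm in c("cfg", "mats", "grid", "arr", "phantom", "cm", "fields",
               "kernel", "svd"))
    assign(nm, get(nm), envir = .tiny)
  as.list(.tiny)
}

## Deterministic pseudo-random complex vector/matrix helpers.
rcomplex <- function(n, seed = 1) {
  set.seed(seed)
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
}
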