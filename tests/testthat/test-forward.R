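test_that("dipole fields obey far-field decay and lossy attenuation", {
  vac <- dispersive_material("vacuumlike", "constant", eps_r = 1, sigma = 0)
  arr <- array_geometry(n_antennas = 2, spacing = 23,
                        check_spacing = FALSE)
  ## transverse observation points far from the source (r >> lambda)
  nodes <- rbind(c(0, 0, 10000), c(0, 0, 20000))  # mm
  g <- list(nodes = nodes, spacing = 3)
  E <- mwablate:::dipole_field(c(0, 0, 0), nodes, c(1, 0, 0), vac, 1e9)
  ratio <- Mod(E[1, 1]) / Mod(E[2, 1])
  expect_equal(ratio, 2, tolerance = 1e-3)

  cm <- material_library()$coupling_medium
  k <- wavenumber(cm, 1e9)
  expect_lt(Im(k), 0)
  Ec <- mwablate:::dipole_field(c(0, 0, 0), nodes, c(1, 0, 0), cm, 1e9)
  alpha <- -Im(k)
  expect_equal(Mod(Ec[1, 1]) / Mod(Ec[2, 1]),
               2 * exp(alpha * 10), tolerance = 1e-3)  # extra e^{-alpha r}
})

test_that("a centered dipole field is mirror-symmetric in x", {
  cm <- material_library()$coupling_medium
  nodes <- rbind(c(12, 5, 30), c(-12, 5, 30))
  E <- mwablate:::dipole_field(c(0, 0, 0), nodes, c(1, 0, 0), cm, 1e9)
  ## x-polarized dipole: |E| is even under x -> -x
  expect_equal(Mod(E[1, ]), Mod(E[2, ]), tolerance = 1e-12)
  expect_equal(E[1, 1], E[2, 1])        # Ex even
  expect_equal(E[1, 2], -E[2, 2])       # Ey odd (polarization parity)
})

test_that("incident fields are finite and source collisions are caught", {
  tb <- tiny_bundle()
  for (E in tb$fields$fields) expect_true(all(is.finite(Mod(E))))
  g0 <- roi_grid(c(6, 6, 6), 3, origin = c(-27, -3, -3))  # node at a tip
  expect_error(incident_field(tb$arr, 1, g0, tb$cm, 1e9), "geometry error")
})

test_that("Born data are linear in the contrast and reciprocal", {
  tb <- tiny_bundle()
  zero <- born_forward(tb$kernel, complex(tb$grid$n_nodes))
  expect_true(all(zero == 0))
  x <- rcomplex(tb$grid$n_nodes, seed = 42)
  d1 <- born_forward(tb$kernel, x)
  d3 <- born_forward(tb$kernel, 3 * x)
  expect_equal(d3, 3 * d1, tolerance = 1e-12)
  ## right singular vector maps to sigma * left singular vector
  sv <- tb$svd
  dm <- born_forward(tb$kernel, sv$v[, 3])
  expect_equal(as.vector(dm), sv$d[3] * sv$u[, 3], tolerance = 1e-8)
  ## reciprocity of the synthetic S-matrices
  S <- as_s_matrices(d1, n_antennas = tb$arr$n_antennas,
                     frequencies = tb$cfg$frequencies_hz)
  for (fi in seq_len(dim(S)[3]))
    expect_lt(max(Mod(S[, , fi] - t(S[, , fi]))) / max(Mod(S[, , fi])),
              1e-10)
})

test_that("data vector ordering round-trips losslessly", {
  arr <- array(rcomplex(8 * 8 * 5, seed = 7), dim = c(8, 8, 5))
  v <- as_data_vector(arr)
  expect_length(v, 320)
  expect_identical(as_s_matrices(v, n_antennas = 8), arr)
  ## frequency-major, then transmitter-major over receiver
  expect_identical(v[1], arr[1, 1, 1])
  expect_identical(v[2], arr[1, 2, 1])   # receiver q fastest
  expect_identical(v[9], arr[2, 1, 1])   # then transmitter p
  expect_identical(v[65], arr[1, 1, 2])  # then frequency
})

test_that("differential data subtract entrywise and check frequencies", {
  freqs <- c(800e6, 1200e6)
  a <- scattering_dataset(array(rcomplex(32, 1), dim = c(4, 4, 2)), freqs)
  b <- scattering_dataset(array(rcomplex(32, 2), dim = c(4, 4, 2)), freqs)
  expect_true(all(differential_data(a, a) == 0))
  d <- differential_data(b, a)
  expect_length(d, 32)
  expect_equal(as_s_matrices(d, 4), b$s - a$s)
  c2 <- scattering_dataset(a$s, c(800e6, 1300e6))
  expect_error(differential_data(a, c2), "frequency")
})

test_that("noise injection is calibrated, seeded and disable-able", {
  freqs <- c(800e6, 1200e6)
  ds <- scattering_dataset(array(rcomplex(32, 3), dim = c(4, 4, 2)), freqs)
  expect_identical(add_noise(ds, noise_spec(Inf)), ds)
  n1 <- add_noise(ds, noise_spec(45, seed = 5))
  n2 <- add_noise(ds, noise_spec(45, seed = 5))
  expect_identical(n1$s, n2$s)
  n3 <- add_noise(ds, noise_spec(45, seed = 6))
  expect_false(identical(n1$s, n3$s))

  ## empirical SNR near the specification
  snrs <- vapply(1:300, function(i) {
    ny <- add_noise(ds, noise_spec(45, seed = i))
    10 * log10(sum(Mod(ds$s)^2) / sum(Mod(ny$s - ds$s)^2))
  }, 0)
  expect_lt(abs(mean(snrs) - 45), 0.5)

  zero <- scattering_dataset(array(0i, dim = c(4, 4, 2)), freqs)
  expect_error(add_noise(zero, noise_spec(45)), "calibration error")
  ## but an external reference power rescues the empty acquisition
  nz <- add_noise(zero, noise_spec(45, seed = 1),
                  reference_power = c(1, 1))
  expect_gt(sum(Mod(nz$s)^2), 0)
})

test_that("refined-grid forward data reduce to the kernel product and
           converge", {
  tb <- tiny_bundle()
  gt <- ground_truth_contrast("s0", "b1", tb$grid, 1e9, tb$mats,
                              tb$phantom)
  coarse <- born_forward(tb$kernel, gt)
  r1 <- fine_grid_forward("s0", "b1", tb$arr, tb$grid, tb$cm,
                          tb$cfg$frequencies_hz, tb$mats, tb$phantom,
                          refinement = 1)
  expect_equal(as.vector(r1), as.vector(coarse), tolerance = 1e-10)
  r2 <- fine_grid_forward("s0", "b1", tb$arr, tb$grid, tb$cm,
                          tb$cfg$frequencies_hz, tb$mats, tb$phantom,
                          refinement = 2)
  rel <- sqrt(sum(Mod(r2 - coarse)^2) / sum(Mod(coarse)^2))
  expect_lt(rel, 0.2)
  r0 <- fine_grid_forward("s0", "s0", tb$arr, tb$grid, tb$cm,
                          tb$cfg$frequencies_hz, tb$mats, tb$phantom,
                          refinement = 2)
  expect_true(all(r0 == 0))
  expect_error(
    fine_grid_forward("s0", "b1", tb$arr, tb$grid, tb$cm,
                      tb$cfg$frequencies_hz, tb$mats, tb$phantom,
                      refinement = 4, node_cap = 1000),
    "memory guard")
})

test_that("Touchstone files round-trip the dataset", {
  tb <- tiny_bundle()
  gt <- ground_truth_contrast("s0", "c2", tb$grid, 1e9, tb$mats,
                              tb$phantom)
  v <- born_forward(tb$kernel, gt)
  ds <- scattering_dataset(as_s_matrices(v, tb$arr$n_antennas),
                           tb$cfg$frequencies_hz, "c2")
  path <- withr::local_tempfile(fileext = ".s4p")
  write_touchstone(ds, path)
  back <- read_touchstone(path, "c2")
  expect_equal(back$frequencies, ds$frequencies)
  expect_equal(back$s, ds$s, tolerance = 1e-10)
})

test_that("incident fields round-trip through the CSV exchange format", {
  cm <- material_library()$coupling_medium
  arr <- array_geometry(n_antennas = 2, spacing = 23)
  g <- roi_grid(c(6, 6, 6), 3, origin = c(-3, -3, 9))
  fl <- incident_field_set(arr, g, cm, c(800e6, 1200e6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(fl, path)
  fl2 <- read_field_csv(path, g, arr, cm)
  expect_equal(fl2$frequencies, fl$frequencies)
  for (i in 1:2) expect_equal(fl2$fields[[i]], fl$fields[[i]],
                              tolerance = 1e-6)
})
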