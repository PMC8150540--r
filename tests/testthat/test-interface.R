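test_that("fixtures encode the documented problem sizes", {
  tiny <- make_fixture("tiny")
  gt <- roi_grid(tiny$grid$extent_mm, tiny$grid$spacing_mm,
                 tiny$grid$origin_mm)
  expect_identical(gt$n_nodes, 891L)                     # 11 x 9 x 9
  expect_equal(length(tiny$frequencies_hz) *
                     tiny$array$n_antennas^2, 32)       # kernel rows
  full <- make_fixture("full")
  gp <- roi_grid(full$grid$extent_mm, full$grid$spacing_mm)
  expect_identical(gp$n_nodes, 50225L)
  expect_equal(length(full$frequencies_hz) *
                     full$array$n_antennas^2, 320)
  expect_equal(full$frequencies_hz,
               c(600e6, 800e6, 1000e6, 1200e6, 1400e6))
  expect_equal(full$noise$snr_db, 45)
})

test_that("configurations survive a YAML round trip", {
  cfg <- make_fixture("tiny", seed = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)
  back <- load_config(path)
  expect_equal(back$frequencies_hz, cfg$frequencies_hz)
  expect_equal(back$grid, cfg$grid)
  expect_equal(back$phantom, cfg$phantom)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$scenarios, cfg$scenarios)
  expect_equal(back$inversion$differential_noise_db, -15)
})

test_that("a two-scenario config yields exactly one differential pair", {
  cfg <- make_fixture("tiny")
  cfg$scenarios <- c("s0", "a1")
  ex <- suppressWarnings(run_experiment(cfg))
  expect_length(ex$pairs, 1L)
  expect_named(ex$pairs, "a1-s0")
  expect_true(is.finite(ex$pairs[["a1-s0"]]$nmse))
})

test_that("experiments are deterministic under the config seed", {
  cfg <- make_fixture("tiny")
  cfg$scenarios <- c("s0", "a1", "b1")
  e1 <- suppressWarnings(run_experiment(cfg))
  e2 <- suppressWarnings(run_experiment(cfg))
  expect_identical(e1$pairs[["b1-a1"]]$data, e2$pairs[["b1-a1"]]$data)
  expect_identical(e1$pairs[["a1-s0"]]$image$values,
                   e2$pairs[["a1-s0"]]$image$values)
  cfg2 <- cfg; cfg2$seed <- 99L
  e3 <- suppressWarnings(run_experiment(cfg2))
  expect_false(identical(e1$pairs[["a1-s0"]]$data,
                         e3$pairs[["a1-s0"]]$data))
  ## noise-free data identical across seeds: only the noise differs
  expect_equal(e1$nmse_table$pair, e3$nmse_table$pair)
})

test_that("the full desk-scale experiment produces ten evaluated pairs", {
  ex <- suppressWarnings(run_experiment(make_fixture("tiny")))
  expect_identical(nrow(ex$nmse_table), 10L)
  expect_true(all(is.finite(ex$nmse_table$nmse)))
  expect_true(all(ex$nmse_table$nmse >= 0))
  expect_gte(ex$nu, 1L)
  ## differential levels exist for every pair and frequency
  expect_identical(nrow(ex$differential_levels), 20L)
  ## signal levels: s0 is the quiet reference of the surrogate
  s0norm <- ex$levels$norm[ex$levels$scenario == "s0"]
  expect_true(all(s0norm == 0))
})

test_that("report bundles are written to disk", {
  dir <- withr::local_tempdir()
  cfg <- make_fixture("tiny")
  cfg$scenarios <- c("s0", "a1")
  cfg$output$dir <- dir
  ex <- suppressWarnings(run_experiment(cfg))
  expect_true(file.exists(file.path(dir, "spectrum.csv")))
  expect_true(file.exists(file.path(dir, "nmse.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(file.exists(file.path(dir, "image_a1-s0.nii.gz")))
  expect_true(file.exists(file.path(dir, "diff_a1-s0.s4p")))
  ## the exported differential data re-read to the in-memory values
  back <- read_touchstone(file.path(dir, "diff_a1-s0.s4p"))
  expect_equal(as.vector(as_data_vector(back$s)),
               as.vector(ex$pairs[["a1-s0"]]$data), tolerance = 1e-9)
  smry <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(smry$nu, ex$nu)
})

test_that("image cropping clamps and preserves values", {
  tb <- tiny_bundle()
  img <- ground_truth_contrast("s0", "a1", tb$grid, 1e9, tb$mats,
                               tb$phantom)
  expect_warning(cr <- crop_image(img, list(x = c(-100, 100),
                                            y = c(-12, 12),
                                            z = c(12, 24))),
                 "clamped")
  expect_identical(cr$grid$shape[3], 5L)  # z in {12,...,24}
  full <- array(img$values, dim = tb$grid$shape)
  expect_equal(array(cr$values, dim = cr$grid$shape),
               full[, , tb$grid$z >= 12 & tb$grid$z <= 24])
})

test_that("slice rendering returns a ggplot with the display crop", {
  tb <- tiny_bundle()
  img <- ground_truth_contrast("s0", "a2", tb$grid, 1e9, tb$mats,
                               tb$phantom)
  p <- render_slices(img, phantom = tb$phantom,
                     crop = list(x = c(-15, 15), y = c(-12, 12),
                                 z = c(9, 27)))
  expect_s3_class(p, "ggplot")
  expect_true(all(p$data$z >= 9 & p$data$z <= 27))
})

test_that("material map exports include coordinates and labels", {
  tb <- tiny_bundle()
  mm <- material_map("c2", tb$grid, tb$phantom)
  csv <- withr::local_tempfile(fileext = ".csv")
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  df <- export_material_map(mm, tb$grid, csv = csv, nifti = nii)
  expect_identical(nrow(df), tb$grid$n_nodes)
  expect_true(file.exists(csv) && file.exists(nii))
  vol <- RNifti::readNifti(nii)
  expect_identical(dim(vol), as.integer(tb$grid$shape))
})
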