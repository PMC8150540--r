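## A forged field set with constant, hand-picked field vectors lets the
## kernel assembly be checked against scalar arithmetic.
forged_fields <- function(grid, freqs, E_by_antenna) {
  p <- length(E_by_antenna)
  fields <- lapply(freqs, function(f) {
    E <- array(0i, dim = c(grid$n_nodes, 3, p))
    for (a in seq_len(p))
      for (cc in 1:3) E[, cc, a] <- E_by_antenna[[a]][cc]
    E
  })
  structure(list(fields = fields, frequencies = freqs, grid = grid,
                 array = NULL, background = NULL),
            class = "incident_field_set")
}

test_that("kernel entries match the scalar formula and are reciprocal", {
  g <- roi_grid(c(3, 3, 3), 3, origin = c(-1.5, -1.5, 10))
  cm <- material_library()$coupling_medium
  f <- 1e9
  E1 <- c(1 + 2i, 0.5 - 1i, 0.25i)
  E2 <- c(-0.5 + 1i, 2, 1 - 1i)
  K <- build_kernel(forged_fields(g, f, list(E1, E2)), g, cm)
  expect_identical(dim(K$matrix), c(4L, 8L))
  eps_cm <- evaluate_permittivity(cm, f)$eps_complex
  dv <- (3e-3)^3
  expected_12 <- -1i / (4 * 2 * pi * f * eps_cm) * sum(E1 * E2) * dv
  expect_equal(K$matrix[2, 1], expected_12, tolerance = 1e-12)
  expected_11 <- -1i / (4 * 2 * pi * f * eps_cm) * sum(E1 * E1) * dv
  expect_equal(K$matrix[1, 1], expected_11, tolerance = 1e-12)
  ## rows (p,q) and (q,p) identical; bilinear (not conjugated) product
  expect_identical(K$matrix[2, ], K$matrix[3, ])
  expect_false(isTRUE(all.equal(
    K$matrix[2, 1],
    -1i / (4 * 2 * pi * f * eps_cm) * sum(E1 * Conj(E2)) * dv)))
})

test_that("kernel row ordering matches the data-vector convention", {
  tb <- tiny_bundle()
  ri <- tb$kernel$row_index
  expect_identical(nrow(ri), 32L)
  expect_identical(ri$q[1:4], 1:4)                  # receiver fastest
  expect_identical(ri$p[c(1, 5)], c(1L, 2L))        # then transmitter
  expect_identical(ri$frequency[c(1, 17)], tb$cfg$frequencies_hz)
})

test_that("the SVD factors reconstruct the kernel", {
  tb <- tiny_bundle()
  sv <- tb$svd
  expect_true(all(diff(sv$d) <= 0))
  recon <- sv$u %*% (sv$d * t(Conj(sv$v)))
  rel <- sqrt(sum(Mod(tb$kernel$matrix - recon)^2) /
                sum(Mod(tb$kernel$matrix)^2))
  expect_lt(rel, 1e-8)
  ## orthonormal columns
  m <- min(8, sv$rank)
  gram <- Conj(t(sv$u[, 1:m])) %*% sv$u[, 1:m]
  expect_equal(gram, diag(1 + 0i, m), tolerance = 1e-10)
  ## homogeneity and a diagonal toy
  k2 <- tb$kernel; k2$matrix <- 2 * k2$matrix
  expect_equal(compute_svd(k2)$d, 2 * sv$d, tolerance = 1e-10)
  toy <- tb$kernel
  toy$matrix <- rbind(c(3, rep(0, 7)), c(0, 1, rep(0, 6))) + 0i
  expect_equal(compute_svd(toy)$d, c(3, 1))
})

test_that("SVD caching returns identical factors", {
  tb <- tiny_bundle()
  dir <- withr::local_tempdir()
  s1 <- compute_svd(tb$kernel, cache_dir = dir)
  expect_length(list.files(dir, pattern = "^svd-.*rds$"), 1L)
  s2 <- compute_svd(tb$kernel, cache_dir = dir)
  expect_identical(s1$d, s2$d)
  expect_identical(s1$v, s2$v)
})

test_that("slope-change detection finds constructed knees and applies the
           noise rule", {
  ## single knee at index 40, well above the -15 dB noise level
  s_db <- c(-0.1 * (0:39), -3.9 - 3 * (1:60))
  thr <- threshold_candidates(10^(s_db / 20))
  expect_identical(thr$candidates, 40L)
  expect_identical(thr$selected, 40L)
  expect_false(thr$fallback)

  ## flat spectrum: no knees, fallback to the noise crossing
  expect_warning(thr2 <- threshold_candidates(rep(1, 50)), "falling back")
  expect_length(thr2$candidates, 0)
  expect_identical(thr2$selected, 50L)
  expect_true(thr2$fallback)

  ## knees at 30 and 58; the curve crosses -15 dB just after 58, so the
  ## largest candidate still above the noise is selected
  s_db3 <- c(-0.01 * (0:29),
             -0.29 - 0.52 * (1:28),
             -14.85 - 5 * (1:40))
  thr3 <- threshold_candidates(10^(s_db3 / 20))
  expect_identical(thr3$candidates, c(30L, 58L))
  expect_identical(thr3$selected, 58L)

  expect_error(threshold_candidates(c(3, 1)), "at least 8")
})

test_that("TSVD solves single modes and equals the ideal projection on
           consistent data", {
  tb <- tiny_bundle()
  sv <- tb$svd
  ## data on the first left singular vector returns the first right one
  img1 <- tsvd_solve(sv, sv$d[1] * sv$u[, 1], nu = 1)
  expect_equal(img1$values, sv$v[, 1], tolerance = 1e-10)
  img5 <- tsvd_solve(sv, sv$d[1] * sv$u[, 1], nu = 5)
  expect_equal(img5$values, sv$v[, 1], tolerance = 1e-10)

  gt <- ground_truth_contrast("s0", "b2", tb$grid, 1e9, tb$mats,
                              tb$phantom)
  data <- born_forward(tb$kernel, gt)
  for (nu in c(1, 3, tb$svd$rank %/% 2, tb$svd$rank)) {
    rec <- tsvd_solve(sv, data, nu)
    ideal <- ideal_reconstruction(sv, gt, nu)
    rel <- sqrt(sum(Mod(rec$values - ideal$values)^2)) /
      sqrt(sum(Mod(ideal$values)^2))
    expect_lt(rel, 1e-6)
  }
  expect_error(tsvd_solve(sv, data, 0), "nu")
  expect_error(tsvd_solve(sv, data[-1], 1), "contract error")
})

test_that("ideal reconstruction is the right-subspace projection", {
  tb <- tiny_bundle()
  sv <- tb$svd
  gt3 <- contrast_image(sv$v[, 3], tb$grid)
  expect_equal(ideal_reconstruction(sv, gt3, 5)$values, sv$v[, 3],
               tolerance = 1e-10)
  ## a mode outside the retained subspace projects to (numerically) zero
  deep <- contrast_image(sv$v[, sv$rank], tb$grid)
  expect_lt(max(Mod(ideal_reconstruction(sv, deep, 2)$values)), 1e-8)
  ## contraction
  x <- contrast_image(rcomplex(tb$grid$n_nodes, 11), tb$grid)
  for (nu in c(2, 10, sv$rank))
    expect_lte(sqrt(sum(Mod(ideal_reconstruction(sv, x, nu)$values)^2)),
               sqrt(sum(Mod(x$values)^2)) * (1 + 1e-12))
})

test_that("noiseless reconstruction error is nonincreasing in nu", {
  tb <- tiny_bundle()
  sv <- tb$svd
  gt <- ground_truth_contrast("s0", "c1", tb$grid, 1e9, tb$mats,
                              tb$phantom)
  data <- born_forward(tb$kernel, gt)
  proj <- ideal_reconstruction(sv, gt, sv$rank)$values
  errs <- vapply(seq_len(sv$rank), function(nu)
    sqrt(sum(Mod(tsvd_solve(sv, data, nu)$values - proj)^2)), 0)
  expect_true(all(diff(errs) <= 1e-9 * errs[1]))
})
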