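# Convergence-index machinery: gradients, VCI, band responses, SVF and the
# volume enhancement map.

test_that("filter parameter invariants are enforced", {
  expect_s3_class(filter_params(), "svf_filter_params")
  expect_error(filter_params(d = 8, r_min = 3), "r_min")       # d/2 > r_min
  expect_error(filter_params(r_min = 10, r_max = 9), "r_min")
  expect_error(filter_params(rad = 10, d = 8, r_min = 4, r_max = 9), "r_max")
  expect_error(filter_params(L = 2), "L")
  expect_error(filter_params(T = 1), "T")
  expect_error(filter_params(d = 5), "even")
})

test_that("the direction grid has exactly 2 L^2 unit vectors", {
  for (L in c(4, 9, 20)) {
    dg <- direction_grid(L)
    expect_equal(nrow(dg), 2 * L^2)
    expect_lt(max(abs(sqrt(rowSums(dg^2)) - 1)), 1e-12)
  }
})

test_that("gradients are exact on flat and linear-ramp volumes", {
  flat <- as_volume(array(7, c(10, 10, 10)))
  g <- compute_gradient(flat, 1)
  expect_equal(max(abs(g$gx)), 0, tolerance = 1e-12)
  expect_equal(max(abs(g$gy)), 0, tolerance = 1e-12)

  ramp <- as_volume(array(rep(0:9, 100), dim = c(10, 10, 10)))  # I = x
  g0 <- compute_gradient(ramp, 0)
  interior <- g0$gx[3:8, 3:8, 3:8]
  expect_equal(as.vector(interior), rep(1, length(interior)), tolerance = 1e-12)
  expect_equal(max(abs(g0$gy[3:8, 3:8, 3:8])), 0, tolerance = 1e-12)
})

test_that("a radial blob has radially inward-pointing gradients", {
  sh <- c(21, 21, 21); ctr <- c(10, 10, 10)
  idx <- as.matrix(expand.grid(x = 0:20, y = 0:20, z = 0:20))
  rho <- sqrt(rowSums((idx - matrix(ctr, nrow(idx), 3, byrow = TRUE))^2))
  blob <- array(200 * exp(-rho^2 / 50), dim = sh)
  g <- compute_gradient(as_volume(blob), 1)
  pick <- idx[rho > 2 & rho < 8, , drop = FALSE]
  gv <- svftrace:::sample_gradient(g, pick)
  dirs <- matrix(ctr, nrow(pick), 3, byrow = TRUE) - pick
  cosang <- rowSums(gv * dirs) /
    (sqrt(rowSums(gv^2)) * sqrt(rowSums(dirs^2)))
  expect_gt(min(cosang), cos(5 * pi / 180))
})

test_that("vci matches its geometric definition at the three canonical angles", {
  # hand-built gradient field: constant gradient (1, 0, 0) everywhere
  gx <- array(1, c(9, 9, 9)); gy <- array(0, c(9, 9, 9)); gz <- gy
  grad <- structure(list(gx = gx, gy = gy, gz = gz, sigma_g = 0),
                    class = "gradient_field")
  P <- c(4, 4, 4)
  expect_equal(vci(grad, O = c(6, 4, 4), P = P), 1.0)    # g points at O
  expect_equal(vci(grad, O = c(4, 6, 4), P = P), 0.0)    # g perpendicular
  expect_equal(vci(grad, O = c(2, 4, 4), P = P), -1.0)   # g points away
  expect_error(vci(grad, O = P, P = P), "distinct")
  # flat gradient handling
  flatg <- compute_gradient(as_volume(array(5, c(9, 9, 9))), 0)
  expect_equal(vci(flatg, c(4, 4, 4), c(6, 4, 4)), 0)
})

test_that("band responses average VCIs and spot the tube wall", {
  gx <- array(-1, c(15, 15, 15)); gy <- array(0, c(15, 15, 15)); gz <- gy
  grad <- structure(list(gx = gx, gy = gy, gz = gz, sigma_g = 0),
                    class = "gradient_field")
  # all VCIs along +x from O are 1 (gradient points back toward O)
  expect_equal(band_response(grad, c(2, 7, 7), c(1, 0, 0), r = 4, d = 4), 1.0)
  expect_error(band_response(grad, c(2, 7, 7), c(1, 0, 0), r = 2, d = 4),
               "r - d/2")
  flatg <- compute_gradient(as_volume(array(0, c(15, 15, 15))), 0)
  expect_equal(band_response(flatg, c(7, 7, 7), c(0, 1, 0), 4, 4), 0)

  # on a hard tube, a band containing the wall beats one inside the flat core
  ph <- small_tube("hard", r = 6)
  g <- compute_gradient(ph$volume, 0)
  O <- c(16, 16, 16)
  wall <- band_response(g, O, c(0, 1, 0), r = 6, d = 2)
  core <- band_response(g, O, c(0, 1, 0), r = 3, d = 2)
  expect_gt(wall, core)
  expect_gt(wall, 0.9)
})

test_that("svf_at matches the naive triple-loop oracle", {
  vol <- random_volume(c(16, 16, 16), seed = 5)
  grad <- compute_gradient(vol, 1)
  fp <- filter_params(rad = 7, d = 2, L = 4, r_min = 2, r_max = 6, T = 0.5)
  set.seed(99)
  pts <- matrix(runif(15, 5, 10), ncol = 3)
  for (i in 1:5) {
    expect_equal(svf_at(grad, pts[i, ], fp), oracle_svf_at(grad, pts[i, ], fp),
                 tolerance = 1e-9)
  }
})

test_that("svf_volume equals pointwise svf_at and respects the mask floor", {
  ph <- make_tube(rbind(c(3, 8, 8), c(13, 8, 8)), 3, shape = c(16, 16, 16))
  fp <- filter_params(rad = 6, d = 2, L = 6, r_min = 2, r_max = 5, T = 0.5)
  grad <- compute_gradient(ph$volume, 1)
  resp <- svf_volume(ph$volume, fp, mask_floor = 0, grad = grad)
  expect_true(all(resp$data >= -1 & resp$data <= 1))
  set.seed(4)
  vox <- cbind(sample(0:15, 8, TRUE), sample(0:15, 8, TRUE),
               sample(0:15, 8, TRUE))
  for (i in seq_len(nrow(vox))) {
    expect_equal(resp$data[vox[i, 1] + 1, vox[i, 2] + 1, vox[i, 3] + 1],
                 svf_at(grad, vox[i, ], fp), tolerance = 1e-9)
  }
  masked <- svf_volume(ph$volume, fp, mask_floor = 10, grad = grad)
  expect_true(all(masked$data[ph$volume$data < 10] == -1))
})

test_that("svf is invariant under global intensity scaling", {
  ph <- small_tube()
  half <- as_volume(ph$volume$data / 2)
  fp <- light_params()
  g1 <- compute_gradient(ph$volume, 1)
  g2 <- compute_gradient(half, 1)
  O <- c(16, 16, 16)
  expect_equal(svf_at(g1, O, fp), svf_at(g2, O, fp), tolerance = 1e-9)
})

test_that("svf response at the tube axis beats a voxel outside the tube", {
  # reference-tube geometry scaled into 48^3 so the full support region fits
  ph <- make_tube(rbind(c(6, 24, 24), c(42, 24, 24)), 4, shape = c(48, 48, 48))
  grad <- compute_gradient(ph$volume)
  fp <- filter_params(rad = 20, d = 8, L = 8, r_min = 5, r_max = 16)
  on_axis <- svf_at(grad, c(24, 24, 24), fp)
  outside <- svf_at(grad, c(24, 38, 24), fp)    # 14 voxels off the axis
  expect_gt(on_axis, outside)
  expect_gt(on_axis, 0.5)
})

test_that("svf is equivariant under 90-degree rotations of a tube", {
  fp <- light_params()
  along_x <- make_tube(rbind(c(4, 16, 16), c(28, 16, 16)), 4,
                       shape = c(32, 32, 32))
  along_y <- make_tube(rbind(c(16, 4, 16), c(16, 28, 16)), 4,
                       shape = c(32, 32, 32))
  sx <- svf_at(compute_gradient(along_x$volume), c(16, 16, 16), fp)
  sy <- svf_at(compute_gradient(along_y$volume), c(16, 16, 16), fp)
  expect_equal(sx, sy, tolerance = 0.02)
})

test_that("enhance_volume reproduces the enhancement formula", {
  svf_vals <- c(0, 0, 0.5, -0.5, 1)
  I_vals <- c(255, 0, 100, 100, 200)
  vol <- as_volume(array(I_vals, dim = c(5, 1, 1)))
  resp <- structure(list(data = array(svf_vals, dim = c(5, 1, 1)),
                         params = filter_params(), mask_floor = 1),
                    class = "svf_response")
  out <- enhance_volume(vol, resp)
  expect_equal(out$data[1, 1, 1], 15 * sqrt(255))          # ~239.53
  expect_equal(out$data[2, 1, 1], 0)
  expect_equal(out$data[3, 1, 1], 15 * sqrt(150))          # ~183.71
  expect_equal(out$data[4, 1, 1], 15 * sqrt(50))
  expect_equal(out$data[5, 1, 1], 15 * sqrt(min(400, 255)))
  expect_true(all(out$data <= 15 * sqrt(255) + 1e-9))
})
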