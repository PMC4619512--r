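# Open-curve snake primitives: GVF field, internal operator, stretch force,
# deformation and initialization.

test_that("gvf is zero on flat volumes and reduces to the gradient at 0 iterations", {
  flat <- as_volume(array(10, c(12, 12, 12)))
  fl <- compute_gvf(flat, n_iters = 5)
  expect_equal(max(abs(fl$gx)), 0)
  expect_equal(max(abs(fl$gz)), 0)

  ph <- small_tube()
  f0 <- compute_gvf(ph$volume, n_iters = 0)
  g <- svftrace:::cpp_central_gradient(ph$volume$data / max(ph$volume$data))
  mag <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  nz <- mag > 0.01 * max(mag)    # above the normalization floor
  expect_lt(max(abs(f0$gx[nz] - g$gx[nz] / mag[nz])), 1e-12)
  expect_true(all(abs(f0$gx[mag < 1e-8]) == 0))
  expect_error(compute_gvf(ph$volume, mu = 0), "mu")
})

test_that("gvf flow at tube-wall voxels points toward the axis", {
  ph <- small_tube()
  flow <- compute_gvf(enhance_volume(ph$volume,
                                     svf_volume(ph$volume, light_params())))
  idx <- as.matrix(expand.grid(x = 10:22, y = 0:31, z = 0:31))
  rho <- sqrt((idx[, 2] - 16)^2 + (idx[, 3] - 16)^2)
  wall <- idx[rho > 2.5 & rho < 4.5, ]
  fv <- svftrace:::sample_flow(flow, wall)
  inward <- cbind(0, 16 - wall[, 2], 16 - wall[, 3])
  dots <- rowSums(fv * inward)
  expect_gt(mean(dots > 0), 0.95)
})

test_that("the internal operator annihilates straight lines and is PSD", {
  sp <- snake_params(alpha = 0.8, beta = 0.2, node_spacing = 1)
  for (n in c(3, 7, 20)) {
    A <- internal_matrix(n, sp, spacing = 1)
    line <- cbind(seq_len(n) * 2, seq_len(n) * -1 + 4, rep(3, n))
    expect_lt(max(abs(A %*% line)), 1e-10)
    ev <- eigen(A, only.values = TRUE)$values
    expect_true(all(Re(ev) >= -1e-10))
    expect_lt(max(abs(Im(ev))), 1e-10)
    expect_lt(max(abs(rowSums(A))), 1e-10)
  }
  # explicit 3x3 alpha-only stencil
  A3 <- internal_matrix(3, snake_params(alpha = 0.8, beta = 0),
                        spacing = 1)
  expect_equal(A3[2, ], c(-0.8, 1.6, -0.8))
  expect_equal(A3[1, ], c(0, 0, 0))
  expect_error(internal_matrix(2, sp), "3 nodes")
})

test_that("stretch magnitude follows the tubeness formula", {
  # lambda = (0, 0, 0): |sqrt(0)/(0 + 0.01) - 1| = 1
  expect_equal(svftrace:::stretch_magnitude(c(0, 0, 0)), 1)
  # a tube-like spectrum gives magnitude >> 1
  expect_gt(svftrace:::stretch_magnitude(c(-0.1, -12, -15)), 10)
  # comparable eigenvalues (blob / neurite terminal) give a small magnitude
  expect_lt(svftrace:::stretch_magnitude(c(-9.99, -10, -10)), 0.2)
})

test_that("stretch forces at the two ends of a straight curve are antiparallel", {
  ph <- small_tube()
  cv <- svftrace:::new_snake_curve(1L, cbind(seq(10, 22, by = 2), 16, 16))
  fh <- stretch_force(cv, "head", ph$volume)
  ft <- stretch_force(cv, "tail", ph$volume)
  expect_gt(attr(fh, "magnitude"), 1)   # mid-tube: strongly tube-like
  ch <- sum(fh * ft) / (sqrt(sum(fh^2)) * sqrt(sum(ft^2)))
  expect_lt(ch, -cos(pi / 180))         # within 1 degree of antiparallel
  # degenerate tangent errors out
  bad <- svftrace:::new_snake_curve(2L, rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_error(stretch_force(bad, "head", ph$volume), "tangent")
})

test_that("deformation is a fixed point on the axis and contracts toward it", {
  ph <- small_tube()
  resp <- svf_volume(ph$volume, light_params())
  flow <- compute_gvf(enhance_volume(ph$volume, resp))
  sp <- snake_params(t_max = 10)
  on_axis <- svftrace:::new_snake_curve(1L, cbind(seq(10, 22, 1.5), 16, 16))
  moved <- deform_curve(on_axis, flow, ph$volume, sp, stretch = FALSE)
  interior <- moved$nodes[2:(nrow(moved$nodes) - 1), ]
  expect_lt(max(abs(interior[, 2] - 16)), 0.1)
  expect_lt(max(abs(interior[, 3] - 16)), 0.1)

  offset <- svftrace:::new_snake_curve(2L, cbind(seq(13, 19, 1.5), 18, 16))
  d0 <- mean(sqrt((offset$nodes[, 2] - 16)^2 + (offset$nodes[, 3] - 16)^2))
  prev <- offset; dists <- d0
  for (k in 1:3) {
    prev <- deform_curve(prev, flow, ph$volume, snake_params(t_max = 3),
                         stretch = FALSE)
    dists <- c(dists, mean(sqrt((prev$nodes[, 2] - 16)^2 +
                                (prev$nodes[, 3] - 16)^2)))
  }
  expect_true(all(diff(dists) < 0.05))
  expect_lt(dists[length(dists)], d0 / 2)
})

test_that("large gamma freezes the curve (explicit small-step limit)", {
  ph <- small_tube()
  flow <- compute_gvf(ph$volume, n_iters = 5)
  start <- cbind(seq(13, 19, 1.5), 18, 16)
  cv <- svftrace:::new_snake_curve(1L, start)
  big <- deform_curve(cv, flow, ph$volume,
                      snake_params(gamma = 1e6, t_max = 1, node_spacing = 1.5),
                      stretch = FALSE)
  expect_lt(max(abs(big$nodes - start)), 1e-3)
})

test_that("init_curve builds a 3-node curve along the principal direction", {
  ph <- small_tube()
  seed <- data.frame(x = 16, y = 16, z = 16, response = 0.9, label = 0L)
  cv <- init_curve(seed, ph$volume, id = 7L)
  expect_equal(nrow(cv$nodes), 3)
  expect_equal(cv$id, 7L)
  tang <- cv$nodes[3, ] - cv$nodes[1, ]
  tang <- tang / sqrt(sum(tang^2))
  expect_gt(abs(tang[1]), cos(5 * pi / 180))   # collinear with the x axis
  cv2 <- init_curve(seed, ph$volume, id = 8L)
  expect_false(cv2$id == cv$id)
  labeled <- transform(seed, label = 3L)
  expect_error(init_curve(labeled, ph$volume, id = 9L), "labeled")
})

test_that("snake parameter guards reject invalid settings", {
  expect_error(snake_params(alpha = 0), "alpha")
  expect_error(snake_params(gamma = -1), "alpha|gamma")
  expect_error(snake_params(extend_step = 4), "extend_step")
  expect_error(snake_params(t_max = 0), "t_max")
  expect_error(snake_params(backoff_factor = 0), "backoff_factor")
})
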