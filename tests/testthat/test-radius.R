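# Cross-section radius estimation with the sliding band filter.

radius_fp <- function() filter_params(rad = 20, d = 4, L = 20, r_min = 2,
                                      r_max = 12, T = 0.7)

test_that("local frames are orthonormal and right-handed", {
  curve <- cbind(seq(0, 10), 0, 0)
  fr <- local_frame(curve, 5)
  expect_equal(fr$v1, c(1, 0, 0))
  expect_lt(abs(sum(fr$v1 * fr$v2)), 1e-10)
  expect_lt(abs(sum(fr$v2 * fr$v3)), 1e-10)
  # property sweep over random tangents
  set.seed(17)
  for (k in 1:1000) {
    t3 <- rnorm(3)
    nodes <- rbind(c(5, 5, 5) - t3, c(5, 5, 5), c(5, 5, 5) + t3)
    fr <- local_frame(nodes, 2)
    M <- cbind(fr$v1, fr$v2, fr$v3)
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-10)
    cross <- c(fr$v2[2] * fr$v3[3] - fr$v2[3] * fr$v3[2],
               fr$v2[3] * fr$v3[1] - fr$v2[1] * fr$v3[3],
               fr$v2[1] * fr$v3[2] - fr$v2[2] * fr$v3[1])
    expect_lt(max(abs(cross - fr$v1)), 1e-9)
  }
  expect_error(local_frame(curve, 99), "out of range")
})

test_that("reversing the curve flips the tangent but not the contour set", {
  ph <- make_tube(rbind(c(8, 32, 32), c(56, 32, 32)), 5, falloff = "hard")
  grad <- compute_gradient(ph$volume, 0)
  fwd <- local_frame(cbind(seq(20, 44, 2), 32, 32), 7)
  rev_ <- local_frame(cbind(seq(44, 20, -2), 32, 32), 7)
  expect_equal(fwd$v1, -rev_$v1)
  c1 <- sbf_boundary(grad, c(32, 32, 32), fwd, 16, radius_fp())
  c2 <- sbf_boundary(grad, c(32, 32, 32), rev_, 16, radius_fp())
  key <- function(ct) paste(round(sort(ct$boundary[, 2] * 100 +
                                       ct$boundary[, 3])), collapse = ",")
  expect_equal(key(c1), key(c2))
})

test_that("sbf recovers circular radii within a voxel (hard-edged tubes)", {
  for (r in c(3, 5, 8)) {
    ph <- make_tube(rbind(c(8, 32, 32), c(56, 32, 32)), r, falloff = "hard")
    grad <- compute_gradient(ph$volume, 0)
    fr <- local_frame(cbind(seq(20, 44, 2), 32, 32), 7)
    ct <- sbf_boundary(grad, c(32, 32, 32), fr, 16, radius_fp())
    expect_lte(abs(ct$mean_radius - r), 1)
    expect_true(all(abs(ct$radii - r) <= radius_fp()$d / 2 + 1))
    # boundary points decompose as center + r_k * (cos, sin) in the frame
    theta <- 2 * pi * (0:15) / 16
    recon <- matrix(ct$center, 16, 3, byrow = TRUE) +
      ct$radii * (outer(cos(theta), fr$v2) + outer(sin(theta), fr$v3))
    expect_lt(max(abs(recon - ct$boundary)), 1e-9)
  }
})

test_that("elliptical cross-sections produce anisotropic radii", {
  el <- make_elliptic_tube(c(8, 32, 32), c(56, 32, 32), c(4, 8),
                           falloff = "hard")
  grad <- compute_gradient(el$volume, 0)
  fr <- local_frame(cbind(seq(20, 44, 2), 32, 32), 7)
  ct <- sbf_boundary(grad, c(32, 32, 32), fr, 16, radius_fp())
  expect_gte(max(ct$radii) / min(ct$radii), 1.5)
})

test_that("flat volumes fall back to the documented degenerate radius", {
  flat <- as_volume(array(0, c(32, 32, 32)))
  grad <- compute_gradient(flat, 0)
  fr <- local_frame(cbind(seq(10, 20, 2), 16, 16), 3)
  ct <- sbf_boundary(grad, c(16, 16, 16), fr, 8, radius_fp())
  expect_true(all(ct$radii == radius_fp()$r_min + 1))
  expect_true(all(ct$responses == 0))
})

test_that("sbf ray argmax agrees exactly with the exhaustive R oracle", {
  vol <- random_volume(c(24, 24, 24), seed = 31)
  grad <- compute_gradient(vol, 1)
  fp <- filter_params(rad = 10, d = 2, L = 8, r_min = 2, r_max = 8, T = 0.5)
  fr <- local_frame(cbind(seq(8, 16, 2), 12, 12), 3)
  n <- 8
  ct <- sbf_boundary(grad, c(12, 12, 12), fr, n, fp)
  theta <- 2 * pi * (0:(n - 1)) / n
  for (k in seq_len(n)) {
    u <- cos(theta[k]) * fr$v2 + sin(theta[k]) * fr$v3
    ref <- oracle_sbf_ray(grad, c(12, 12, 12), u, fp)
    expect_identical(ct$radii[k], ref[1])
    expect_equal(ct$responses[k], ref[2], tolerance = 1e-9)
  }
})

test_that("refining n improves the polygonal area estimate on circles", {
  ph <- make_tube(rbind(c(8, 32, 32), c(56, 32, 32)), 6, falloff = "hard")
  grad <- compute_gradient(ph$volume, 0)
  fr <- local_frame(cbind(seq(20, 44, 2), 32, 32), 7)
  poly_area <- function(n) {
    ct <- sbf_boundary(grad, c(32, 32, 32), fr, n, radius_fp())
    # area of the polygon with vertices r_k at angles theta_k
    th <- 2 * pi * (seq_len(n) - 1) / n
    r <- ct$radii
    sum(0.5 * r * c(r[-1], r[1]) * sin(diff(c(th, 2 * pi))))
  }
  true_area <- pi * 6^2
  errs <- abs(vapply(c(8, 16, 32), poly_area, numeric(1)) - true_area)
  # refinement improves the estimate overall; strict per-step monotonicity is
  # broken by the integer quantization of the per-ray radii
  expect_lte(errs[3], errs[1] + 1e-9)
  expect_lt(errs[3] / true_area, 0.25)
})

test_that("contours cover every node except near branch points", {
  ph <- make_tube(rbind(c(8, 32, 32), c(56, 32, 32)), 4, falloff = "hard")
  grad <- compute_gradient(ph$volume, 0)
  nodes <- cbind(seq(12, 52, 2), 32, 32)
  cv <- svftrace:::new_snake_curve(1L, nodes)
  tr <- svftrace:::new_neuron_trace(list(cv))
  out <- contours_for_trace(tr, grad, n = 16, radius_fp(), backoff_D = 0)
  expect_equal(length(out$contours), nrow(nodes))
  radii <- vapply(out$contours, function(ct) ct$mean_radius, numeric(1))
  expect_lt(sd(radii), 1)
  expect_equal(out$trace$curves[[1]]$mean_radius, mean(radii))

  # with a branch point at the curve middle, nearby nodes are skipped
  tr$branch_points <- data.frame(x = 32, y = 32, z = 32,
                                 parent = 1L, child = 2L)
  out2 <- contours_for_trace(tr, grad, n = 16, radius_fp(), backoff_D = 6)
  centers <- t(vapply(out2$contours, function(ct) ct$center, numeric(3)))
  expect_gt(min(sqrt(colSums((t(centers) - c(32, 32, 32))^2))), 6 - 2)
  expect_lt(length(out2$contours), length(out$contours))
})
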