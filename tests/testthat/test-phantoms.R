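# Synthetic phantom generators: geometry, intensity profiles, noise and
# attenuation models.

test_that("tube profile peaks on the centerline and vanishes at the wall", {
  ph <- small_tube()   # straight x-tube, r = 4, peak 200, cosine
  d <- ph$volume$data
  expect_equal(d[17, 17, 17], 200, tolerance = 0.05 * 200)
  # at distance exactly r from the axis the cosine profile has fallen to ~0
  # (box supersampling averages a few interior subsamples into the voxel,
  # leaving a residual close to one 8-bit level)
  expect_lte(d[17, 17 + 4, 17], 1.5)
  # monotone non-increasing with distance from the axis
  profile <- d[17, 17:24, 17]
  expect_true(all(diff(profile) <= 1e-6))
})

test_that("hard-profile tube foreground matches the analytic cylinder volume", {
  ph <- make_tube(rbind(c(4, 16, 16), c(28, 16, 16)), 5, falloff = "hard",
                  shape = c(32, 32, 32))
  # count a mid-tube slab (x in [10, 22]) to stay clear of the rounded caps
  fg <- sum(ph$volume$data[11:23, , ] > 100)
  analytic <- pi * 5^2 * 13
  expect_lt(abs(fg - analytic) / analytic, 0.10)
})

test_that("a linearly growing radius widens the half-max profile monotonically", {
  ph <- make_tube(rbind(c(6, 24, 24), c(42, 24, 24)),
                  radius = function(s) 3 + 5 * s / 36,
                  shape = c(48, 48, 48))
  halfmax_width <- function(x) {
    prof <- ph$volume$data[x + 1, , 25]
    sum(prof > 100)
  }
  w <- vapply(c(10, 18, 26, 34), halfmax_width, numeric(1))
  expect_true(all(diff(w) >= 0))
  expect_gt(w[4], w[1])
  # brute-force check against the distance transform of the centerline
  dmax <- dist_to_centerline(which(ph$volume$data > 100, arr.ind = TRUE) - 1,
                             ph$centerline)
  expect_lte(max(dmax), 8 + 1)
})

test_that("helix centerline has the analytic arclength and stays on the ridge", {
  ph <- make_helix(helix_radius = 18, pitch = 20, turns = 2, tube_radius = 4)
  analytic <- 2 * 2 * pi * sqrt(18^2 + (20 / (2 * pi))^2)
  expect_equal(polyline_length(ph$centerline), analytic, tolerance = 0.01)
  # every centerline voxel outshines anything a tube radius away
  idx <- round(ph$centerline[seq(1, nrow(ph$centerline), by = 25), ]) + 1
  on_axis <- min(apply(idx, 1, function(p) ph$volume$data[p[1], p[2], p[3]]))
  far <- dist_to_centerline(which(ph$volume$data > 0, arr.ind = TRUE) - 1,
                            ph$centerline)
  outside_max <- max(c(0, ph$volume$data[ph$volume$data > 0][far >= 4]))
  expect_gt(on_axis, outside_max)
})

test_that("degenerate phantom requests are rejected", {
  expect_error(make_helix(turns = 0), "turns")
  expect_error(make_helix(helix_radius = 40), "fit")
  expect_error(make_tube(rbind(c(-5, 16, 16), c(20, 16, 16)), 4,
                         shape = c(32, 32, 32)), "bounds")
  expect_error(make_tube(rbind(c(4, 16, 16), c(28, 16, 16)), 1,
                         shape = c(32, 32, 32)), ">= 2")
  expect_error(make_y_branch(branch_angle = 180), "180")
  expect_error(make_y_branch(branch_angle = 0), "180")
  expect_error(make_y_branch(radii = c(1, 4, 4)), ">= 2")
})

test_that("the Y-branch phantom has one junction and additive limb lengths", {
  yb <- make_y_branch()
  expect_equal(nrow(yb$branch_points), 1)
  total <- sum(vapply(yb$gold, polyline_length, numeric(1)))
  analytic <- sum(vapply(yb$gold, function(g) {
    sqrt(sum((g[nrow(g), ] - g[1, ])^2))   # straight limbs
  }, numeric(1)))
  expect_equal(total, analytic, tolerance = 0.02)
})

test_that("attenuation scales intensities linearly", {
  vol <- as_volume(array(100, c(8, 8, 8)))
  expect_equal(attenuate_signal(vol, 0)$data, vol$data)
  expect_equal(unique(as.vector(attenuate_signal(vol, 0.4)$data)), 60)
  tot <- vapply(c(0.1, 0.2, 0.3, 0.4),
                function(f) sum(attenuate_signal(vol, f)$data), numeric(1))
  expect_true(all(diff(tot) < 0))
  expect_error(attenuate_signal(vol, 1), "fraction")
  expect_error(attenuate_signal(vol, -0.1), "fraction")
})

test_that("gaussian noise follows the stated unit-scale model and is reproducible", {
  vol <- as_volume(array(128, c(100, 100, 100)))
  expect_identical(add_gaussian_noise(vol, 0)$data, vol$data)
  noisy <- add_gaussian_noise(vol, 0.01, seed = 11)
  # sd should be sqrt(0.01) * 255 = 25.5 on the 8-bit scale (n = 1e6)
  expect_equal(sd(noisy$data - 128), 25.5, tolerance = 0.02)
  again <- add_gaussian_noise(vol, 0.01, seed = 11)
  expect_identical(noisy$data, again$data)
  other <- add_gaussian_noise(vol, 0.01, seed = 12)
  expect_false(identical(noisy$data, other$data))
  expect_error(add_gaussian_noise(vol, -1), "variance")
  expect_true(all(add_gaussian_noise(vol, 0.5, seed = 1)$data >= 0))
})

test_that("noiseless phantom centerlines sit on local intensity ridges", {
  # ground-truth validation: each centerline sample is within a voxel of the
  # local maximum of the intensity in its cross-sectional neighbourhood
  for (ph in list(small_tube(), make_helix(helix_radius = 10, pitch = 14,
                                           turns = 1, tube_radius = 3,
                                           shape = c(48, 48, 48)))) {
    samples <- ph$centerline[seq(1, nrow(ph$centerline), by = 40), ,
                             drop = FALSE]
    for (i in seq_len(nrow(samples))) {
      p <- samples[i, ]
      win <- expand.grid(x = -2:2, y = -2:2, z = -2:2)
      vals <- svftrace:::cpp_sample_trilinear(
        ph$volume$data, as.matrix(sweep(win, 2, p, "+")))
      center_val <- svftrace:::cpp_sample_trilinear(ph$volume$data,
                                                    matrix(p, 1, 3))
      best <- which.max(vals)
      offset <- sqrt(sum(as.numeric(win[best, ])^2))
      expect_true(center_val >= max(vals) - 1e-9 || offset < 2)
    }
  }
})
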