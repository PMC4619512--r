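# Shared fixtures and independent pure-R oracles for the test suite.
# The oracles deliberately re-derive each quantity with naive enumeration,
# separately from the package's optimized C++ paths.

# ---- small fixtures (built in code, cached per session) --------------------

fixture_env <- new.env(parent = emptyenv())

with_fixture <- function(name, maker) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- maker()
  fixture_env[[name]]
}

small_tube <- function(falloff = "cosine", r = 4) {
  with_fixture(paste0("tube_", falloff, "_", r), function() {
    make_tube(rbind(c(4, 16, 16), c(28, 16, 16)), r, peak_intensity = 200,
              falloff = falloff, shape = c(32, 32, 32))
  })
}

light_params <- function() filter_params(rad = 8, d = 4, L = 8, r_min = 3,
                                         r_max = 6, T = 0.5)

# deterministic random volume in [0, 255]
random_volume <- function(shape = c(16, 16, 16), seed = 42) {
  set.seed(seed)
  as_volume(array(runif(prod(shape), 0, 255), dim = shape))
}

# ---- oracles ---------------------------------------------------------------

# trilinear interpolation, plain R, zero padding
oracle_trilinear <- function(a, p) {
  d <- dim(a)
  at <- function(x, y, z) {
    if (x < 0 || y < 0 || z < 0 || x >= d[1] || y >= d[2] || z >= d[3]) return(0)
    a[x + 1, y + 1, z + 1]
  }
  x0 <- floor(p[1]); y0 <- floor(p[2]); z0 <- floor(p[3])
  fx <- p[1] - x0; fy <- p[2] - y0; fz <- p[3] - z0
  acc <- 0
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx) fx else 1 - fx) * (if (cy) fy else 1 - fy) *
         (if (cz) fz else 1 - fz)
    acc <- acc + w * at(x0 + cx, y0 + cy, z0 + cz)
  }
  acc
}

oracle_vci <- function(grad, O, P) {
  g <- c(oracle_trilinear(grad$gx, P), oracle_trilinear(grad$gy, P),
         oracle_trilinear(grad$gz, P))
  ng <- sqrt(sum(g^2))
  if (ng < 1e-6) return(0)
  po <- O - P
  sum(g * po) / (ng * sqrt(sum(po^2)))
}

oracle_band <- function(grad, O, u, r, d) {
  mean(vapply(seq(r - d / 2, r + d / 2), function(rho) {
    oracle_vci(grad, O, O + rho * u)
  }, numeric(1)))
}

# naive triple-loop SVF: directions x band centers x samples
oracle_svf_at <- function(grad, O, params) {
  dirs <- direction_grid(params$L)
  total <- 0
  for (m in seq_len(nrow(dirs))) {
    best <- -2
    for (r in (params$r_min + 1):(params$r_max - 1)) {
      br <- oracle_band(grad, O, dirs[m, ], r, params$d)
      if (br > best) best <- br
    }
    total <- total + best
  }
  total / nrow(dirs)
}

# exhaustive sliding-band radius scan along one ray (ties -> smaller r)
oracle_sbf_ray <- function(grad, center, u, params) {
  best <- -2; bestr <- params$r_min + 1
  for (r in (params$r_min + 1):(params$r_max - 1)) {
    br <- oracle_band(grad, center, u, r, params$d)
    if (br > best + 1e-15) { best <- br; bestr <- r }
  }
  c(bestr, best)
}

# all-pairs brute-force nearest-neighbour distances
oracle_nn_dist <- function(query, ref) {
  apply(query, 1, function(q) {
    min(sqrt(colSums((t(ref) - q)^2)))
  })
}

# distance from points to a dense polyline sampling (used as ground truth)
dist_to_centerline <- function(pts, centerline, step = 0.25) {
  dense <- resample_polyline(centerline, step)
  svftrace:::cpp_nn_dist(as_matrix3(pts), dense)
}

as_matrix3 <- function(pts) {
  if (is.data.frame(pts)) as.matrix(pts[, c("x", "y", "z")]) else as.matrix(pts)
}

# minimal independent SWC parser (reference reader for export tests)
reference_swc_reader <- function(path) {
  lines <- grep("^\\s*#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  vals <- lapply(strsplit(trimws(lines), "[ \t]+"), as.numeric)
  stopifnot(all(lengths(vals) == 7))
  m <- do.call(rbind, vals)
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  as.data.frame(m)
}
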