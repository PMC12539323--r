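# Boundary-point extraction, family fitting, derivative thresholds.

test_that("boundary percentiles match the closed form and brute force", {
  # constant response: every boundary point equals it
  pts <- extract_boundary_points(runif(5000), rep(7, 5000), n_bins = 20,
                                 min_count = 10)
  expect_true(all(pts$boundary_y == 7))
  # a bin holding 1..1000: 99.9th percentile = 999.001 by interpolation
  q <- quantile(1:1000, 0.999, type = 7)
  expect_equal(unname(q), 999.001)
  expect_equal(unname(q), brute_percentile(1:1000, 0.999))
  # implementation vs brute force on random bins
  set.seed(3)
  xx <- runif(1000); yy <- rnorm(1000)
  pts2 <- extract_boundary_points(xx, yy, n_bins = 10, q = 99.9, min_count = 5)
  edges <- attr(pts2, "bin_edges")
  bins <- cut(xx, edges, labels = FALSE, include.lowest = TRUE)
  for (r in seq_len(nrow(pts2))) {
    b <- which(abs((edges[-1] + edges[-11]) / 2 - pts2$boundary_x[r]) < 1e-12)
    expect_equal(pts2$boundary_y[r], brute_percentile(yy[bins == b], 0.999),
                 tolerance = 1e-12)
  }
})

test_that("boundary dominance and scale equivariance hold", {
  # ~300 points per bin: the 99.9th percentile leaves at most one point
  # above it, so the below-boundary fraction is at least (n-1)/n > 99.5%
  d <- simulate_constraint_scatter(3e4, apex = 0.4, seed = 77)
  pts <- extract_boundary_points(d$x, d$y)
  edges <- attr(pts, "bin_edges")
  bins <- cut(d$x, edges, labels = FALSE, include.lowest = TRUE)
  frac_below <- vapply(seq_len(nrow(pts)), function(r) {
    b <- which.min(abs((edges[-1] + edges[-length(edges)]) / 2 - pts$boundary_x[r]))
    mean(d$y[bins == b] <= pts$boundary_y[r])
  }, 0)
  expect_true(all(frac_below >= 0.995))
  expect_true(all(pts$boundary_y >= vapply(seq_len(nrow(pts)), function(r) {
    b <- which.min(abs((edges[-1] + edges[-length(edges)]) / 2 - pts$boundary_x[r]))
    median(d$y[bins == b])
  }, 0)))
  # affine rescale of y rescales boundary_y and threshold_y, not threshold_x
  fit1 <- fit_constraint_line(pts)
  pts2 <- pts; pts2$boundary_y <- 3 * pts$boundary_y + 5
  fit2 <- fit_constraint_line(pts2)
  expect_equal(fit2$threshold_x, fit1$threshold_x, tolerance = 1e-6)
  expect_equal(fit2$threshold_y, 3 * fit1$threshold_y + 5, tolerance = 1e-6)
  # too few qualifying bins is a structured error
  expect_error(extract_boundary_points(runif(30), runif(30), min_count = 10),
               class = "esd_data_error")
})

test_that("exact-fit limits recover each family with R2 = 1", {
  x <- seq(-2, 2, length.out = 40)
  # parabola with apex 0.8
  pq <- data.frame(boundary_x = x, boundary_y = -(x - 0.8)^2 + 2)
  f1 <- fit_constraint_line(pq)
  expect_equal(f1$family, "hump_quadratic")
  expect_equal(f1$r2, 1, tolerance = 1e-12)
  expect_equal(f1$threshold_x, 0.8, tolerance = 1e-8)
  expect_equal(f1$threshold_y, 2, tolerance = 1e-8)
  expect_equal(f1$flag, "ok")
  # cubic with one interior maximum on the range
  pc <- data.frame(boundary_x = x, boundary_y = x^3 - 2 * x)
  f2 <- fit_constraint_line(pc,
                            families = c("hump_quadratic", "convex_wave_cubic"))
  expect_equal(f2$family, "convex_wave_cubic")
  expect_equal(f2$r2, 1, tolerance = 1e-12)
  expect_equal(f2$threshold_x, -sqrt(2 / 3), tolerance = 1e-8)
  # monotone cubic: no interior maximum, flagged at the right endpoint
  pm <- data.frame(boundary_x = x, boundary_y = x^3 + 3 * x)
  f3 <- fit_constraint_line(pm,
                            families = c("hump_quadratic", "convex_wave_cubic"))
  expect_equal(f3$flag, "boundary_max")
  expect_equal(f3$threshold_x, 2)
  # gaussian boundary: gaussian family wins with the apex at its mean
  pg <- data.frame(boundary_x = x,
                   boundary_y = 0.3 + 1.7 * exp(-(x - 0.5)^2 / (2 * 0.6^2)))
  f4 <- fit_constraint_line(pg)
  expect_equal(f4$family, "hump_gaussian")
  expect_equal(f4$threshold_x, 0.5, tolerance = 1e-6)
  expect_error(fit_constraint_line(pq[1:4, ]), class = "esd_data_error")
})

test_that("noisy parabolic boundaries select the quadratic family reliably", {
  set.seed(55)
  wins <- 0
  for (i in 1:40) {
    x <- seq(-2, 2, length.out = 60)
    y <- -(x - 0.3)^2 + 2 + rnorm(60, 0, 0.02 * 4)  # SD = 2% of x-range
    fit <- fit_constraint_line(data.frame(boundary_x = x, boundary_y = y))
    wins <- wins + (fit$family == "hump_quadratic")
  }
  expect_gte(wins / 40, 0.9)
})

test_that("planted apices are recovered from full scatters", {
  errs <- vapply(1:20, function(i) {
    apex <- c(-0.3, 0.5, 0.81)[(i %% 3) + 1]
    d <- simulate_constraint_scatter(1e4, apex, height = 1, kappa = 0.15,
                                     noise_sd = 0.02, seed = 500 + i)
    pts <- extract_boundary_points(d$x, d$y)
    fit <- fit_constraint_line(pts)
    abs(fit$threshold_x - apex)
  }, 0)
  expect_true(all(errs <= 0.1))
})

test_that("per-land-use analysis recovers distinct planted apices in order", {
  sh <- shared_landscape()
  fits <- constraint_analysis_by_landuse(sh$ls, sh$es)
  ok <- fits[!fits$skipped, ]
  expect_gte(nrow(ok), 12)
  # forest WR and SC apices (0.81, 0.96) sit far above cropland's (0.30, 0.25)
  for (esn in c("wr", "sc")) {
    f_for <- ok[ok$es == esn & ok$land_use == "forest", ]
    f_crp <- ok[ok$es == esn & ok$land_use == "cropland", ]
    planted_forest <- sh$cfg$boundary_spec[
      sh$cfg$boundary_spec$es == esn &
        sh$cfg$boundary_spec$land_use == "forest", "apex"]
    expect_gt(f_for$threshold_x, f_crp$threshold_x)
    expect_lt(abs(f_for$threshold_x - planted_forest), 0.3)
  }
  # a stratum with constant SPEI cannot support boundary extraction
  ls2 <- sh$ls
  ls2$dynamic <- lapply(ls2$dynamic, function(a) a)
  ls2$dynamic$SPEI[] <- 0.1
  fits2 <- constraint_analysis_by_landuse(ls2, sh$es)
  expect_true(all(fits2$skipped))
})
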