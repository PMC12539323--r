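# Service formula oracles, invariants and the scalar reference comparison.

as_m <- function(x) matrix(x, 1, 1)

test_that("water retention matches hand-computed cases", {
  # all attenuation terms saturate at 1
  expect_equal(compute_water_retention(as_m(200), as_m(4), as_m(350), as_m(800))[1, 1],
               800)
  # 0.5 * 0.5 * 0.5 * 400
  expect_equal(compute_water_retention(as_m(498), as_m(5 / 3), as_m(150), as_m(400))[1, 1],
               50, tolerance = 1e-12)
  expect_equal(compute_water_retention(as_m(498), as_m(5 / 3), as_m(150), as_m(0))[1, 1],
               0)
  expect_error(compute_water_retention(as_m(0), as_m(1), as_m(1), as_m(1)),
               class = "esd_domain_error")
})

test_that("soil conservation follows the printed (1 - P*C) form", {
  expect_equal(compute_soil_conservation(as_m(100), as_m(0.5), as_m(1.2),
                                         as_m(2), as_m(0.4), as_m(0.5))[1, 1],
               96, tolerance = 1e-12)
  # no-practice / no-cover limits and zero erosivity
  expect_equal(compute_soil_conservation(as_m(100), as_m(0.5), as_m(1.2),
                                         as_m(2), as_m(0), as_m(0.5))[1, 1],
               100 * 0.5 * 1.2 * 2)
  expect_equal(compute_soil_conservation(as_m(0), as_m(0.5), as_m(1.2),
                                         as_m(2), as_m(0.4), as_m(0.5))[1, 1], 0)
  # textbook variant
  expect_equal(compute_soil_conservation(as_m(100), as_m(0.5), as_m(1.2),
                                         as_m(2), as_m(0.4), as_m(0.5),
                                         variant = "textbook")[1, 1],
               120 * 0.6 * 0.5)
  expect_error(compute_soil_conservation(as_m(1), as_m(1), as_m(1), as_m(1),
                                         as_m(1.2), as_m(0.5)),
               class = "esd_domain_error")
})

test_that("carbon sequestration is 1.63 x NPP with area scaling", {
  expect_equal(compute_carbon_sequestration(as_m(600))[1, 1], 978)
  expect_equal(compute_carbon_sequestration(as_m(0))[1, 1], 0)
  # the reported year-2000 landscape mean CS of 1000.48 t km^-2 implies
  # mean NPP 613.79 under the printed coefficient
  expect_equal(compute_carbon_sequestration(as_m(613.79))[1, 1], 1000.48,
               tolerance = 1e-4)
  expect_equal(compute_carbon_sequestration(as_m(600), cell_area_km2 = 4,
                                            output = "total")[1, 1], 978 * 4)
  expect_error(compute_carbon_sequestration(as_m(-1)),
               class = "esd_domain_error")
})

test_that("food supply allocation is NDVI-proportional and conservative", {
  ndvi <- matrix(c(0.2, 0.3, 0.5, 0.9), 2, 2)
  lu <- matrix(c(1, 1, 1, 2), 2, 2)     # three cropland cells + one forest
  zones <- matrix(1L, 2, 2)
  tot <- data.frame(zone_id = 1L, p_sum_t = 100)
  fs <- allocate_food_supply(ndvi, lu, zones, tot)
  expect_equal(as.vector(fs), c(20, 30, 50, 0))
  # single cropland cell takes everything
  lu1 <- matrix(c(1, 2, 2, 2), 2, 2)
  fs1 <- allocate_food_supply(ndvi, lu1, zones, tot)
  expect_equal(fs1[1, 1], 100)
  # zero total allocates nothing
  fs0 <- allocate_food_supply(ndvi, lu, zones,
                              data.frame(zone_id = 1L, p_sum_t = 0))
  expect_true(all(fs0 == 0))
  # positive total but no usable cropland NDVI names the zone
  expect_error(
    allocate_food_supply(ndvi, matrix(2, 2, 2), zones, tot),
    "zone 1", class = "esd_alloc_error")
  # negative cropland NDVI excluded with a warning, conservation kept
  ndvi2 <- ndvi; ndvi2[1, 1] <- -0.2
  expect_warning(fs2 <- allocate_food_supply(ndvi2, lu, zones, tot),
                 "negative NDVI")
  expect_equal(sum(fs2), 100)
  expect_equal(fs2[1, 1], 0)
})

test_that("mass conservation holds over random zone layouts", {
  set.seed(404)
  for (rep in 1:100) {
    nr <- sample(5:12, 1); nc <- sample(5:12, 1)
    zones <- matrix(sample.int(4, nr * nc, replace = TRUE), nr, nc)
    lu <- matrix(sample(c(1, 1, 2, 3), nr * nc, replace = TRUE), nr, nc)
    ndvi <- matrix(runif(nr * nc, 0.05, 0.95), nr, nc)
    has_crop <- vapply(1:4, function(z) any(zones == z & lu == 1), TRUE)
    tot <- data.frame(zone_id = 1:4,
                      p_sum_t = ifelse(has_crop, runif(4, 0, 500), 0))
    fs <- allocate_food_supply(ndvi, lu, zones, tot)
    for (z in 1:4) {
      expect_lt(abs(sum(fs[zones == z]) - tot$p_sum_t[z]),
                1e-9 * max(tot$p_sum_t[z], 1))
    }
    expect_true(all(fs[lu != 1] == 0))
  }
})

test_that("service responses are monotone and linear where the formulas say so", {
  set.seed(11)
  v <- matrix(runif(25, 150, 500), 5, 5)
  ti <- matrix(runif(25, 0.5, 5), 5, 5)
  ks <- matrix(runif(25, 10, 500), 5, 5)
  yl <- matrix(runif(25, 0, 900), 5, 5)
  base <- compute_water_retention(v, ti, ks, yl)
  expect_true(all(compute_water_retention(v, ti, ks, yl * 1.3) >= base))
  expect_true(all(compute_water_retention(v, ti + 0.5, ks, yl) >= base))
  expect_true(all(compute_water_retention(v, ti, ks + 40, yl) >= base))
  expect_true(all(compute_water_retention(v * 1.2, ti, ks, yl) <= base))
  expect_true(all(base <= yl))
  # RUSLE linearity in each factor; CS proportionality
  r <- matrix(runif(25, 0, 300), 5, 5); k <- matrix(runif(25, 0, 1), 5, 5)
  l <- matrix(runif(25, 0.5, 3), 5, 5); s <- matrix(runif(25, 0.5, 9), 5, 5)
  cc <- matrix(runif(25), 5, 5); pp <- matrix(runif(25), 5, 5)
  q1 <- compute_soil_conservation(r, k, l, s, cc, pp)
  expect_equal(compute_soil_conservation(3 * r, k, l, s, cc, pp), 3 * q1)
  expect_equal(compute_soil_conservation(r, 2 * k * 0.5, l * 2, s, cc, pp), 2 * q1)
  npp <- matrix(runif(25, 0, 1200), 5, 5)
  expect_equal(compute_carbon_sequestration(2.5 * npp),
               2.5 * compute_carbon_sequestration(npp))
})

test_that("gridded formulas agree with a scalar loop reference to 1e-12", {
  set.seed(21)
  n <- 10
  v <- matrix(runif(n^2, 100, 600), n, n); ti <- matrix(runif(n^2, 0, 6), n, n)
  ks <- matrix(runif(n^2, 0, 600), n, n); yl <- matrix(runif(n^2, 0, 1000), n, n)
  wr <- compute_water_retention(v, ti, ks, yl)
  r <- matrix(runif(n^2, 0, 400), n, n); k <- matrix(runif(n^2, 0, 1), n, n)
  l <- matrix(runif(n^2, 0, 4), n, n); s <- matrix(runif(n^2, 0, 10), n, n)
  cc <- matrix(runif(n^2), n, n); pp <- matrix(runif(n^2), n, n)
  sc <- compute_soil_conservation(r, k, l, s, cc, pp)
  npp <- matrix(runif(n^2, 0, 1500), n, n)
  cs <- compute_carbon_sequestration(npp)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      wr_ref <- min(1, 249 / v[i, j]) * min(1, 0.9 * ti[i, j] / 3) *
        min(1, ks[i, j] / 300) * yl[i, j]
      sc_ref <- r[i, j] * k[i, j] * l[i, j] * s[i, j] *
        (1 - pp[i, j] * cc[i, j])
      expect_equal(wr[i, j], wr_ref, tolerance = 1e-12)
      expect_equal(sc[i, j], sc_ref, tolerance = 1e-12)
      expect_equal(cs[i, j], 1.63 * npp[i, j], tolerance = 1e-12)
    }
  }
})
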