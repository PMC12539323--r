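# Drought classification, frequency, stratified comparison and the binned
# SPEI surface.

test_that("classification applies half-open intervals with severe-side closure", {
  lab <- classify_drought(c(0, -0.5, -1, -1.5, -2, -2.3, 1.7))
  classes <- attr(lab, "classes")
  expect_equal(classes[lab],
               c("none", "slight", "medium", "serious", "extreme", "extreme",
                 "none"))
  expect_error(classify_drought(c(0.2, Inf)), class = "esd_data_error")
})

test_that("every cell-year gets exactly one class and counts sum to n_years", {
  sh <- shared_landscape()
  lab <- sh$labels
  expect_true(all(!is.na(lab[rep(as.vector(sh$ls$mask), sh$ls$n_years)])))
  counts <- drought_class_counts(lab)
  total <- Reduce(`+`, counts)
  expect_true(all(total[sh$ls$mask] == sh$ls$n_years))
})

test_that("lowering SPEI never yields a less severe class", {
  set.seed(9)
  x <- sort(runif(500, -3.5, 1.5), decreasing = TRUE)
  lab <- classify_drought(x)
  expect_true(all(diff(lab) >= 0))
})

test_that("drought frequency counts drought years and ignores non-drought relabeling", {
  # hand-counted toy series: 3 drought years of 5
  spei <- array(c(0.1, -0.6, -1.2, 0.5, -2.5), c(1, 1, 5))
  lab <- classify_drought(spei)
  expect_equal(drought_frequency(lab)[1, 1], 3 / 5)
  expect_equal(drought_frequency(classify_drought(array(1, c(1, 1, 23))))[1, 1], 0)
  expect_equal(drought_frequency(classify_drought(array(-3, c(1, 1, 23))))[1, 1], 1)
  # 5 of 23
  s23 <- array(c(rep(-0.7, 5), rep(0.3, 18)), c(1, 1, 23))
  expect_equal(drought_frequency(classify_drought(s23))[1, 1], 5 / 23)
  # merging all drought classes into one leaves SPEI_F unchanged
  coarse <- drought_class_table(breaks = -0.5, classes = c("none", "drought"))
  expect_equal(drought_frequency(classify_drought(spei, coarse))[1, 1], 3 / 5)
})

test_that("planted drought suppression is recovered with a significant Welch test", {
  set.seed(31)
  nr <- 50; nc <- 40; ny <- 10
  spei <- array(rnorm(nr * nc * ny, 0.4, 0.2), c(nr, nc, ny))
  spei[, , c(3, 7)] <- rnorm(nr * nc * 2, -1.2, 0.2)
  lab <- classify_drought(spei)
  base <- matrix(runif(nr * nc, 300, 500), nr, nc)
  wr <- array(0, c(nr, nc, ny))
  for (t in 1:ny) {
    supp <- ifelse(t %in% c(3, 7), 0.7, 1)   # 30% suppression in drought years
    wr[, , t] <- base * supp * exp(rnorm(nr * nc, 0, 0.05))
  }
  es <- structure(list(wr = wr, sc = wr, cs = wr, fs = wr,
                       years = 2000 + 1:ny, cell_km = 1), class = "es_stack")
  lu <- matrix(2L, nr, nc)
  out <- stratify_es_by_drought(es, lab, lu, mode = "cell-year")
  row <- out[out$es == "wr" & out$land_use == "all", ]
  expect_equal(row$mean_drought / row$mean_nondrought, 0.7, tolerance = 0.02)
  expect_lt(row$p_welch, 0.001)
})

test_that("degenerate strata are flagged undefined, not fatal", {
  spei <- array(rep(0.5, 8), c(2, 2, 2))  # no drought at all
  lab <- classify_drought(spei)
  es <- structure(list(wr = spei, sc = spei, cs = spei, fs = spei,
                       years = 2000:2001, cell_km = 1), class = "es_stack")
  out <- stratify_es_by_drought(es, lab, matrix(1L, 2, 2), mode = "cell-year")
  expect_true(all(out$undefined))
  out2 <- stratify_es_by_drought(es, lab, matrix(1L, 2, 2), mode = "class-zone")
  expect_true(all(out2$undefined[out2$degree == "extreme"]))
  expect_true(all(is.na(out2$mean[out2$degree == "extreme"])))
})

test_that("the binned surface recovers constants and planted minima", {
  # constant SPEI fills every occupied bin with that constant
  nr <- 10; nc <- 10; ny <- 4
  tem <- array(runif(nr * nc * ny, 10, 30), c(nr, nc, ny))
  pre <- array(runif(nr * nc * ny, 200, 1500), c(nr, nc, ny))
  spei <- array(0.42, c(nr, nc, ny))
  surf <- binned_spei_surface(tem, pre, spei)
  expect_true(all(abs(surf$mean[surf$n > 0] - 0.42) < 1e-12))
  expect_true(all(is.na(surf$mean[surf$n == 0])))
  # planted low SPEI only in the hot-dry regime
  hot_dry <- tem >= 23 & tem < 25 & pre >= 400 & pre < 600
  spei2 <- array(0.8, c(nr, nc, ny)); spei2[hot_dry] <- -1.6
  surf2 <- binned_spei_surface(tem, pre, spei2)
  lowest <- which(surf2$mean == min(surf2$mean, na.rm = TRUE), arr.ind = TRUE)
  tb <- surf2$tem_breaks[lowest[, 1]]
  pb <- surf2$pre_breaks[lowest[, 2]]
  expect_true(all(tb >= 23 & tb < 25))
  expect_true(all(pb >= 400 & pb < 600))
  expect_error(binned_spei_surface(tem, pre, spei, tem_breaks = c(3, 2, 1)),
               class = "esd_config_error")
})

test_that("the generated landscape places its lowest mean SPEI in the hot-dry bins", {
  sh <- shared_landscape()
  surf <- binned_spei_surface(sh$ls$dynamic$TEM, sh$ls$dynamic$PRE,
                              sh$ls$dynamic$SPEI)
  lowest <- which(surf$mean == min(surf$mean, na.rm = TRUE), arr.ind = TRUE)
  expect_true(all(surf$tem_breaks[lowest[, 1]] >= 23 &
                    surf$tem_breaks[lowest[, 1]] < 25))
  expect_true(all(surf$pre_breaks[lowest[, 2]] >= 400 &
                    surf$pre_breaks[lowest[, 2]] < 600))
})
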