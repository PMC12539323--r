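# Feature standardization, SOM clustering, bundle summaries.

toy_es <- function(vals, ny = 3) {
  # vals: matrix cells x 4 of per-cell constant services on a 1-column grid
  nr <- nrow(vals)
  mk <- function(v) array(rep(v, ny), c(nr, 1, ny))
  structure(list(wr = mk(vals[, 1]), sc = mk(vals[, 2]),
                 cs = mk(vals[, 3]), fs = mk(vals[, 4]),
                 years = 2000 + seq_len(ny) - 1, cell_km = 1),
            class = "es_stack")
}

test_that("z-scores match the closed form and are idempotent", {
  es <- toy_es(matrix(c(0, 1,  0, 1,  0, 1,  0, 1), 2, 4))
  sf <- matrix(c(0.2, 0.8), 2, 1)
  fm <- build_feature_matrix(es, sf)
  # two-point z-scores are +-(1/sqrt(2)) under the sample SD
  expect_equal(as.vector(fm$x[, "WR"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(colMeans(fm$x)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(fm$x, 2, sd)), rep(1, 5), tolerance = 1e-9)
  # feeding standardized values back changes nothing (up to 1e-12)
  es2 <- toy_es(fm$x[, 1:4])
  fm2 <- build_feature_matrix(es2, matrix(fm$x[, 5], 2, 1))
  expect_equal(fm2$x, fm$x, tolerance = 1e-12, ignore_attr = TRUE)
  # zero-variance column named in the error
  es3 <- toy_es(matrix(c(0, 1, 0, 1, 0, 1, 5, 5), 2, 4))
  expect_error(build_feature_matrix(es3, sf), "FS",
               class = "esd_standardize_error")
})

make_clusters <- function(n = 2000, sep = 6, seed = 99) {
  set.seed(seed)
  cent <- matrix(c(0, 0, 0, 0, 0,
                   sep, 0, 0, sep, 0,
                   0, sep, sep, 0, 0,
                   sep, sep, 0, 0, sep), 4, 5, byrow = TRUE)
  truth <- sample(1:4, n, replace = TRUE)
  x <- cent[truth, ] + matrix(rnorm(n * 5), n, 5)
  colnames(x) <- c("WR", "SC", "CS", "FS", "SPEI_F")
  list(x = x, truth = truth)
}

test_that("well-separated planted clusters are recovered near-perfectly", {
  cl <- make_clusters()
  a <- som_cluster(cl$x, k = 4, epochs = 120, seed = 3)
  expect_equal(a$k_realized, 4)
  expect_gte(adjusted_rand_index(a$labels, cl$truth), 0.9)
  expect_equal(sum(a$sizes), nrow(cl$x))
  # per-bundle means sit within 0.1 SD of the planted centroids
  sm <- summarize_bundles(a, cl$x)
  for (b in 1:4) {
    bm <- sm$mean[sm$bundle == b]
    tab <- table(cl$truth[a$labels == b])   # majority planted cluster
    tcl <- as.integer(names(which.max(tab)))
    tr_mean <- colMeans(cl$x[cl$truth == tcl, , drop = FALSE])
    expect_lt(max(abs(bm - tr_mean)), 0.1)
  }
})

test_that("SOM training is seed-deterministic and duplicate-consistent", {
  cl <- make_clusters(n = 600)
  a1 <- som_cluster(cl$x, k = 4, epochs = 60, seed = 8)
  a2 <- som_cluster(cl$x, k = 4, epochs = 60, seed = 8)
  expect_identical(a1$labels, a2$labels)
  expect_identical(a1$codebook, a2$codebook)
  # duplicated rows always land in the same unit
  xd <- rbind(cl$x, cl$x)
  ad <- som_cluster(xd, k = 4, epochs = 60, seed = 8)
  n <- nrow(cl$x)
  expect_identical(ad$labels[1:n], ad$labels[(n + 1):(2 * n)])
})

test_that("degenerate k = 1 assigns everything to one bundle", {
  cl <- make_clusters(n = 300)
  a <- som_cluster(cl$x, k = 1, epochs = 50, seed = 2)
  expect_equal(a$k_realized, 1)
  expect_true(all(a$labels == 1))
  expect_equal(a$quantization_error,
               mean(sqrt(rowSums(sweep(cl$x, 2, a$codebook[1, ])^2))),
               tolerance = 1e-9)
})

test_that("training beats the trivial grand-mean codebook", {
  cl <- make_clusters(n = 1500, sep = 4)
  a <- som_cluster(cl$x, k = 4, epochs = 100, seed = 6)
  trivial <- mean(sqrt(rowSums(sweep(cl$x, 2, colMeans(cl$x))^2)))
  expect_lt(a$quantization_error, trivial)
  expect_error(som_cluster(cl$x[1:20, ], k = 4, epochs = 10, seed = 1),
               class = "esd_data_error")
})

test_that("bundle labels map back onto the grid over valid cells only", {
  sh <- shared_landscape()
  fm <- build_feature_matrix(sh$es, sh$spei_f)
  a <- som_cluster(fm, k = 4, epochs = 60, seed = 4)
  bm <- bundle_map(a)
  expect_equal(dim(bm), c(40, 40))
  expect_true(all(is.na(bm[!sh$ls$mask])))
  expect_true(all(!is.na(bm[sh$ls$mask])))
  # single-row bundle summary degenerates to the row itself
  one <- matrix(rnorm(5), 1, 5, dimnames = list(NULL, colnames(fm$x)))
  xx <- rbind(fm$x[1:199, ], one)
  a2 <- som_cluster(xx, k = 2, epochs = 40, seed = 9)
  sizes <- table(a2$labels)
  if (any(sizes == 1)) {
    b <- as.integer(names(sizes)[sizes == 1])
    sm <- summarize_bundles(a2, xx)
    sub <- sm[sm$bundle == b, ]
    expect_equal(sub$iqr, rep(0, nrow(sub)))
    expect_equal(sub$median, sub$mean)
  }
})
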