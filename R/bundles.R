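# Ecosystem-service bundles: z-scored feature matrix over valid cells,
# self-organizing-map clustering (one codebook unit per bundle by default),
# and per-bundle summaries.

#' Build the standardized cell feature matrix
#'
#' One row per valid cell; columns are the period-mean services (or the
#' year-stacked services with `period_stat = "per-year"`, one row per
#' cell-year) plus drought frequency, z-score standardized. The column means
#' and SDs are retained so features can be mapped back to natural units.
#'
#' @param es an `es_stack`.
#' @param spei_f drought-frequency matrix from [drought_frequency()].
#' @param period_stat `"mean"` (default; period-mean per cell) or
#'   `"per-year"` (one row per cell-year; SPEI_F repeats across years).
#' @param extra optional named list of additional feature matrices.
#' @return object of class `feature_matrix`: list with `x` (standardized
#'   matrix), `center`, `scale`, `cells` (cell indices of rows), `dim`
#'   (grid shape), `standardized = TRUE`.
#' @export
build_feature_matrix <- function(es, spei_f, period_stat = c("mean", "per-year"),
                                 extra = NULL) {
  period_stat <- match.arg(period_stat)
  d <- dim(es$wr)
  if (period_stat == "mean") {
    means <- es_period_means(es)
    cols <- c(lapply(means, as.vector), list(spei_f = as.vector(spei_f)))
  } else {
    ny <- d[3]
    cols <- lapply(stats::setNames(ES_NAMES, ES_NAMES),
                   function(v) as.vector(es[[v]]))
    cols$spei_f <- rep(as.vector(spei_f), ny)
  }
  if (!is.null(extra)) cols <- c(cols, lapply(extra, as.vector))
  names(cols)[seq_along(ES_NAMES)] <- toupper(ES_NAMES)
  names(cols)[names(cols) == "spei_f"] <- "SPEI_F"
  raw <- do.call(cbind, cols)
  keep <- rowSums(is.na(raw)) == 0
  raw <- raw[keep, , drop = FALSE]
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    stop_esd("esd_standardize_error",
             "zero-variance feature column(s): %s",
             paste(colnames(raw)[zero], collapse = ", "))
  }
  x <- sweep(sweep(raw, 2, ctr, "-"), 2, scl, "/")
  structure(list(x = x, center = ctr, scale = scl,
                 cells = which(keep), dim = d[1:2],
                 period_stat = period_stat, standardized = TRUE),
            class = "feature_matrix")
}

#' Cluster cells into service bundles with a self-organizing map
#'
#' Online SOM on a small rectangular map (default 2 x 2, one unit per
#' bundle), Gaussian neighbourhood, learning rate and radius decayed
#' linearly (0.5 to 0.01 and half the map diagonal to 0.3) over
#' `epochs` passes in seeded random order; codebook initialized from `k`
#' seeded sample rows. Each cell is assigned its best-matching unit.
#' Deterministic given the seed. If training empties a unit, the realized
#' bundle count is reported with a warning.
#'
#' @param features a `feature_matrix` (or plain numeric matrix).
#' @param k number of bundles (codebook units) when `grid_shape` is NULL.
#' @param grid_shape length-2 map shape; default `c(1, k)` arranged as close
#'   to square as possible.
#' @param epochs training passes over the data (default 500).
#' @param seed integer seed for init and presentation order.
#' @param alpha learning-rate range (start, end).
#' @return object of class `bundle_assignment`: `labels` (per-row unit id,
#'   renumbered 1..realized k), `unit` (raw best-matching unit),
#'   `codebook`, `grid`, `quantization_error`, `sizes`, `k_realized`,
#'   `seed`; plus `cells`/`dim` carried from the feature matrix for mapping.
#' @export
som_cluster <- function(features, k = 4, grid_shape = NULL, epochs = 500,
                        seed = 1, alpha = c(0.5, 0.01)) {
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  n <- nrow(x)
  if (is.null(grid_shape)) {
    gr <- max(1L, floor(sqrt(k)))
    gc <- ceiling(k / gr)
    grid_shape <- c(gr, gc)
  }
  k_units <- prod(grid_shape)
  if (n < 10 * k_units) {
    stop_esd("esd_data_error", "need >= %d rows for %d units (got %d)",
             10 * k_units, k_units, n)
  }
  grid <- as.matrix(expand.grid(seq_len(grid_shape[1]), seq_len(grid_shape[2])))
  storage.mode(grid) <- "double"
  set.seed(seed)
  init_rows <- sample.int(n, k_units)
  codebook <- x[init_rows, , drop = FALSE]
  radius0 <- max(sqrt(sum((apply(grid, 2, max) - apply(grid, 2, min))^2)) / 2,
                 0.5)
  order <- as.integer(unlist(lapply(seq_len(epochs),
                                    function(e) sample.int(n, n))))
  codebook <- som_train_cpp(x, codebook, grid, order,
                            alpha[1], alpha[2], radius0, 0.3)
  mapped <- som_map_cpp(x, codebook)
  unit <- mapped$bmu
  qe <- mean(sqrt(mapped$dist2))
  occupied <- sort(unique(unit))
  if (length(occupied) < k_units) {
    warning(sprintf("SOM left %d unit(s) empty; realized bundle count is %d",
                    k_units - length(occupied), length(occupied)))
  }
  labels <- match(unit, occupied)
  rownames(codebook) <- paste0("unit", seq_len(k_units))
  colnames(codebook) <- colnames(x)
  structure(list(labels = labels, unit = unit, codebook = codebook,
                 grid = grid, grid_shape = grid_shape,
                 quantization_error = qe,
                 sizes = as.vector(table(labels)),
                 k_realized = length(occupied), seed = seed,
                 cells = if (inherits(features, "feature_matrix"))
                   features$cells else NULL,
                 dim = if (inherits(features, "feature_matrix"))
                   features$dim else NULL),
            class = "bundle_assignment")
}

#' @export
print.bundle_assignment <- function(x, ...) {
  cat(sprintf("<bundle_assignment> %d cells, %d bundle(s), QE = %.4f\n",
              length(x$labels), x$k_realized, x$quantization_error))
  print(stats::setNames(x$sizes, paste0("B", seq_along(x$sizes))))
  invisible(x)
}

#' Map bundle labels back onto the grid
#'
#' @param assignment a `bundle_assignment` produced from a `feature_matrix`.
#' @return integer matrix of bundle labels (NA on invalid cells).
#' @export
bundle_map <- function(assignment) {
  if (is.null(assignment$dim)) {
    stop_esd("esd_data_error", "assignment carries no grid information")
  }
  m <- matrix(NA_integer_, assignment$dim[1], assignment$dim[2])
  m[assignment$cells] <- assignment$labels
  m
}

#' Per-bundle feature summaries
#'
#' Median, interquartile range, mean and SD of each feature within each
#' bundle (the boxplot statistics of the published bundle profiles), in the
#' standardized units of the feature matrix.
#'
#' @param assignment a `bundle_assignment`.
#' @param features the `feature_matrix` (or matrix) it was trained on.
#' @return data.frame with bundle, feature, n, median, q25, q75, iqr, mean, sd.
#' @export
summarize_bundles <- function(assignment, features) {
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  if (nrow(x) != length(assignment$labels)) {
    stop_esd("esd_dim_error", "labels do not cover the feature rows")
  }
  rows <- list()
  for (b in seq_len(assignment$k_realized)) {
    xb <- x[assignment$labels == b, , drop = FALSE]
    for (j in seq_len(ncol(x))) {
      v <- xb[, j]
      qs <- quantile(v, c(0.25, 0.5, 0.75), type = 7)
      rows[[length(rows) + 1L]] <- data.frame(
        bundle = b, feature = colnames(x)[j], n = length(v),
        median = unname(qs[2]), q25 = unname(qs[1]), q75 = unname(qs[3]),
        iqr = unname(qs[3] - qs[1]), mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
    }
  }
  do.call(rbind, rows)
}
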