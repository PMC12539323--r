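# Per-cell monotone trend analysis: Theil-Sen median slope and the
# Mann-Kendall test with tie-corrected variance and continuity correction.

#' Theil-Sen median slope
#'
#' The median of all pairwise slopes `(x_j - x_i) / (t_j - t_i)`, `j > i`.
#' Missing values are dropped pairwise while their time indices keep their
#' calendar spacing, so the slope stays in units of the variable per year.
#'
#' @param series numeric vector (>= 3 finite values required).
#' @param t time coordinates (default the observation index).
#' @return the slope.
#' @export
sen_slope <- function(series, t = seq_along(series)) {
  ok <- is.finite(series)
  x <- series[ok]; tt <- t[ok]
  n <- length(x)
  if (n < 3) {
    stop_esd("esd_data_error",
             "Theil-Sen slope needs >= 3 finite values (got %d)", n)
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  median((x[pairs[, 2]] - x[pairs[, 1]]) / (tt[pairs[, 2]] - tt[pairs[, 1]]))
}

#' Mann-Kendall trend test
#'
#' Computes `S = sum_{i<j} sign(x_j - x_i)`, the tie-corrected variance
#' `Var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` (sum over tie-group
#' sizes t), the continuity-corrected normal score `z = (S -+ 1)/sqrt(Var(S))`
#' (z = 0 when S = 0), and the two-sided p-value. An all-tied series is not
#' an error: S = 0, z = 0, p = 1.
#'
#' @param series numeric vector (>= 4 finite values required).
#' @param t time coordinates used only for the accompanying Sen slope.
#' @param alpha significance level for the trend class.
#' @return list of class `trend_result`: `slope`, `s` (integer S), `var_s`,
#'   `z`, `p`, `sig_class` in {"sig_increase", "sig_decrease", "nonsig"}, `n`.
#' @export
mann_kendall <- function(series, t = seq_along(series), alpha = 0.05) {
  ok <- is.finite(series)
  x <- series[ok]
  n <- length(x)
  if (n < 4) {
    stop_esd("esd_data_error",
             "Mann-Kendall test needs >= 4 finite values (got %d)", n)
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  s <- sum(sign(x[pairs[, 2]] - x[pairs[, 1]]))
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  if (var_s == 0) z <- 0
  p <- if (z == 0 && s == 0) 1 else 2 * pnorm(-abs(z))
  slope <- sen_slope(series, t)
  sig_class <- if (p < alpha && s > 0) "sig_increase"
    else if (p < alpha && s < 0) "sig_decrease" else "nonsig"
  structure(list(slope = slope, s = as.integer(s), var_s = var_s, z = z,
                 p = p, sig_class = sig_class, n = n, alpha = alpha),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %d, z = %.3f, p = %.4g (%s); Sen slope = %.4g\n",
              x$s, x$z, x$p, x$sig_class, x$slope))
  invisible(x)
}

#' Per-cell trend maps for an annual grid series
#'
#' Vectorized Theil-Sen slope and Mann-Kendall test for every valid cell of
#' a row x col x year array, plus optional zone-mean slopes.
#'
#' @param arr row x col x year array.
#' @param alpha significance level (default 0.05, the published star level).
#' @param years calendar time coordinates (default 1..n_years).
#' @param zones optional zone matrix for zone-mean slopes.
#' @return list with matrices `slope`, `s`, `z`, `p`, `sig` (coded -1/0/+1
#'   for significant decrease / nonsignificant / significant increase) and,
#'   when zones are given, a `zone_slopes` data.frame.
#' @export
trend_raster <- function(arr, alpha = 0.05, years = NULL, zones = NULL) {
  d <- dim(arr)
  ny <- d[3]
  if (is.null(years)) years <- seq_len(ny)
  X <- matrix(arr, d[1] * d[2], ny)
  pairs <- which(upper.tri(matrix(0, ny, ny)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  D <- X[, j, drop = FALSE] - X[, i, drop = FALSE]
  dt <- years[j] - years[i]
  slopes_mat <- sweep(D, 2, dt, "/")
  slope <- apply(slopes_mat, 1, median)  # NA if any pair missing; cells are
                                         # either fully valid or fully NA
  s <- rowSums(sign(D))
  # Tie correction per cell (ties are rare on continuous data but the
  # variance formula is applied exactly).
  var_s <- apply(X, 1, function(v) {
    v <- v[is.finite(v)]
    n <- length(v)
    if (n < 4) return(NA_real_)
    ties <- table(v); ties <- ties[ties > 1]
    (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  })
  z <- ifelse(s > 0, (s - 1) / sqrt(var_s),
              ifelse(s < 0, (s + 1) / sqrt(var_s), 0))
  z[var_s == 0] <- 0
  p <- ifelse(s == 0 & z == 0, 1, 2 * pnorm(-abs(z)))
  sig <- ifelse(p < alpha, sign(s), 0)
  shape <- function(v) matrix(v, d[1], d[2])
  out <- list(slope = shape(slope), s = shape(s), z = shape(z),
              p = shape(p), sig = shape(sig), alpha = alpha)
  if (!is.null(zones)) {
    zv <- as.vector(zones)
    keep <- !is.na(zv) & !is.na(slope)
    agg <- stats::aggregate(list(mean_slope = slope[keep]),
                            by = list(zone_id = zv[keep]), FUN = mean)
    out$zone_slopes <- agg[order(agg$zone_id), ]
  }
  out
}
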