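# Constraint-line (upper boundary) extraction and threshold identification.
#
# Procedure: split the constraining variable's range into equal-width
# intervals (default 100), take the 99.9th percentile of the response within
# each sufficiently populated interval as a boundary point, least-squares fit
# a small catalog of boundary families to the points, keep the best-fitting
# family (penalized for size, since the catalog is partly nested), and locate
# the drought-response threshold where the fitted curve's derivative vanishes
# (an interior maximum).

CONSTRAINT_FAMILIES <- c("hump_quadratic", "hump_gaussian", "convex_wave_cubic")

#' Extract constraint-boundary points from a scatter
#'
#' Equal-width bins over `[min(x), max(x)]`; within each bin holding at least
#' `min_count` points, the `q`-th percentile of the response (linear
#' interpolation between order statistics, `quantile(type = 7)`) is a
#' boundary point located at the bin midpoint. Sparse bins are dropped, not
#' merged. At least 10 qualifying bins are required.
#'
#' @param x,y paired finite observations.
#' @param n_bins number of equal-width intervals (default 100).
#' @param q boundary percentile (default 99.9).
#' @param min_count minimum points for a bin to qualify (default 10).
#' @return object of class `boundary_points`: data.frame with `boundary_x`
#'   (bin midpoints), `boundary_y`, `count`, plus attributes `bin_edges`, `q`.
#' @export
extract_boundary_points <- function(x, y, n_bins = 100, q = 99.9,
                                    min_count = 10) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x) || diff(range(x)) == 0) {
    stop_esd("esd_data_error", "constraining variable has no spread")
  }
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- cut(x, edges, labels = FALSE, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  qualify <- which(counts >= min_count)
  if (length(qualify) < 10) {
    stop_esd("esd_data_error",
             "only %d bin(s) hold >= %d points; boundary not extractable",
             length(qualify), min_count)
  }
  boundary_y <- vapply(qualify, function(b) {
    unname(quantile(y[bin == b], q / 100, type = 7))
  }, 0)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(boundary_x = mids[qualify], boundary_y = boundary_y,
                    count = counts[qualify])
  attr(out, "bin_edges") <- edges
  attr(out, "q") <- q
  class(out) <- c("boundary_points", "data.frame")
  out
}

# Least-squares fits of each candidate family to the boundary points.
# Returns NULL on failure (e.g., nls non-convergence), which drops the family.
fit_family <- function(family, bx, by) {
  n_params <- c(hump_quadratic = 3, hump_gaussian = 4, convex_wave_cubic = 4)
  r2_of <- function(fitted) {
    sst <- sum((by - mean(by))^2)
    if (sst == 0) return(if (all(abs(fitted - by) < 1e-12)) 1 else -Inf)
    1 - sum((by - fitted)^2) / sst
  }
  wrap <- function(f) {
    f$sse <- sum((by - f$predict(bx))^2)
    f$n_params <- n_params[[family]]
    f
  }
  tryCatch(switch(family,
    hump_quadratic = {
      fit <- lm(by ~ bx + I(bx^2))
      cf <- coef(fit)
      wrap(list(coefficients = c(a0 = unname(cf[1]), a1 = unname(cf[2]),
                            a2 = unname(cf[3])),
           predict = function(xx) cf[1] + cf[2] * xx + cf[3] * xx^2,
           r2 = r2_of(stats::fitted(fit))))
    },
    convex_wave_cubic = {
      fit <- lm(by ~ bx + I(bx^2) + I(bx^3))
      cf <- coef(fit)
      wrap(list(coefficients = c(a0 = unname(cf[1]), a1 = unname(cf[2]),
                            a2 = unname(cf[3]), a3 = unname(cf[4])),
           predict = function(xx) cf[1] + cf[2] * xx + cf[3] * xx^2 + cf[4] * xx^3,
           r2 = r2_of(stats::fitted(fit))))
    },
    hump_gaussian = {
      m0 <- bx[which.max(by)]
      h0 <- max(by) - min(by)
      if (h0 <= 0) h0 <- abs(max(by)) + 1
      s0 <- diff(range(bx)) / 4
      k0 <- min(by)
      fit <- suppressWarnings(
        nls(by ~ k + h * exp(-(bx - m)^2 / (2 * s^2)),
            start = list(k = k0, h = h0, m = m0, s = s0),
            control = stats::nls.control(maxiter = 200, warnOnly = TRUE)))
      cf <- coef(fit)
      pred <- function(xx) cf["k"] + cf["h"] * exp(-(xx - cf["m"])^2 / (2 * cf["s"]^2))
      wrap(list(coefficients = c(cf), predict = pred, r2 = r2_of(pred(bx))))
    }
  ), error = function(e) NULL)
}

#' Fit candidate boundary families and keep the best
#'
#' Each family is least-squares fitted to the boundary points and judged by
#' its goodness of fit there (R^2 is computed on the boundary points, not
#' the full scatter). Because the cubic nests the quadratic and the Gaussian
#' can mimic it, raw R^2 alone would always prefer the larger family; the
#' winner is therefore the family with the smallest BIC
#' (`n log(SSE/n) + k log(n)`), which reduces to maximum R^2 among
#' equal-size families. Families that fit exactly (R^2 = 1 to numerical
#' precision) are preferred by parsimony: the exact family with fewest
#' parameters wins. The derivative-based threshold is attached via
#' [find_threshold()].
#'
#' @param points a `boundary_points` object (or data.frame with columns
#'   `boundary_x`, `boundary_y`).
#' @param families subset of
#'   `c("hump_quadratic", "hump_gaussian", "convex_wave_cubic")`.
#' @return object of class `constraint_fit`: `family`, `coefficients`, `r2`,
#'   `predict`, `threshold_x`, `threshold_y`, `flag` ("ok" or
#'   "boundary_max"), `critical_points`, `x_range`, and `all_r2`.
#' @export
fit_constraint_line <- function(points, families = CONSTRAINT_FAMILIES) {
  families <- match.arg(families, CONSTRAINT_FAMILIES, several.ok = TRUE)
  bx <- points$boundary_x; by <- points$boundary_y
  for (fam in families) {
    need <- switch(fam, hump_quadratic = 3, hump_gaussian = 4,
                   convex_wave_cubic = 4) + 2
    if (length(bx) < need) {
      stop_esd("esd_data_error",
               "family %s needs >= %d boundary points (got %d)",
               fam, need, length(bx))
    }
  }
  fits <- lapply(families, fit_family, bx = bx, by = by)
  names(fits) <- families
  ok <- !vapply(fits, is.null, TRUE)
  ok <- ok & vapply(fits, function(f) {
    !is.null(f) && all(is.finite(f$coefficients)) && is.finite(f$r2)
  }, TRUE)
  if (!any(ok)) {
    stop_esd("esd_fit_error", "no boundary family converged (tried: %s)",
             paste(families, collapse = ", "))
  }
  r2s <- vapply(fits[ok], function(f) f$r2, 0)
  n <- length(bx)
  sst <- sum((by - mean(by))^2)
  exact <- vapply(fits[ok], function(f) f$sse <= 1e-12 * max(sst, 1e-300), TRUE)
  kpar <- vapply(fits[ok], function(f) f$n_params, 0)
  bic <- n * log(pmax(vapply(fits[ok], function(f) f$sse, 0), 1e-300) / n) +
    kpar * log(n)
  best_name <- if (any(exact)) {
    names(which(exact))[which.min(kpar[exact])]
  } else {
    names(bic)[which.min(bic)]
  }
  best <- fits[[best_name]]
  out <- structure(list(family = best_name,
                        coefficients = best$coefficients,
                        r2 = best$r2, predict = best$predict,
                        x_range = range(bx),
                        all_r2 = r2s, bic = bic),
                   class = "constraint_fit")
  thr <- find_threshold(out, out$x_range)
  out$threshold_x <- thr$threshold_x
  out$threshold_y <- thr$threshold_y
  out$flag <- thr$flag
  out$critical_points <- thr$critical_points
  out
}

#' Threshold of a fitted constraint line
#'
#' The threshold is the constraining-variable value where the fitted curve
#' attains its maximum: the root of dy/dx with d2y/dx2 < 0, found
#' analytically for the polynomial families and by bracketed root-finding on
#' the derivative for the Gaussian family. When the maximum over `x_range`
#' sits at an endpoint (no interior maximum), the result is flagged
#' `"boundary_max"` and the endpoint is reported. All derivative roots found
#' in range are returned as `critical_points` for transparency.
#'
#' @param fit a `constraint_fit` (threshold fields are ignored on input).
#' @param x_range length-2 interval to search.
#' @return list with `threshold_x`, `threshold_y`, `flag`, `critical_points`.
#' @export
find_threshold <- function(fit, x_range = fit$x_range) {
  cf <- fit$coefficients
  lo <- x_range[1]; hi <- x_range[2]
  crit <- numeric(0)
  interior_max <- NULL
  if (fit$family == "hump_quadratic") {
    if (cf["a2"] != 0) {
      v <- -cf["a1"] / (2 * cf["a2"])
      crit <- v
      if (cf["a2"] < 0 && v > lo && v < hi) interior_max <- v
    }
  } else if (fit$family == "convex_wave_cubic") {
    disc <- (2 * cf["a2"])^2 - 4 * (3 * cf["a3"]) * cf["a1"]
    if (cf["a3"] != 0 && disc >= 0) {
      roots <- (-2 * cf["a2"] + c(-1, 1) * sqrt(disc)) / (2 * 3 * cf["a3"])
      crit <- roots
      second <- 6 * cf["a3"] * roots + 2 * cf["a2"]
      cand <- roots[second < 0 & roots > lo & roots < hi]
      if (length(cand)) {
        interior_max <- cand[which.max(fit$predict(cand))]
      }
    } else if (cf["a3"] == 0 && cf["a2"] != 0) {
      v <- -cf["a1"] / (2 * cf["a2"])
      crit <- v
      if (cf["a2"] < 0 && v > lo && v < hi) interior_max <- v
    }
  } else if (fit$family == "hump_gaussian") {
    # dy/dx = -h (x - m)/s^2 exp(...): single sign change at x = m; bracket it.
    dfun <- function(xx) {
      -cf["h"] * (xx - cf["m"]) / cf["s"]^2 *
        exp(-(xx - cf["m"])^2 / (2 * cf["s"]^2))
    }
    if (dfun(lo) * dfun(hi) < 0) {
      root <- uniroot(dfun, c(lo, hi), tol = 1e-10)$root
      crit <- root
      eps <- (hi - lo) * 1e-4
      if (fit$predict(root) >= max(fit$predict(root - eps),
                                   fit$predict(root + eps))) {
        interior_max <- root
      }
    }
  }
  if (is.null(interior_max)) {
    ends <- c(lo, hi)
    at <- ends[which.max(fit$predict(ends))]
    list(threshold_x = unname(at), threshold_y = unname(fit$predict(at)),
         flag = "boundary_max", critical_points = unname(crit))
  } else {
    list(threshold_x = unname(interior_max),
         threshold_y = unname(fit$predict(interior_max)),
         flag = "ok", critical_points = unname(crit))
  }
}

#' @export
print.constraint_fit <- function(x, ...) {
  cat(sprintf("<constraint_fit> %s, R2 = %.4f, threshold x = %.3f (%s)\n",
              x$family, x$r2, x$threshold_x, x$flag))
  invisible(x)
}

#' Constraint-line analysis of every service per land-use type
#'
#' Pools cell-years within each land-use class, extracts the SPEI-service
#' boundary, fits the candidate families and reports the winning fit and its
#' threshold. Classes without enough populated bins are reported as skipped
#' rather than failing the whole analysis.
#'
#' @param landscape a `landscape`.
#' @param es an `es_stack`.
#' @param n_bins,q,min_count boundary-extraction settings, see
#'   [extract_boundary_points()].
#' @param families candidate families, see [fit_constraint_line()].
#' @return data.frame with one row per (es, land_use): family, r2,
#'   threshold_x, threshold_y, flag, coefficients (JSON string), skipped,
#'   reason. The fitted objects are attached as attribute `fits`.
#' @export
constraint_analysis_by_landuse <- function(landscape, es, n_bins = 100,
                                           q = 99.9, min_count = 10,
                                           families = CONSTRAINT_FAMILIES) {
  lu_levels <- landscape$land_use_levels
  ny <- landscape$n_years
  lu_vec <- rep(as.vector(landscape$land_use), ny)
  spei_vec <- as.vector(landscape$dynamic$SPEI)
  rows <- list(); fits <- list()
  for (es_name in ES_NAMES) {
    y_all <- as.vector(es[[es_name]])
    for (lu in seq_along(lu_levels)) {
      sel <- !is.na(lu_vec) & lu_vec == lu & !is.na(spei_vec) & !is.na(y_all)
      key <- paste(es_name, lu_levels[lu], sep = ".")
      res <- tryCatch({
        pts <- extract_boundary_points(spei_vec[sel], y_all[sel],
                                       n_bins = n_bins, q = q,
                                       min_count = min_count)
        fit <- fit_constraint_line(pts, families = families)
        fits[[key]] <- fit
        data.frame(es = es_name, land_use = lu_levels[lu],
                   family = fit$family, r2 = fit$r2,
                   threshold_x = fit$threshold_x,
                   threshold_y = fit$threshold_y, flag = fit$flag,
                   coefficients = as.character(jsonlite::toJSON(
                     as.list(fit$coefficients), auto_unbox = TRUE, digits = 10)),
                   skipped = FALSE, reason = "")
      }, esdrought_error = function(e) {
        data.frame(es = es_name, land_use = lu_levels[lu],
                   family = NA_character_, r2 = NA_real_,
                   threshold_x = NA_real_, threshold_y = NA_real_,
                   flag = NA_character_, coefficients = NA_character_,
                   skipped = TRUE, reason = conditionMessage(e))
      })
      rows[[key]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
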