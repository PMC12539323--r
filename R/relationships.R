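# Trade-off / synergy analysis: pairwise Pearson correlations among services
# (negative = trade-off, positive = synergy) within strata defined by drought
# degree or bundle membership, and simple linear service~SPEI relationships
# per land-use type.

#' Pairwise Pearson correlation matrix with significance
#'
#' @param x numeric matrix (observations x features).
#' @return object of class `correlation_matrix`: `r`, `p` (two-sided, exact
#'   t-transform with n-2 df), `n` (pairwise complete sizes), `stars`,
#'   `flags` (e.g., zero-variance features), `features`.
#' @export
correlation_matrix <- function(x) {
  x <- as.matrix(x)
  f <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  k <- ncol(x)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(f, f))
  n <- matrix(0L, k, k, dimnames = list(f, f))
  flags <- matrix("", k, k, dimnames = list(f, f))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    p[i, i] <- 0
    n[i, i] <- sum(!is.na(x[, i]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      m <- sum(ok)
      n[i, j] <- n[j, i] <- m
      if (m < 3) { flags[i, j] <- flags[j, i] <- "insufficient_n"; next }
      if (sd(x[ok, i]) == 0 || sd(x[ok, j]) == 0) {
        flags[i, j] <- flags[j, i] <- "zero_variance"
        next
      }
      rr <- cor(x[ok, i], x[ok, j])
      tt <- rr * sqrt((m - 2) / max(1 - rr^2, .Machine$double.eps))
      pp <- 2 * pt(-abs(tt), df = m - 2)
      r[i, j] <- r[j, i] <- rr
      p[i, j] <- p[j, i] <- pp
    }
  }
  structure(list(r = r, p = p, n = n, stars = p_stars(p), flags = flags,
                 features = f),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix>\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Trade-off/synergy matrices per stratum
#'
#' Pearson correlations among period-mean services (plus drought frequency
#' when supplied) across the cells of each stratum — drought-degree zones or
#' bundles. Per-year pooling of cell-years is available via
#' `unit = "cell-year"`.
#'
#' @param es an `es_stack`.
#' @param strata integer matrix of stratum labels per cell (e.g.
#'   [cell_drought_degree()] output or [bundle_map()]).
#' @param spei_f optional drought-frequency matrix to include as a feature.
#' @param unit `"cell"` (period means, default) or `"cell-year"`.
#' @param stratum_names optional names for the stratum codes.
#' @param min_n minimum observations per stratum (default 3).
#' @return named list of `correlation_matrix`, one per stratum present.
#' @export
tradeoff_matrix <- function(es, strata, spei_f = NULL,
                            unit = c("cell", "cell-year"),
                            stratum_names = NULL, min_n = 3) {
  unit <- match.arg(unit)
  if (unit == "cell") {
    means <- es_period_means(es)
    feat <- do.call(cbind, lapply(means, as.vector))
    colnames(feat) <- toupper(ES_NAMES)
    if (!is.null(spei_f)) feat <- cbind(feat, SPEI_F = as.vector(spei_f))
    svec <- as.vector(strata)
  } else {
    ny <- dim(es$wr)[3]
    feat <- do.call(cbind, lapply(stats::setNames(ES_NAMES, toupper(ES_NAMES)),
                                  function(v) as.vector(es[[v]])))
    if (!is.null(spei_f)) feat <- cbind(feat, SPEI_F = rep(as.vector(spei_f), ny))
    svec <- rep(as.vector(strata), ny)
  }
  out <- list()
  for (s in sort(unique(svec[!is.na(svec)]))) {
    sel <- !is.na(svec) & svec == s
    if (sum(sel) < min_n) next
    nm <- if (!is.null(stratum_names)) stratum_names[s] else as.character(s)
    out[[nm]] <- correlation_matrix(feat[sel, , drop = FALSE])
  }
  out
}

#' Classify pairwise relationships as trade-offs or synergies
#'
#' @param cm a `correlation_matrix`.
#' @param alpha significance level.
#' @return data.frame of feature pairs with r, p, stars and relationship in
#'   {"trade-off", "synergy", "ns"}.
#' @export
tradeoff_table <- function(cm, alpha = 0.05) {
  f <- cm$features
  rows <- list()
  for (i in seq_along(f)) for (j in seq_along(f)) {
    if (j <= i) next
    r <- cm$r[i, j]; p <- cm$p[i, j]
    rel <- if (is.na(r) || is.na(p) || p >= alpha) "ns"
      else if (r < 0) "trade-off" else "synergy"
    rows[[length(rows) + 1L]] <- data.frame(
      feature1 = f[i], feature2 = f[j], r = r, p = p,
      stars = cm$stars[i, j], n = cm$n[i, j], relationship = rel,
      flag = cm$flags[i, j])
  }
  do.call(rbind, rows)
}

#' Linear service ~ SPEI relationship per land-use type
#'
#' For each land-use class and service: ordinary least squares of the
#' class-mean annual service on the class-mean annual SPEI, with Pearson r
#' and its two-sided p-value. Classes with fewer than 3 year-points or
#' degenerate SPEI variance are flagged undefined.
#'
#' @param es an `es_stack`.
#' @param spei row x col x year SPEI array.
#' @param land_use integer land-use matrix.
#' @param land_use_levels names of the codes.
#' @return data.frame with es, land_use, n_years, slope, intercept, r, p,
#'   stars, undefined.
#' @export
es_spei_regression <- function(es, spei, land_use,
                               land_use_levels = LAND_USE_LEVELS) {
  ny <- dim(spei)[3]
  lu_vec <- as.vector(land_use)
  rows <- list()
  for (lu in seq_along(land_use_levels)) {
    cells <- !is.na(lu_vec) & lu_vec == lu
    if (!any(cells)) next
    spei_year <- vapply(seq_len(ny), function(t) {
      mean(as.vector(spei[, , t])[cells], na.rm = TRUE)
    }, 0)
    for (es_name in ES_NAMES) {
      es_year <- vapply(seq_len(ny), function(t) {
        mean(as.vector(es[[es_name]][, , t])[cells], na.rm = TRUE)
      }, 0)
      ok <- is.finite(spei_year) & is.finite(es_year)
      undefined <- sum(ok) < 3 || sd(spei_year[ok]) == 0 || sd(es_year[ok]) == 0
      if (undefined) {
        rows[[length(rows) + 1L]] <- data.frame(
          es = es_name, land_use = land_use_levels[lu], n_years = sum(ok),
          slope = NA_real_, intercept = NA_real_, r = NA_real_, p = NA_real_,
          stars = "", undefined = TRUE)
        next
      }
      fit <- lm(es_year[ok] ~ spei_year[ok])
      ct <- cor.test(spei_year[ok], es_year[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        es = es_name, land_use = land_use_levels[lu], n_years = sum(ok),
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        r = unname(ct$estimate), p = ct$p.value, stars = p_stars(ct$p.value),
        undefined = FALSE)
    }
  }
  do.call(rbind, rows)
}
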