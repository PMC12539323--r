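# Driver attribution via exact Shapley values.
#
# A surrogate predictor f is fitted to a service from twelve driver features;
# per-instance attributions are computed by full subset enumeration of
#
#   phi_i = sum_{S subseteq N \ {i}} |S|! (|N|-|S|-1)! / |N|! [f_x(S u {i}) - f_x(S)]
#
# with the interventional value function f_x(S): the expectation of f over a
# background set with the features in S pinned to the instance's values.
# Enumeration is exact up to |N| = 15 features (12 by default).

DRIVER_FEATURES <- c("TEM", "PRE", "ET", "SPEI_F", "EL", "SL", "NDVI", "WUE",
                     "SOC", "RSMC", "GDP", "POP")

#' Fit a surrogate predictor of one service from driver features
#'
#' The attribution contract is model-agnostic: any object with a
#' `predict(object, newdata_matrix)` returning one finite prediction per row
#' may be plugged into [exact_shapley()]. The default surrogate is an
#' ordinary least-squares linear model; `method = "gam"` fits a thin-plate
#' spline additive model (mgcv) when nonlinearity matters. Predictions bind
#' features by column name, and a fixed seed makes the held-out split (and
#' hence the reported fit quality) reproducible.
#'
#' @param features numeric matrix (rows = instances, named columns).
#' @param target numeric response vector.
#' @param method `"lm"` (default) or `"gam"`.
#' @param seed integer seed for the held-out split.
#' @param holdout fraction of rows held out for the fit-quality score.
#' @return object of class `surrogate_predictor` with `predict_fn`,
#'   `feature_names`, `method`, `r2_holdout`, `constant` (degenerate-fit
#'   flag), `seed`.
#' @export
fit_surrogate <- function(features, target, method = c("lm", "gam"),
                          seed = 1, holdout = 0.2) {
  method <- match.arg(method)
  x <- as.matrix(features)
  if (is.null(colnames(x))) {
    stop_esd("esd_config_error", "feature columns must be named")
  }
  if (nrow(x) < 50) {
    stop_esd("esd_data_error", "surrogate needs >= 50 rows (got %d)", nrow(x))
  }
  if (anyNA(x) || anyNA(target)) {
    stop_esd("esd_data_error", "surrogate inputs must be complete (no NA)")
  }
  fnames <- colnames(x)
  if (sd(target) == 0) {
    warning("constant target: surrogate degenerates to the constant baseline")
    const <- target[1]
    return(structure(list(
      predict_fn = function(newx) rep(const, nrow(newx)),
      feature_names = fnames, method = "constant", r2_holdout = NA_real_,
      constant = TRUE, seed = seed), class = "surrogate_predictor"))
  }
  set.seed(seed)
  n <- nrow(x)
  test_idx <- sample.int(n, max(1, round(holdout * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  df <- as.data.frame(x)
  df$.y <- target
  if (method == "lm") {
    fml <- stats::reformulate(fnames, response = ".y")
    fit <- lm(fml, data = df[train_idx, ])
    predict_fn <- function(newx) {
      nd <- as.data.frame(newx[, fnames, drop = FALSE])
      unname(predict(fit, newdata = nd))
    }
  } else {
    if (!requireNamespace("mgcv", quietly = TRUE)) {
      stop_esd("esd_config_error", "method 'gam' requires the mgcv package")
    }
    terms <- vapply(fnames, function(f) {
      if (length(unique(df[[f]][train_idx])) > 10) sprintf("s(%s)", f) else f
    }, "")
    fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    fit <- mgcv::gam(fml, data = df[train_idx, ])
    predict_fn <- function(newx) {
      nd <- as.data.frame(newx[, fnames, drop = FALSE])
      unname(as.vector(mgcv::predict.gam(fit, newdata = nd)))
    }
  }
  pred_test <- predict_fn(x[test_idx, , drop = FALSE])
  sst <- sum((target[test_idx] - mean(target[test_idx]))^2)
  r2 <- if (sst > 0) 1 - sum((target[test_idx] - pred_test)^2) / sst else NA_real_
  structure(list(predict_fn = predict_fn, feature_names = fnames,
                 method = method, r2_holdout = r2, constant = FALSE,
                 seed = seed),
            class = "surrogate_predictor")
}

#' @export
print.surrogate_predictor <- function(x, ...) {
  cat(sprintf("<surrogate_predictor> %s over %d features, held-out R2 = %.3f\n",
              x$method, length(x$feature_names), x$r2_holdout))
  invisible(x)
}

predict_surrogate <- function(predictor, newx) {
  predictor$predict_fn(newx[, predictor$feature_names, drop = FALSE])
}

#' Interventional value function
#'
#' `f_x(S)`: the mean prediction over the background rows after pinning the
#' features in `S` to the instance's values (features outside `S` keep each
#' background row's values). `f_x(empty set)` is the background-mean
#' prediction; `f_x(N)` is the prediction at the instance.
#'
#' @param predictor a `surrogate_predictor` (or any list with `predict_fn`
#'   and `feature_names`).
#' @param instance named numeric vector (one row of features).
#' @param subset character or integer subset S of the features.
#' @param background numeric matrix of background rows (named columns).
#' @return scalar expected prediction.
#' @export
value_function <- function(predictor, instance, subset, background) {
  background <- as.matrix(background)
  if (nrow(background) == 0) {
    stop_esd("esd_config_error", "background set must be non-empty")
  }
  fnames <- predictor$feature_names
  if (is.character(subset)) subset <- match(subset, fnames)
  if (anyNA(subset)) stop_esd("esd_config_error", "subset outside feature set")
  mixed <- background[, fnames, drop = FALSE]
  for (j in subset) mixed[, j] <- instance[[fnames[j]]]
  mean(predict_surrogate(predictor, mixed))
}

# Subset-sum machinery shared by exact_shapley: value v(S) for every one of
# the 2^p subsets, computed with a single batched prediction.
all_subset_values <- function(predictor, instance, background) {
  fnames <- predictor$feature_names
  p <- length(fnames)
  m <- nrow(background)
  n_sub <- 2L^p
  masks <- 0:(n_sub - 1L)
  bg <- as.matrix(background)[, fnames, drop = FALSE]
  big <- bg[rep.int(seq_len(m), n_sub), , drop = FALSE]
  xvals <- as.numeric(instance[fnames])
  for (j in seq_len(p)) {
    inset <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L
    big[rep(inset, each = m), j] <- xvals[j]
  }
  pred <- predict_surrogate(predictor, big)
  v <- .colMeans(pred, m, n_sub)
  list(v = v, masks = masks, p = p)
}

#' Exact Shapley attribution of one prediction
#'
#' Full enumeration of all feature subsets with the combinatorial weights
#' `|S|! (|N|-|S|-1)! / |N|!`, using the interventional value function over
#' the supplied background. Satisfies the efficiency axiom
#' `sum(phi) = f(x) - E[f]` to numerical precision, and the symmetry and
#' dummy axioms by construction. Enumeration is bounded at 15 features.
#'
#' @param predictor a `surrogate_predictor`.
#' @param instance named numeric vector of feature values.
#' @param background matrix of background rows.
#' @return object of class `shapley_attribution`: `phi` (named per-feature
#'   values), `baseline` (`f_x(empty)`), `fx` (`f_x(N)`), `background_size`.
#' @export
exact_shapley <- function(predictor, instance, background) {
  p <- length(predictor$feature_names)
  if (p > 15) {
    stop_esd("esd_config_error",
             "exact enumeration bounded at 15 features (got %d); use a sampling approximation", p)
  }
  background <- as.matrix(background)
  if (nrow(background) == 0) {
    stop_esd("esd_config_error", "background set must be non-empty")
  }
  sv <- all_subset_values(predictor, instance, background)
  v <- sv$v; masks <- sv$masks
  sizes <- popcount(masks)
  # weight by |S| for subsets S not containing i
  lf <- lfactorial
  w_by_size <- exp(lf(0:(p - 1)) + lf(p - 1 - (0:(p - 1))) - lf(p))
  phi <- numeric(p)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- bitwAnd(masks, bit) == 0L
    s_mask <- masks[without]
    s_size <- sizes[without]
    phi[i] <- sum(w_by_size[s_size + 1L] *
                    (v[s_mask + bit + 1L] - v[s_mask + 1L]))
  }
  names(phi) <- predictor$feature_names
  structure(list(phi = phi, baseline = v[1], fx = v[length(v)],
                 background_size = nrow(background)),
            class = "shapley_attribution")
}

popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat(sprintf("<shapley_attribution> f(x) = %.4g, baseline = %.4g, sum(phi) = %.4g\n",
              x$fx, x$baseline, sum(x$phi)))
  print(round(sort(x$phi, decreasing = TRUE), 4))
  invisible(x)
}

#' Shapley attribution of sampled instances, with importance summary
#'
#' Fits (or reuses) a surrogate per target, attributes a seeded random
#' sample of instances against a seeded background sample, and summarizes
#' per-feature mean |phi| importance alongside the signed (feature value,
#' phi) pairs used for beeswarm-style displays. Positive phi raises the
#' predicted service.
#'
#' @param features numeric matrix of driver features (named columns).
#' @param target numeric response (same rows).
#' @param n_instances instances to attribute (default 500).
#' @param n_background background rows (default 100).
#' @param seed integer seed for sampling (and the surrogate split).
#' @param predictor optional pre-fitted `surrogate_predictor`.
#' @param method surrogate method when fitting here.
#' @return object of class `shap_summary`: `importance` (data.frame feature,
#'   mean_abs_phi, rank), `values` (instance, feature, value, phi),
#'   `predictor`, `baseline_mean`.
#' @export
shap_summary <- function(features, target, n_instances = 500,
                         n_background = 100, seed = 1, predictor = NULL,
                         method = "lm") {
  x <- as.matrix(features)
  if (is.null(predictor)) {
    predictor <- fit_surrogate(x, target, method = method, seed = seed)
  }
  set.seed(derive_seed(seed, "shap_sample"))
  n <- nrow(x)
  inst_idx <- sample.int(n, min(n_instances, n))
  bg_idx <- sample.int(n, min(n_background, n))
  background <- x[bg_idx, , drop = FALSE]
  vals <- vector("list", length(inst_idx))
  baselines <- numeric(length(inst_idx))
  for (ii in seq_along(inst_idx)) {
    inst <- x[inst_idx[ii], ]
    att <- exact_shapley(predictor, inst, background)
    baselines[ii] <- att$baseline
    vals[[ii]] <- data.frame(instance = inst_idx[ii],
                             feature = names(att$phi),
                             value = as.numeric(inst[names(att$phi)]),
                             phi = as.numeric(att$phi))
  }
  values <- do.call(rbind, vals)
  imp <- stats::aggregate(list(mean_abs_phi = abs(values$phi)),
                          by = list(feature = values$feature), FUN = mean)
  imp <- imp[order(-imp$mean_abs_phi), ]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  structure(list(importance = imp, values = values, predictor = predictor,
                 baseline_mean = mean(baselines)),
            class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, ...) {
  cat(sprintf("<shap_summary> %d instances attributed; top drivers:\n",
              length(unique(x$values$instance))))
  print(head(x$importance, 5))
  invisible(x)
}

#' Assemble the per-cell driver feature matrix of a landscape
#'
#' Period means of the twelve drivers (temperature, precipitation, actual
#' evapotranspiration, drought frequency, elevation, slope, NDVI, water-use
#' efficiency, soil organic carbon, relative soil moisture, GDP, population
#' density) over the valid cells.
#'
#' @param landscape a `landscape`.
#' @param spei_f drought-frequency matrix.
#' @return list with `x` (cells x 12 matrix), `cells` (grid indices).
#' @export
driver_features <- function(landscape, spei_f) {
  ls <- landscape
  pm <- function(v) apply(ls$dynamic[[v]], c(1, 2), mean)
  wue <- derive_wue(ls$dynamic$GPP, ls$dynamic$ET)
  cols <- list(
    TEM = pm("TEM"), PRE = pm("PRE"), ET = pm("ET"),
    SPEI_F = spei_f, EL = ls$static$EL, SL = ls$static$SL,
    NDVI = pm("NDVI"), WUE = apply(wue, c(1, 2), mean),
    SOC = pm("SOC"), RSMC = pm("RSMC"),
    GDP = pm("GDP"), POP = pm("POP"))
  x <- do.call(cbind, lapply(cols, as.vector))
  colnames(x) <- names(cols)
  keep <- rowSums(is.na(x)) == 0
  list(x = x[keep, , drop = FALSE], cells = which(keep))
}
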