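# Synthetic landscape generator.
#
# Produces a seeded multi-year gridded dataset with the statistical structure
# the downstream analysis assumes: planted drought years (low SPEI), planted
# hump-shaped upper boundaries of each ecosystem service against SPEI per
# land-use type, linear trends on selected driver variables, a four-component
# bundle mixture in (WR, SC, CS, FS, drought-frequency) space with recorded
# true labels, and drought-stratified cross-service correlations.
#
# Driver rasters are back-solved from the planted service targets through the
# exact service equations, so every formula stage recovers the planted values.

LAND_USE_LEVELS <- c("cropland", "forest", "grassland", "shrub", "other")
ES_NAMES <- c("wr", "sc", "cs", "fs")
DYNAMIC_VARS <- c("SPEI", "PRE", "TEM", "ET", "GPP", "NPP", "NDVI", "SOC",
                  "RSMC", "Yield", "R", "POP", "GDP")
STATIC_VARS <- c("Ks", "TI", "Velocity", "K", "L", "S", "C", "P", "EL", "SL")

#' Default constraint-boundary parameters per (service, land use)
#'
#' Quadratic hump \eqn{g(x) = h \, \max(1 - \kappa (x - x^*)^2,\ 0.05)}
#' giving the maximum attainable service value at SPEI = x. Apex locations
#' default to the published pattern: boundaries peak under non-drought
#' conditions (apex SPEI mostly above -0.5), with forest water retention and
#' soil conservation peaking at SPEI 0.81 and 0.96.
#'
#' @return data.frame with columns es, land_use, apex, height, kappa.
#' @export
default_boundary_spec <- function() {
  spec <- rbind(
    data.frame(es = "wr", land_use = LAND_USE_LEVELS,
               apex = c(0.30, 0.81, 0.20, 0.40, 0.00),
               height = c(600, 900, 500, 550, 300)),
    data.frame(es = "sc", land_use = LAND_USE_LEVELS,
               apex = c(0.25, 0.96, 0.15, 0.35, 0.00),
               height = c(400, 1200, 600, 800, 100)),
    data.frame(es = "cs", land_use = LAND_USE_LEVELS,
               apex = c(0.10, 0.50, 0.20, 0.30, 0.00),
               height = c(1000, 1600, 1100, 1200, 300)),
    data.frame(es = "fs", land_use = LAND_USE_LEVELS,
               apex = c(0.20, NA, NA, NA, NA),
               height = c(220, 0, 0, 0, 0))
  )
  spec$kappa <- 0.10
  spec
}

#' Default bundle centroids (service levels)
#'
#' Four bundles expressed as mean service *levels* in (0, 1): the fraction of
#' the local boundary height a cell attains. B1 is a conservation bundle
#' (high WR/SC), B2 a fragile low-service bundle, B3 an agricultural bundle
#' (high FS), B4 a carbon-stable bundle.
#'
#' @return 4 x 4 matrix, rows B1..B4, columns wr, sc, cs, fs.
#' @export
default_bundle_levels <- function() {
  m <- rbind(
    B1 = c(wr = 0.75, sc = 0.75, cs = 0.65, fs = 0.25),
    B2 = c(wr = 0.30, sc = 0.28, cs = 0.32, fs = 0.30),
    B3 = c(wr = 0.45, sc = 0.40, cs = 0.50, fs = 0.75),
    B4 = c(wr = 0.58, sc = 0.62, cs = 0.75, fs = 0.40)
  )
  colnames(m) <- ES_NAMES
  m
}

default_landuse_by_bundle <- function() {
  m <- rbind(
    B1 = c(cropland = 0.10, forest = 0.55, grassland = 0.15, shrub = 0.12, other = 0.08),
    B2 = c(cropland = 0.10, forest = 0.20, grassland = 0.40, shrub = 0.20, other = 0.10),
    B3 = c(cropland = 0.75, forest = 0.05, grassland = 0.10, shrub = 0.05, other = 0.05),
    B4 = c(cropland = 0.15, forest = 0.45, grassland = 0.25, shrub = 0.10, other = 0.05)
  )
  m
}

default_stratum_by_bundle <- function() {
  # Rows: bundles; columns: drought-proneness strata (none..extreme).
  m <- rbind(
    B1 = c(0.35, 0.30, 0.20, 0.10, 0.05),
    B2 = c(0.55, 0.25, 0.12, 0.05, 0.03),
    B3 = c(0.25, 0.30, 0.25, 0.12, 0.08),
    B4 = c(0.10, 0.20, 0.25, 0.25, 0.20)
  )
  colnames(m) <- c("none", "slight", "medium", "serious", "extreme")
  m
}

default_noise_spec <- function() {
  list(
    spei_cell = 0.05,   # cell-level SPEI jitter around the annual value
    es_year   = 0.03,   # year-to-year jitter of a cell's service level
    ndvi      = 0.02,
    tem       = 0.30,   # degC
    pre       = 40,     # mm
    soc       = 1.00,   # g/kg
    rsmc      = 0.03,
    el        = 150,    # m
    sl        = 1.00    # degrees
  )
}

#' Configuration of the synthetic landscape generator
#'
#' The defaults state the emulated world once: a 23-year (2000-2022) annual
#' record, two forced drought years (2011 and 2022, the study period's
#' observed drought years), quadratic hump boundaries of each service against
#' SPEI peaking under non-drought conditions, four service bundles, and a
#' planted trade-off between water retention and food supply within the
#' extreme-drought stratum (r = -0.25).
#'
#' @param n_rows,n_cols grid dimensions (cells).
#' @param n_years number of annual steps (>= 3), mapped to calendar years
#'   `start_year + 0:(n_years-1)`.
#' @param cell_km cell edge length in km (all cells share one size).
#' @param seed integer seed; identical config + seed gives bit-identical output.
#' @param start_year first calendar year label.
#' @param drought_years calendar years forced into meteorological drought
#'   (grid-mean SPEI below -1).
#' @param n_zones number of municipal zones (laid out as contiguous
#'   rectangular blocks; the realized count is the nearest feasible block
#'   grid, reported in the dataset).
#' @param invalid_fraction fraction of cells marked invalid everywhere.
#' @param mixing_fractions length-4 bundle mixing weights (sum to 1).
#' @param bundle_levels 4 x 4 matrix of bundle mean service levels in (0, 1),
#'   see [default_bundle_levels()].
#' @param landuse_by_bundle 4 x 5 row-stochastic matrix P(land use | bundle).
#' @param stratum_by_bundle 4 x 5 row-stochastic matrix P(drought stratum |
#'   bundle); strata order none..extreme.
#' @param boundary_spec data.frame as [default_boundary_spec()].
#' @param trend_spec named per-year linear slopes planted on driver variables
#'   (supported names: NDVI, TEM, PRE, SOC, SPEI).
#' @param noise_spec named list of noise SDs, see [default_noise_spec()];
#'   all zero gives a fully deterministic smooth landscape.
#' @param tradeoff_spec named list: per stratum name, a named numeric vector
#'   of target Pearson correlations between service pairs ("wr_fs" etc.)
#'   among that stratum's cells (pairs involving fs are planted conditional
#'   on cropland, where food supply is defined).
#' @param level_sd SD of cell service levels around their bundle centroid.
#' @param envelope_fraction fraction of cell-years drawn from the dense
#'   upper-envelope component (Beta(shape, 1)) so the constraint boundary is
#'   well populated.
#' @param envelope_shape Beta shape parameter of the envelope component.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 60, n_cols = 60, n_years = 23,
                             cell_km = 1, seed = 42, start_year = 2000,
                             drought_years = c(2011, 2022),
                             n_zones = 9, invalid_fraction = 0.02,
                             mixing_fractions = c(B1 = 0.30, B2 = 0.15,
                                                  B3 = 0.30, B4 = 0.25),
                             bundle_levels = default_bundle_levels(),
                             landuse_by_bundle = default_landuse_by_bundle(),
                             stratum_by_bundle = default_stratum_by_bundle(),
                             boundary_spec = default_boundary_spec(),
                             trend_spec = c(NDVI = 0.002, TEM = 0.01),
                             noise_spec = default_noise_spec(),
                             tradeoff_spec = list(extreme = c(wr_fs = -0.25)),
                             level_sd = 0.12,
                             envelope_fraction = 0.05,
                             envelope_shape = 20) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              n_years = as.integer(n_years), cell_km = cell_km,
              seed = as.integer(seed), start_year = as.integer(start_year),
              drought_years = as.integer(drought_years),
              n_zones = as.integer(n_zones),
              invalid_fraction = invalid_fraction,
              mixing_fractions = mixing_fractions,
              bundle_levels = bundle_levels,
              landuse_by_bundle = landuse_by_bundle,
              stratum_by_bundle = stratum_by_bundle,
              boundary_spec = boundary_spec,
              trend_spec = trend_spec,
              noise_spec = utils::modifyList(default_noise_spec(),
                                             as.list(noise_spec)),
              tradeoff_spec = tradeoff_spec,
              level_sd = level_sd,
              envelope_fraction = envelope_fraction,
              envelope_shape = envelope_shape)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop_esd("esd_config_error", "invalid config field '%s': %s", field, msg)
  }
  chk(cfg$n_rows >= 1, "n_rows", "must be a positive count")
  chk(cfg$n_cols >= 1, "n_cols", "must be a positive count")
  chk(cfg$n_years >= 3, "n_years", "must be >= 3")
  chk(cfg$cell_km > 0, "cell_km", "must be positive")
  chk(cfg$n_zones >= 1, "n_zones", "must be a positive count")
  chk(cfg$invalid_fraction >= 0 && cfg$invalid_fraction < 1,
      "invalid_fraction", "must be in [0, 1)")
  chk(abs(sum(cfg$mixing_fractions) - 1) < 1e-8,
      "mixing_fractions", "must sum to 1")
  chk(all(cfg$mixing_fractions >= 0), "mixing_fractions", "must be non-negative")
  chk(all(unlist(cfg$noise_spec) >= 0), "noise_spec", "SDs must be >= 0")
  chk(all(abs(rowSums(cfg$landuse_by_bundle) - 1) < 1e-8),
      "landuse_by_bundle", "rows must sum to 1")
  chk(all(abs(rowSums(cfg$stratum_by_bundle) - 1) < 1e-8),
      "stratum_by_bundle", "rows must sum to 1")
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  chk(all(cfg$drought_years %in% years), "drought_years",
      "must fall inside the simulated calendar span")
  for (sname in names(cfg$tradeoff_spec %||% list())) {
    chk(sname %in% colnames(cfg$stratum_by_bundle), "tradeoff_spec",
        sprintf("unknown stratum '%s'", sname))
    pairs <- strsplit(names(cfg$tradeoff_spec[[sname]]), "_", fixed = TRUE)
    chk(all(unlist(pairs) %in% ES_NAMES), "tradeoff_spec",
        "pair names must combine wr, sc, cs, fs as '<a>_<b>'")
  }
  chk(cfg$level_sd > 0, "level_sd", "must be positive")
  chk(cfg$envelope_fraction >= 0 && cfg$envelope_fraction <= 1,
      "envelope_fraction", "must be in [0, 1]")
  invisible(cfg)
}

# Mean SPEI targets of each proneness stratum in a forced drought year, and
# the stratum's mild SPEI offset in ordinary years. Targets sit safely inside
# the default severity classes (none > -0.5 ... extreme <= -2) so planted
# stratum labels match realized classifications.
STRATUM_DROUGHT_TARGET <- c(none = -0.35, slight = -0.90, medium = -1.40,
                            serious = -1.90, extreme = -2.40)
STRATUM_BASE_OFFSET <- c(none = 0.50, slight = 0.25, medium = 0.00,
                         serious = -0.25, extreme = -0.50)

# Quadratic hump boundary (floored at 5% of height so services stay positive).
boundary_value <- function(x, apex, height, kappa) {
  height * pmax(1 - kappa * (x - apex)^2, 0.05)
}

boundary_lookup <- function(spec, es) {
  sub <- spec[spec$es == es, , drop = FALSE]
  rownames(sub) <- sub$land_use
  sub
}

# Solve, from the mixture algebra, the latent Gaussian correlation rho* that
# yields the requested within-stratum Pearson correlation rho_t of cell
# service levels, accounting for the covariance already induced by the
# bundle centroids:
#   rho* = (rho_t * sqrt(Vp Vq) - Cov_bundle) / level_sd^2
# with Vp = Var_bundle(m_p) + level_sd^2 under the bundle distribution
# conditional on the stratum (and on cropland for pairs involving fs).
solve_latent_rho <- function(cfg, stratum, pair, rho_t) {
  p <- pair[1]; q <- pair[2]
  s_idx <- match(stratum, colnames(cfg$stratum_by_bundle))
  w <- cfg$mixing_fractions * cfg$stratum_by_bundle[, s_idx]
  if ("fs" %in% pair) w <- w * cfg$landuse_by_bundle[, "cropland"]
  w <- w / sum(w)
  mp <- cfg$bundle_levels[, p]; mq <- cfg$bundle_levels[, q]
  mbar_p <- sum(w * mp); mbar_q <- sum(w * mq)
  cb <- sum(w * mp * mq) - mbar_p * mbar_q
  vp <- sum(w * mp^2) - mbar_p^2 + cfg$level_sd^2
  vq <- sum(w * mq^2) - mbar_q^2 + cfg$level_sd^2
  rho_star <- (rho_t * sqrt(vp * vq) - cb) / cfg$level_sd^2
  if (abs(rho_star) > 0.99) {
    warning(sprintf(
      "tradeoff_spec %s/%s-%s: requested r = %.3f needs latent rho %.3f; clamped",
      stratum, p, q, rho_t, rho_star))
    rho_star <- clamp(rho_star, -0.99, 0.99)
  }
  rho_star
}

#' Generate a synthetic landscape dataset
#'
#' @param config a [synthetic_config()].
#' @return object of class `landscape`: a list with grid dimensions, calendar
#'   `years`, `dynamic` (named list of row x col x year arrays), `static`
#'   (named list of matrices), `land_use` and `zones` integer matrices,
#'   `zone_grain_yield` table, the validity `mask`, and `truth` (planted
#'   bundle/stratum labels, cell service levels, solved latent correlations)
#'   for validation of downstream stages.
#' @export
generate_landscape <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  set.seed(cfg$seed)
  nr <- cfg$n_rows; nc <- cfg$n_cols; ny <- cfg$n_years
  ncell <- nr * nc
  years <- cfg$start_year + seq_len(ny) - 1L
  drought_idx <- match(cfg$drought_years, years)
  noise <- cfg$noise_spec
  trend <- cfg$trend_spec
  tr <- function(v) if (v %in% names(trend)) trend[[v]] else 0
  tindex <- seq_len(ny) - 1L

  mask <- matrix(runif(ncell) >= cfg$invalid_fraction, nr, nc)

  # --- categorical cell structure -----------------------------------------
  bundle <- sample.int(4L, ncell, replace = TRUE, prob = cfg$mixing_fractions)
  stratum <- integer(ncell)
  lu <- integer(ncell)
  for (b in 1:4) {
    idx <- which(bundle == b)
    stratum[idx] <- sample.int(5L, length(idx), replace = TRUE,
                               prob = cfg$stratum_by_bundle[b, ])
    lu[idx] <- sample.int(5L, length(idx), replace = TRUE,
                          prob = cfg$landuse_by_bundle[b, ])
  }

  # Municipal zones: contiguous rectangular blocks.
  zr <- max(1L, floor(sqrt(cfg$n_zones)))
  zc <- max(1L, ceiling(cfg$n_zones / zr))
  zone_row <- pmin(ceiling(seq_len(nr) / ceiling(nr / zr)), zr)
  zone_col <- pmin(ceiling(seq_len(nc) / ceiling(nc / zc)), zc)
  zones <- matrix(as.integer(outer(zone_row, zone_col,
                                   function(r, c) (r - 1L) * zc + c)), nr, nc)

  # --- per-cell service levels with planted cross-service correlation -----
  z <- matrix(rnorm(ncell * 4L), ncell, 4L, dimnames = list(NULL, ES_NAMES))
  solved_rho <- list()
  for (sname in names(cfg$tradeoff_spec %||% list())) {
    targets <- cfg$tradeoff_spec[[sname]]
    s_idx <- match(sname, colnames(cfg$stratum_by_bundle))
    if (is.na(s_idx)) {
      stop_esd("esd_config_error",
               "invalid config field 'tradeoff_spec': unknown stratum '%s'", sname)
    }
    cells <- which(stratum == s_idx)
    for (pname in names(targets)) {
      pair <- strsplit(pname, "_", fixed = TRUE)[[1]]
      if (!all(pair %in% ES_NAMES)) {
        stop_esd("esd_config_error",
                 "invalid config field 'tradeoff_spec': unknown pair '%s'", pname)
      }
      rho_star <- solve_latent_rho(cfg, sname, pair, targets[[pname]])
      solved_rho[[paste(sname, pname, sep = ".")]] <- rho_star
      z[cells, pair[2]] <- rho_star * z[cells, pair[1]] +
        sqrt(1 - rho_star^2) * z[cells, pair[2]]
    }
  }
  levels_u <- cfg$bundle_levels[bundle, , drop = FALSE] + cfg$level_sd * z
  levels_u <- clamp(levels_u, 0.01, 0.995)

  # --- SPEI ----------------------------------------------------------------
  year_base <- rnorm(ny, 0.10, 0.35) + tr("SPEI") * tindex
  cell_offset <- STRATUM_BASE_OFFSET[stratum]
  cell_target <- STRATUM_DROUGHT_TARGET[stratum]
  spei <- matrix(0, ncell, ny)
  for (t in seq_len(ny)) {
    base <- if (t %in% drought_idx) cell_target else year_base[t] + cell_offset
    spei[, t] <- base + rnorm(ncell, 0, noise$spei_cell)
  }

  # --- service targets under the planted boundaries -----------------------
  lu_names <- LAND_USE_LEVELS[lu]
  es_target <- list()
  for (es in ES_NAMES) {
    bs <- boundary_lookup(cfg$boundary_spec, es)[lu_names, ]
    g <- boundary_value(spei, bs$apex, bs$height, bs$kappa)
    g[is.na(g)] <- 0  # land uses without a defined boundary supply nothing
    u_year <- clamp(levels_u[, es] + matrix(rnorm(ncell * ny, 0, noise$es_year),
                                            ncell, ny), 0, 1)
    if (cfg$envelope_fraction > 0) {
      env <- matrix(rbinom(ncell * ny, 1L, cfg$envelope_fraction) == 1L, ncell, ny)
      u_year[env] <- rbeta(sum(env), cfg$envelope_shape, 1)
    }
    tgt <- g * u_year
    if (es == "fs") tgt[lu != 1L, ] <- 0  # food supply only on cropland
    es_target[[es]] <- tgt
  }

  # --- back-solved driver rasters ------------------------------------------
  static <- list()
  static$Velocity <- matrix(runif(ncell, 150, 500), nr, nc)
  static$TI <- matrix(runif(ncell, 2, 5), nr, nc)
  static$Ks <- matrix(runif(ncell, 120, 450), nr, nc)
  atten <- pmin(1, 249 / static$Velocity) * pmin(1, 0.9 * static$TI / 3) *
    pmin(1, static$Ks / 300)
  static$K <- matrix(runif(ncell, 0.15, 0.45), nr, nc)
  static$L <- matrix(runif(ncell, 1, 3), nr, nc)
  static$S <- matrix(runif(ncell, 1, 8), nr, nc)
  static$C <- matrix(runif(ncell, 0.05, 0.8), nr, nc)
  static$P <- matrix(ifelse(lu == 1L, runif(ncell, 0.3, 0.9), 1), nr, nc)
  el_mean <- c(500, 3500, 300, 1800)[bundle]
  static$EL <- matrix(pmax(el_mean + rnorm(ncell, 0, noise$el), 0), nr, nc)
  static$SL <- matrix(clamp(2.5 * as.vector(static$S) + rnorm(ncell, 0, noise$sl),
                            0.1, 45), nr, nc)

  dyn <- lapply(stats::setNames(DYNAMIC_VARS, DYNAMIC_VARS),
                function(v) array(NA_real_, c(nr, nc, ny)))
  to_arr <- function(m) array(m, c(nr, nc, ny))
  dyn$SPEI <- to_arr(spei)
  dyn$Yield <- to_arr(es_target$wr / as.vector(atten))
  sc_denom <- as.vector(static$K * static$L * static$S *
                          (1 - static$P * static$C))
  dyn$R <- to_arr(es_target$sc / sc_denom)
  dyn$NPP <- to_arr(es_target$cs / 1.63)
  gpp_fac <- runif(ncell, 1.8, 2.2)
  dyn$GPP <- to_arr(es_target$cs / 1.63 * gpp_fac)
  wue_level <- 0.8 + 2 * levels_u[, "cs"]
  dyn$ET <- dyn$GPP / wue_level

  # Climate: drought cell-years sit in the hot/dry regime (23-25 degC,
  # 400-600 mm) that the binned SPEI surface is expected to isolate.
  tem_base <- runif(ncell, 13.5, 16.5)
  pre_base <- 750 + 600 * levels_u[, "wr"]
  tem <- matrix(0, ncell, ny); pre <- matrix(0, ncell, ny)
  for (t in seq_len(ny)) {
    dry <- spei[, t] <= -0.5
    tem[, t] <- ifelse(dry, runif(ncell, 23, 25),
                       tem_base + tr("TEM") * tindex[t] +
                         rnorm(ncell, 0, noise$tem))
    pre[, t] <- ifelse(dry, runif(ncell, 400, 600),
                       pmax(pre_base + tr("PRE") * tindex[t] +
                              rnorm(ncell, 0, noise$pre), 0))
  }
  dyn$TEM <- to_arr(tem)
  dyn$PRE <- to_arr(pre)

  soc_base <- 4 + 18 * levels_u[, "sc"]
  rsmc_base <- 0.5 + 0.25 * cell_offset
  soc <- matrix(0, ncell, ny); rsmc <- matrix(0, ncell, ny)
  ndvi <- matrix(0, ncell, ny)
  ndvi_base <- 0.25 + 0.5 * (levels_u[, "sc"] + levels_u[, "cs"]) / 2
  for (t in seq_len(ny)) {
    soc[, t] <- pmax(soc_base + tr("SOC") * tindex[t] +
                       rnorm(ncell, 0, noise$soc), 0)
    rsmc[, t] <- clamp(rsmc_base + 0.05 * pmin(spei[, t], 1) +
                         rnorm(ncell, 0, noise$rsmc), 0.02, 0.98)
    ndvi[, t] <- clamp(ndvi_base + tr("NDVI") * tindex[t] +
                         rnorm(ncell, 0, noise$ndvi), -1, 1)
  }
  dyn$SOC <- to_arr(soc)
  dyn$RSMC <- to_arr(rsmc)

  pop_base <- rlnorm(ncell, meanlog = 3, sdlog = 1)
  dyn$POP <- to_arr(outer(pop_base, 1.015^tindex))
  gdp_fac <- runif(ncell, 2, 6)
  dyn$GDP <- to_arr(outer(pop_base * gdp_fac, 1.04^tindex))

  # Cropland NDVI carries the food-supply spatial pattern so that
  # NDVI-proportional allocation of the zone totals reproduces the planted
  # per-cell targets exactly; elsewhere NDVI follows its planted trend.
  cell_area <- cfg$cell_km^2
  crop <- lu == 1L & as.vector(mask)
  zvec <- as.vector(zones)
  zone_ids <- sort(unique(zvec))
  p_sum <- matrix(0, length(zone_ids), ny, dimnames = list(zone_ids, years))
  for (t in seq_len(ny)) {
    fs_t <- es_target$fs[, t] * cell_area  # t per pixel
    tot <- vapply(zone_ids, function(z) sum(fs_t[crop & zvec == z]), 0)
    p_sum[, t] <- tot
    for (z in zone_ids) {
      zc_idx <- which(crop & zvec == z)
      if (!length(zc_idx)) next
      mx <- max(fs_t[zc_idx])
      ndvi[zc_idx, t] <- if (mx > 0)
        pmax(0.9 * fs_t[zc_idx] / mx, 0.02) else 0.02
    }
  }
  dyn$NDVI <- to_arr(ndvi)

  zone_grain_yield <- data.frame(
    zone_id = rep(as.integer(zone_ids), times = ny),
    year = rep(as.integer(years), each = length(zone_ids)),
    p_sum_t = as.vector(p_sum)
  )

  # --- apply the shared validity mask --------------------------------------
  invalid <- !mask
  for (v in names(dyn)) {
    a <- dyn[[v]]
    a[rep(as.vector(invalid), ny)] <- NA_real_
    dimnames(a) <- list(NULL, NULL, years)
    dyn[[v]] <- a
  }
  for (v in names(static)) static[[v]][invalid] <- NA_real_
  land_use <- matrix(lu, nr, nc); land_use[invalid] <- NA_integer_
  zones_m <- zones; zones_m[invalid] <- NA_integer_
  bundle_m <- matrix(bundle, nr, nc); bundle_m[invalid] <- NA_integer_
  stratum_m <- matrix(stratum, nr, nc); stratum_m[invalid] <- NA_integer_
  levels_mats <- lapply(stats::setNames(ES_NAMES, ES_NAMES), function(es) {
    m <- matrix(levels_u[, es], nr, nc); m[invalid] <- NA_real_; m
  })

  structure(list(
    n_rows = nr, n_cols = nc, n_years = ny, years = years,
    cell_km = cfg$cell_km,
    dynamic = dyn, static = static,
    land_use = land_use, land_use_levels = LAND_USE_LEVELS,
    zones = zones_m, zone_grain_yield = zone_grain_yield,
    mask = mask,
    truth = list(bundle = bundle_m, stratum = stratum_m,
                 stratum_levels = colnames(cfg$stratum_by_bundle),
                 levels = levels_mats, solved_rho = solved_rho,
                 year_base = year_base),
    config = cfg
  ), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d cells (%g km), %d years (%d-%d)\n",
              x$n_rows, x$n_cols, x$cell_km, x$n_years,
              min(x$years), max(x$years)))
  cat(sprintf("  dynamic: %s\n", paste(names(x$dynamic), collapse = ", ")))
  cat(sprintf("  static:  %s\n", paste(names(x$static), collapse = ", ")))
  cat(sprintf("  valid cells: %d/%d; zones: %d\n",
              sum(x$mask), length(x$mask),
              length(unique(stats::na.omit(as.vector(x$zones))))))
  invisible(x)
}

#' Water-use efficiency from productivity and evapotranspiration
#'
#' WUE = GPP / ET, the ratio of gross primary productivity to actual
#' evapotranspiration. Cells with ET = 0 are marked invalid (NA); ET must be
#' non-negative wherever valid.
#'
#' @param gpp,et co-registered matrices or arrays (same shape).
#' @return grid of the same shape.
#' @export
derive_wue <- function(gpp, et) {
  if (!identical(dim(gpp), dim(et))) {
    stop_esd("esd_dim_error", "GPP and ET grids differ in shape")
  }
  if (any(et < 0, na.rm = TRUE)) {
    stop_esd("esd_domain_error", "ET must be >= 0 on valid cells")
  }
  out <- gpp / et
  out[!is.na(et) & et == 0] <- NA_real_
  out
}

#' Simulate a constraint-bounded scatter
#'
#' Draws `n` points whose response lies at or below a planted quadratic hump
#' boundary \eqn{g(x) = h\,\max(1-\kappa(x-x^*)^2, 0.05)}: x uniform over
#' `x_range`, response `g(x) * U` with `U ~ Beta(shape, 1)` so the upper
#' envelope is densely populated, plus optional Gaussian measurement noise.
#' Used to exercise boundary extraction and threshold recovery in isolation.
#'
#' @param n number of points.
#' @param apex boundary apex location x*.
#' @param height apex height h.
#' @param kappa curvature.
#' @param x_range length-2 range of the constraining variable.
#' @param noise_sd SD of additive response noise.
#' @param envelope_shape Beta shape of the envelope draw.
#' @param seed optional integer seed.
#' @return data.frame with columns x, y and attribute `boundary` (function).
#' @export
simulate_constraint_scatter <- function(n, apex, height = 1, kappa = 0.15,
                                        x_range = c(-2.5, 2.5), noise_sd = 0,
                                        envelope_shape = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- runif(n, x_range[1], x_range[2])
  g <- boundary_value(x, apex, height, kappa)
  y <- g * rbeta(n, envelope_shape, 1)
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  out <- data.frame(x = x, y = y)
  attr(out, "boundary") <- function(xx) boundary_value(xx, apex, height, kappa)
  out
}
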