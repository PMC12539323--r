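# The four ecosystem-service models, per cell and year.
#
# Water retention: InVEST-style retention adjustment of water yield,
#   Retention = min(1, 249/Velocity) * min(1, 0.9*TI/3) * min(1, Ks/300) * Yield
# Soil conservation: RUSLE, Q_sc = R*K*L*S*(1 - P*C) as printed in the source
#   method (a "textbook" (1-C)(1-P) variant is provided as an option).
# Carbon sequestration: G_V = 1.63 * A * NPP, reported per area as 1.63 * NPP
#   (1 g m^-2 == 1 t km^-2).
# Food supply: municipal grain totals disaggregated to cropland cells in
#   proportion to NDVI, P_i = NDVI_i / NDVI_sum * P_sum.

#' Water retention from water yield and attenuation factors
#'
#' Retention (mm) is the InVEST water yield attenuated by three terms each
#' clamped to \[0, 1\]: flow velocity `min(1, 249/Velocity)`, topographic
#' index `min(1, 0.9 * TI / 3)`, and saturated hydraulic conductivity
#' `min(1, Ks / 300)`. Retention never exceeds Yield.
#'
#' @param velocity dimensionless flow-velocity coefficient, > 0 on valid cells.
#' @param ti dimensionless topographic index.
#' @param ks saturated hydraulic conductivity (cm/d), >= 0.
#' @param yield_ water yield (mm), >= 0.
#' @return grid of retention (mm), same shape as the inputs.
#' @export
compute_water_retention <- function(velocity, ti, ks, yield_) {
  check_same_shape(velocity, ti, ks, yield_,
                   .names = c("velocity", "ti", "ks", "yield"))
  if (any(velocity <= 0, na.rm = TRUE)) {
    stop_esd("esd_domain_error", "velocity must be > 0 on valid cells")
  }
  pmin(1, 249 / velocity) * pmin(1, 0.9 * ti / 3) * pmin(1, ks / 300) * yield_
}

#' Soil conservation from RUSLE factors
#'
#' `Q_sc = R * K * L * S * (1 - P * C)` with the cover (C) and practice (P)
#' factors in \[0, 1\]. `variant = "textbook"` applies `(1 - C) * (1 - P)`
#' instead of the printed `(1 - P * C)` form.
#'
#' @param r rainfall erosivity, MJ mm (hm^2 h a)^-1.
#' @param k soil erodibility, t h (MJ mm)^-1.
#' @param l,s slope-length and slope factors (dimensionless).
#' @param c_,p_ cover and practice factors in \[0, 1\].
#' @param variant `"printed"` (default) or `"textbook"`.
#' @return grid of soil conservation, t (hm^2 a)^-1.
#' @export
compute_soil_conservation <- function(r, k, l, s, c_, p_,
                                      variant = c("printed", "textbook")) {
  variant <- match.arg(variant)
  check_same_shape(r, k, l, s, c_, p_,
                   .names = c("r", "k", "l", "s", "c", "p"))
  if (any(c_ < 0 | c_ > 1, na.rm = TRUE)) {
    stop_esd("esd_domain_error", "cover factor C must lie in [0, 1]")
  }
  if (any(p_ < 0 | p_ > 1, na.rm = TRUE)) {
    stop_esd("esd_domain_error", "practice factor P must lie in [0, 1]")
  }
  adj <- switch(variant,
                printed = 1 - p_ * c_,
                textbook = (1 - c_) * (1 - p_))
  r * k * l * s * adj
}

#' Carbon sequestration from net primary productivity
#'
#' `G_V = 1.63 * A * NPP`. With NPP in g m^-2 a^-1 (numerically equal to
#' t km^-2 a^-1) the per-area form is `1.63 * NPP` in t km^-2; the per-cell
#' total multiplies by the cell area in km^2.
#'
#' @param npp net primary productivity grid (g m^-2 a^-1), >= 0 on valid cells.
#' @param cell_area_km2 cell area A (km^2); only used for `output = "total"`.
#' @param output `"density"` (t km^-2, default) or `"total"` (t per cell).
#' @return grid of carbon sequestration.
#' @export
compute_carbon_sequestration <- function(npp, cell_area_km2 = 1,
                                         output = c("density", "total")) {
  output <- match.arg(output)
  if (any(npp < 0, na.rm = TRUE)) {
    stop_esd("esd_domain_error", "NPP must be >= 0 on valid cells")
  }
  cs <- 1.63 * npp
  if (output == "total") cs <- cs * cell_area_km2
  cs
}

#' Allocate municipal grain totals to cropland cells by NDVI share
#'
#' Within each zone and year, total grain yield `P_sum` (t) is split over the
#' zone's cropland cells proportionally to their NDVI:
#' `P_i = NDVI_i / NDVI_sum * P_sum`. Non-cropland cells receive 0. Mass is
#' conserved exactly per zone-year. Cropland cells with negative NDVI are
#' excluded from `NDVI_sum` (and receive 0) rather than clipped, which keeps
#' allocations non-negative while preserving conservation; such cells are
#' reported via a warning.
#'
#' @param ndvi NDVI matrix for one year (values in \[-1, 1\]).
#' @param land_use integer land-use matrix; `cropland_code` marks cropland.
#' @param zones integer zone-id matrix.
#' @param zone_totals data.frame with columns `zone_id` and `p_sum_t` (t)
#'   for this year (a `year` column, if present, must be single-valued).
#' @param cell_area_km2 if non-NULL, divide by the cell area to report food
#'   supply as a density (t km^-2) instead of t per pixel.
#' @param cropland_code integer code of cropland in `land_use` (default 1).
#' @return matrix of allocated grain yield (t per pixel, or t km^-2).
#' @export
allocate_food_supply <- function(ndvi, land_use, zones, zone_totals,
                                 cell_area_km2 = NULL, cropland_code = 1L) {
  check_same_shape(ndvi, land_use, zones, .names = c("ndvi", "land_use", "zones"))
  if (!is.null(zone_totals$year) && length(unique(zone_totals$year)) > 1) {
    stop_esd("esd_config_error",
             "zone_totals spans multiple years; pass one year at a time")
  }
  out <- matrix(0, nrow(ndvi), ncol(ndvi))
  out[is.na(land_use)] <- NA_real_
  crop <- !is.na(land_use) & land_use == cropland_code
  neg <- crop & !is.na(ndvi) & ndvi < 0
  if (any(neg)) {
    warning(sprintf(
      "%d cropland cell(s) with negative NDVI excluded from allocation",
      sum(neg)))
  }
  use <- crop & !neg & !is.na(ndvi)
  totals <- stats::setNames(zone_totals$p_sum_t, zone_totals$zone_id)
  present <- unique(zones[!is.na(zones)])
  missing <- setdiff(present, as.integer(names(totals)))
  if (length(missing)) {
    stop_esd("esd_alloc_error", "zone_totals missing zone(s): %s",
             paste(missing, collapse = ", "))
  }
  for (z in present) {
    p_sum <- totals[[as.character(z)]]
    inz <- use & !is.na(zones) & zones == z
    if (p_sum == 0) next
    ndvi_sum <- sum(ndvi[inz])
    if (!any(inz) || ndvi_sum <= 0) {
      stop_esd("esd_alloc_error",
               "zone %s has grain yield %g t but no positive cropland NDVI",
               z, p_sum)
    }
    out[inz] <- ndvi[inz] / ndvi_sum * p_sum
  }
  if (!is.null(cell_area_km2)) out <- out / cell_area_km2
  out
}

#' Compute the four ecosystem services for every year of a landscape
#'
#' Applies the four service models to a (typically synthetic) landscape,
#' returning co-registered annual stacks: water retention WR (mm), soil
#' conservation SC (t hm^-2 a^-1), carbon sequestration CS (t km^-2), and
#' food supply FS (t km^-2).
#'
#' @param landscape a `landscape` object (see [generate_landscape()] and
#'   [read_landscape()]).
#' @param rusle_variant `"printed"` or `"textbook"`, see
#'   [compute_soil_conservation()].
#' @return object of class `es_stack`: list of four row x col x year arrays
#'   (`wr`, `sc`, `cs`, `fs`) plus `years` and `cell_km`.
#' @export
compute_es_stack <- function(landscape, rusle_variant = "printed") {
  ls <- landscape
  ny <- ls$n_years
  area <- ls$cell_km^2
  wr <- sc <- cs <- fs <- array(NA_real_, c(ls$n_rows, ls$n_cols, ny))
  for (t in seq_len(ny)) {
    wr[, , t] <- compute_water_retention(ls$static$Velocity, ls$static$TI,
                                         ls$static$Ks, ls$dynamic$Yield[, , t])
    sc[, , t] <- compute_soil_conservation(ls$dynamic$R[, , t], ls$static$K,
                                           ls$static$L, ls$static$S,
                                           ls$static$C, ls$static$P,
                                           variant = rusle_variant)
    cs[, , t] <- compute_carbon_sequestration(ls$dynamic$NPP[, , t])
    zt <- ls$zone_grain_yield[ls$zone_grain_yield$year == ls$years[t], ]
    fs[, , t] <- allocate_food_supply(ls$dynamic$NDVI[, , t], ls$land_use,
                                      ls$zones, zt, cell_area_km2 = area)
  }
  dn <- list(NULL, NULL, ls$years)
  dimnames(wr) <- dimnames(sc) <- dimnames(cs) <- dimnames(fs) <- dn
  structure(list(wr = wr, sc = sc, cs = cs, fs = fs,
                 years = ls$years, cell_km = ls$cell_km),
            class = "es_stack")
}

#' @export
print.es_stack <- function(x, ...) {
  d <- dim(x$wr)
  cat(sprintf("<es_stack> %d x %d cells, %d years (%d-%d)\n",
              d[1], d[2], d[3], min(x$years), max(x$years)))
  for (es in ES_NAMES) {
    cat(sprintf("  %s: mean %.2f\n", toupper(es), mean(x[[es]], na.rm = TRUE)))
  }
  invisible(x)
}

#' Period-mean service grids
#'
#' @param es an `es_stack`.
#' @return named list of matrices (mean over years per cell).
#' @export
es_period_means <- function(es) {
  lapply(stats::setNames(ES_NAMES, ES_NAMES),
         function(v) apply(es[[v]], c(1, 2), mean))
}

#' Per-zone annual service summary
#'
#' @param es an `es_stack`.
#' @param zones integer zone matrix.
#' @return data.frame with zone_id, year and the mean of each service.
#' @export
summarize_es_by_zone <- function(es, zones) {
  zvec <- as.vector(zones)
  rows <- list()
  for (t in seq_along(es$years)) {
    d <- data.frame(zone_id = zvec,
                    wr = as.vector(es$wr[, , t]), sc = as.vector(es$sc[, , t]),
                    cs = as.vector(es$cs[, , t]), fs = as.vector(es$fs[, , t]))
    d <- d[!is.na(d$zone_id), ]
    agg <- stats::aggregate(d[ES_NAMES], by = list(zone_id = d$zone_id),
                            FUN = mean, na.rm = TRUE)
    agg$year <- es$years[t]
    rows[[t]] <- agg
  }
  out <- do.call(rbind, rows)
  names(out)[match(ES_NAMES, names(out))] <- paste0(ES_NAMES, "_mean")
  out[order(out$zone_id, out$year), c("zone_id", "year", paste0(ES_NAMES, "_mean"))]
}
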