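# Raster and table I/O.
#
# Rasters are exchanged as single-band ESRI ASCII grids (.asc), a plain-text
# format with a 6-line header; values are written with 17 significant digits
# so a write/read round trip is bit-exact for doubles. A manifest records an
# MD5 checksum per file so corruption is detected at read time.

ASC_NODATA <- -999999999

#' Write a grid to an ESRI ASCII raster
#'
#' @param m numeric matrix (row 1 = northernmost row); NA becomes the nodata
#'   value.
#' @param path output file.
#' @param cellsize cell edge length (m or km; recorded verbatim).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, cellsize = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.17g", cellsize),
    sprintf("NODATA_value %d", ASC_NODATA)), con)
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    s <- ifelse(is.na(v), as.character(ASC_NODATA), sprintf("%.17g", v))
    writeLines(paste(s, collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path input file.
#' @return numeric matrix with attribute `cellsize`; nodata becomes NA.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) {
    stop_esd("esd_io_error", "raster not found: %s", path)
  }
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  nr <- as.integer(vals["nrows"]); nc <- as.integer(vals["ncols"])
  nodata <- vals["nodata_value"]
  body <- strsplit(trimws(lines[7:(6 + nr)]), "\\s+")
  m <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    row <- as.numeric(body[[i]])
    if (length(row) != nc) {
      stop_esd("esd_format_error", "raster %s: row %d has %d of %d values",
               path, i, length(row), nc)
    }
    m[i, ] <- row
  }
  m[m == nodata] <- NA_real_
  attr(m, "cellsize") <- unname(vals["cellsize"])
  m
}

#' Write a landscape dataset to a fixture directory
#'
#' One ASCII raster per dynamic variable and year (`<VAR>_<YEAR>.asc`), one
#' per static variable (`<VAR>.asc`), `land_use.asc` and `zones.asc`,
#' `zone_grain_yield.csv`, and `manifest.json` carrying the grid contract
#' (shape, cell size, years, variable lists) plus an MD5 checksum per file.
#' A read of the written directory reproduces the dataset bit-exactly.
#'
#' @param landscape a `landscape`.
#' @param directory output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_fixture <- function(landscape, directory) {
  ls <- landscape
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop_esd("esd_io_error", "cannot create directory %s", directory)
  }
  files <- character(0)
  put <- function(m, name) {
    write_ascii_grid(m, file.path(directory, name), cellsize = ls$cell_km)
    files[[length(files) + 1]] <<- name
  }
  for (v in names(ls$dynamic)) {
    for (t in seq_along(ls$years)) {
      put(ls$dynamic[[v]][, , t], sprintf("%s_%d.asc", v, ls$years[t]))
    }
  }
  for (v in names(ls$static)) put(ls$static[[v]], sprintf("%s.asc", v))
  put(ls$land_use, "land_use.asc")
  put(ls$zones, "zones.asc")
  zy <- ls$zone_grain_yield
  zpath <- file.path(directory, "zone_grain_yield.csv")
  writeLines(c("zone_id,year,p_sum_t",
               sprintf("%d,%d,%.17g", zy$zone_id, zy$year, zy$p_sum_t)),
             zpath)
  files[[length(files) + 1]] <- "zone_grain_yield.csv"
  sums <- tools::md5sum(file.path(directory, files))
  manifest <- list(
    format = "esdrought-fixture-1",
    n_rows = ls$n_rows, n_cols = ls$n_cols, n_years = ls$n_years,
    years = ls$years, cell_km = ls$cell_km,
    dynamic_vars = names(ls$dynamic), static_vars = names(ls$static),
    land_use_levels = ls$land_use_levels,
    checksums = as.list(stats::setNames(unname(sums), files))
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a landscape dataset from a fixture directory
#'
#' Verifies every file against its manifest checksum, then enforces the
#' shared-grid contract: every raster must match the manifest's shape and
#' cell size, the validity mask is taken from `land_use.asc`, and any raster
#' whose NA set departs from that mask is reported. Missing variable-years
#' raise a completeness error listing the gaps.
#'
#' @param directory fixture directory written by [write_fixture()].
#' @return a `landscape` (without generator ground truth).
#' @export
read_landscape <- function(directory) {
  mpath <- file.path(directory, "manifest.json")
  if (!file.exists(mpath)) {
    stop_esd("esd_io_error", "no manifest.json in %s", directory)
  }
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  files <- names(man$checksums)
  missing <- files[!file.exists(file.path(directory, files))]
  if (length(missing)) {
    stop_esd("esd_completeness_error", "fixture file(s) missing: %s",
             paste(missing, collapse = ", "))
  }
  sums <- tools::md5sum(file.path(directory, files))
  bad <- files[unname(sums) != unlist(man$checksums[files])]
  if (length(bad)) {
    stop_esd("esd_checksum_error", "checksum mismatch in: %s",
             paste(bad, collapse = ", "))
  }
  nr <- man$n_rows; nc <- man$n_cols
  years <- as.integer(man$years)
  misaligned <- character(0)
  get_grid <- function(name) {
    m <- read_ascii_grid(file.path(directory, name))
    if (nrow(m) != nr || ncol(m) != nc ||
        abs(attr(m, "cellsize") - man$cell_km) > 1e-12) {
      misaligned <<- c(misaligned, name)
    }
    attr(m, "cellsize") <- NULL
    m
  }
  dynamic <- lapply(stats::setNames(man$dynamic_vars, man$dynamic_vars),
                    function(v) {
    a <- array(NA_real_, c(nr, nc, length(years)),
               dimnames = list(NULL, NULL, years))
    for (t in seq_along(years)) {
      name <- sprintf("%s_%d.asc", v, years[t])
      if (!name %in% files) {
        stop_esd("esd_completeness_error", "fixture lacks %s", name)
      }
      a[, , t] <- get_grid(name)
    }
    a
  })
  static <- lapply(stats::setNames(man$static_vars, man$static_vars),
                   function(v) get_grid(sprintf("%s.asc", v)))
  land_use <- get_grid("land_use.asc")
  zones <- get_grid("zones.asc")
  if (length(misaligned)) {
    stop_esd("esd_alignment_error", "raster(s) off the shared grid: %s",
             paste(unique(misaligned), collapse = ", "))
  }
  storage.mode(land_use) <- "integer"
  storage.mode(zones) <- "integer"
  zy <- read.csv(file.path(directory, "zone_grain_yield.csv"))
  structure(list(
    n_rows = nr, n_cols = nc, n_years = length(years), years = years,
    cell_km = man$cell_km,
    dynamic = dynamic, static = static,
    land_use = land_use, land_use_levels = man$land_use_levels,
    zones = zones, zone_grain_yield = zy,
    mask = !is.na(land_use),
    truth = NULL, config = NULL
  ), class = "landscape")
}
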