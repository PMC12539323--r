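# Staged analysis pipeline: synthetic (or on-disk) landscape -> services ->
# drought metrics -> trends -> constraint lines -> bundles -> relationships
# -> attribution, with every output file checksummed into a run manifest.
# All randomness flows from the config seed, so a rerun with the same config
# reproduces every output bit-identically.

PIPELINE_STAGES <- c("es", "drought", "trends", "constraints", "bundles",
                     "relationships", "attribution")
STAGE_DEPS <- list(
  es = character(0),
  drought = character(0),
  trends = "es",
  constraints = "es",
  bundles = c("es", "drought"),
  relationships = c("es", "drought", "bundles"),
  attribution = c("es", "drought", "bundles")
)

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()] used to generate the input
#'   landscape (exactly one of `synthetic` / `input_dir`).
#' @param input_dir fixture directory readable by [read_landscape()].
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived from it deterministically.
#' @param class_breaks SPEI drought class cutoffs, see [drought_class_table()].
#' @param rusle_variant soil-conservation variant, see
#'   [compute_soil_conservation()].
#' @param alpha significance level for trends and stars.
#' @param n_bins,q,min_count constraint-line settings.
#' @param families constraint-line family catalog.
#' @param som_k,som_epochs bundle count and SOM training passes.
#' @param attr_instances,attr_background per-(bundle, service) Shapley
#'   sample sizes (kept at desk scale: 12 features means 4096 subsets per
#'   instance).
#' @param write_rasters write per-year service rasters (default TRUE).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input_dir = NULL,
                            out_dir = tempfile("esdrought_run_"),
                            seed = 42,
                            class_breaks = c(-2, -1.5, -1, -0.5),
                            rusle_variant = "printed", alpha = 0.05,
                            n_bins = 100, q = 99.9, min_count = 10,
                            families = CONSTRAINT_FAMILIES,
                            som_k = 4, som_epochs = 500,
                            attr_instances = 20, attr_background = 50,
                            write_rasters = TRUE) {
  if (is.null(synthetic) == is.null(input_dir)) {
    stop_esd("esd_config_error",
             "provide exactly one of 'synthetic' or 'input_dir'")
  }
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 out_dir = out_dir, seed = as.integer(seed),
                 class_breaks = class_breaks, rusle_variant = rusle_variant,
                 alpha = alpha, n_bins = n_bins, q = q, min_count = min_count,
                 families = families, som_k = som_k, som_epochs = som_epochs,
                 attr_instances = attr_instances,
                 attr_background = attr_background,
                 write_rasters = write_rasters),
            class = "pipeline_config")
}

config_hash <- function(config) {
  ser <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                          force = TRUE, null = "null")
  tmp <- tempfile()
  writeLines(as.character(ser), tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  h
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order and writes their
#' outputs (ASCII rasters, CSV tables) plus a run manifest
#' (`run_manifest.json`) holding the config hash, derived stage seeds,
#' per-stage timing, machine-readable warnings, and an MD5 checksum for
#' every output file.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("es","drought","trends","constraints","bundles","relationships","attribution")`
#'   or `"all"`. A requested stage whose prerequisite is not requested
#'   raises a dependency error naming the missing stage.
#' @return list with the run `manifest` and the in-memory stage `results`,
#'   invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) {
    stop_esd("esd_config_error", "unknown stage(s): %s", paste(bad, collapse = ", "))
  }
  for (st in stages) {
    need <- setdiff(STAGE_DEPS[[st]], stages)
    if (length(need)) {
      stop_esd("esd_dependency_error",
               "stage '%s' requires stage '%s' to run first", st, need[1])
    }
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = stages, files = list(), seeds = list(),
                   timing_s = list(), warnings = list())
  note <- function(stage, msg) {
    manifest$warnings[[stage]] <<- c(manifest$warnings[[stage]], msg)
  }
  emit <- function(stage, name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest$files[[name]] <<- unname(tools::md5sum(path))
    invisible(path)
  }
  emit_csv <- function(stage, name, df) {
    emit(stage, name, function(p) write.csv(df, p, row.names = FALSE))
  }
  emit_grid <- function(stage, name, m, cellsize) {
    emit(stage, name, function(p) write_ascii_grid(m, p, cellsize = cellsize))
  }
  results <- list()
  timer <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    manifest$timing_s[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }

  # --- input landscape -----------------------------------------------------
  landscape <- timer("input", {
    if (!is.null(config$synthetic)) generate_landscape(config$synthetic)
    else read_landscape(config$input_dir)
  })
  results$landscape <- landscape
  ck <- landscape$cell_km

  es <- NULL; labels <- NULL; spei_f <- NULL; assignment <- NULL
  bmap <- NULL; features <- NULL

  if ("es" %in% stages) {
    es <- timer("es", compute_es_stack(landscape,
                                       rusle_variant = config$rusle_variant))
    results$es <- es
    if (config$write_rasters) {
      for (v in ES_NAMES) {
        for (t in seq_along(es$years)) {
          emit_grid("es", sprintf("%s_%d.asc", toupper(v), es$years[t]),
                    es[[v]][, , t], ck)
        }
      }
    }
    emit_csv("es", "es_zone_summary.csv",
             summarize_es_by_zone(es, landscape$zones))
  }

  if ("drought" %in% stages) {
    timer("drought", {
      table <- drought_class_table(breaks = config$class_breaks)
      labels <- classify_drought(landscape$dynamic$SPEI, table)
      spei_f <- drought_frequency(labels)
      emit_grid("drought", "spei_f.asc", spei_f, ck)
      counts <- drought_class_counts(labels)
      for (cl in names(counts)) {
        emit_grid("drought", sprintf("class_freq_%s.asc", cl), counts[[cl]], ck)
      }
      if (!is.null(es)) {
        strata <- stratify_es_by_drought(es, labels, landscape$land_use,
                                         mode = "cell-year",
                                         land_use_levels = landscape$land_use_levels)
        emit_csv("drought", "drought_strata.csv", strata)
        strata2 <- stratify_es_by_drought(es, labels, landscape$land_use,
                                          mode = "class-zone",
                                          land_use_levels = landscape$land_use_levels)
        emit_csv("drought", "drought_degree_stats.csv", strata2)
      }
      surf <- binned_spei_surface(landscape$dynamic$TEM, landscape$dynamic$PRE,
                                  landscape$dynamic$SPEI)
      sdf <- data.frame(
        tem_bin = rep(head(surf$tem_breaks, -1), times = ncol(surf$mean)),
        pre_bin = rep(head(surf$pre_breaks, -1), each = nrow(surf$mean)),
        mean_spei = as.vector(surf$mean), n = as.vector(surf$n))
      emit_csv("drought", "spei_surface.csv", sdf)
      results$drought <- list(labels = labels, spei_f = spei_f, surface = surf)
    })
  }

  if ("trends" %in% stages) {
    timer("trends", {
      zone_rows <- list()
      for (v in c(ES_NAMES, "SPEI")) {
        arr <- if (v == "SPEI") landscape$dynamic$SPEI else es[[v]]
        tr <- trend_raster(arr, alpha = config$alpha, years = landscape$years,
                           zones = landscape$zones)
        nm <- if (v == "SPEI") "SPEI" else toupper(v)
        emit_grid("trends", sprintf("%s_sen.asc", nm), tr$slope, ck)
        emit_grid("trends", sprintf("%s_mk_p.asc", nm), tr$p, ck)
        emit_grid("trends", sprintf("%s_sig.asc", nm), tr$sig, ck)
        zs <- tr$zone_slopes
        zs$variable <- nm
        zone_rows[[nm]] <- zs
        results$trends[[nm]] <- tr
      }
      emit_csv("trends", "zone_slopes.csv", do.call(rbind, zone_rows))
    })
  }

  if ("constraints" %in% stages) {
    timer("constraints", {
      fits <- constraint_analysis_by_landuse(
        landscape, es, n_bins = config$n_bins, q = config$q,
        min_count = config$min_count, families = config$families)
      emit_csv("constraints", "constraint_fits.csv", fits)
      skipped <- fits[fits$skipped, ]
      if (nrow(skipped)) {
        note("constraints", sprintf("skipped %s/%s: %s", skipped$es,
                                    skipped$land_use, skipped$reason))
      }
      results$constraints <- fits
    })
  }

  if ("bundles" %in% stages) {
    timer("bundles", {
      features <- build_feature_matrix(es, spei_f)
      som_seed <- derive_seed(config$seed, "som")
      manifest$seeds$bundles <- som_seed
      assignment <- withCallingHandlers(
        som_cluster(features, k = config$som_k, epochs = config$som_epochs,
                    seed = som_seed),
        warning = function(w) {
          note("bundles", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      bmap <- bundle_map(assignment)
      emit_grid("bundles", "bundles.asc", bmap, ck)
      emit_csv("bundles", "bundle_summary.csv",
               summarize_bundles(assignment, features))
      cb <- as.data.frame(assignment$codebook)
      cb$unit <- rownames(assignment$codebook)
      emit_csv("bundles", "codebook.csv", cb)
      results$bundles <- assignment
    })
  }

  if ("relationships" %in% stages) {
    timer("relationships", {
      degree <- cell_drought_degree(labels)
      classes <- attr(labels, "classes")
      by_degree <- tradeoff_matrix(es, degree, spei_f = spei_f,
                                   stratum_names = classes)
      for (nm in names(by_degree)) {
        emit_csv("relationships", sprintf("tradeoffs_%s.csv", nm),
                 tradeoff_table(by_degree[[nm]], alpha = config$alpha))
      }
      by_bundle <- tradeoff_matrix(es, bmap, spei_f = spei_f,
                                   stratum_names = paste0("B", seq_len(
                                     max(bmap, na.rm = TRUE))))
      for (nm in names(by_bundle)) {
        emit_csv("relationships", sprintf("tradeoffs_bundle_%s.csv", nm),
                 tradeoff_table(by_bundle[[nm]], alpha = config$alpha))
      }
      emit_csv("relationships", "es_spei_regression.csv",
               es_spei_regression(es, landscape$dynamic$SPEI,
                                  landscape$land_use,
                                  landscape$land_use_levels))
      results$relationships <- list(by_degree = by_degree,
                                     by_bundle = by_bundle)
    })
  }

  if ("attribution" %in% stages) {
    timer("attribution", {
      drv <- driver_features(landscape, spei_f)
      means <- es_period_means(es)
      attr_seed <- derive_seed(config$seed, "attribution")
      manifest$seeds$attribution <- attr_seed
      for (b in seq_len(assignment$k_realized)) {
        in_bundle <- drv$cells %in% features$cells[assignment$labels == b]
        xb <- drv$x[in_bundle, , drop = FALSE]
        for (es_name in ES_NAMES) {
          y <- as.vector(means[[es_name]])[drv$cells][in_bundle]
          key <- sprintf("B%d_%s", b, es_name)
          if (nrow(xb) < 50) {
            note("attribution", sprintf("%s: only %d cells, skipped", key, nrow(xb)))
            next
          }
          sm <- withCallingHandlers(
            shap_summary(xb, y, n_instances = config$attr_instances,
                         n_background = config$attr_background,
                         seed = derive_seed(attr_seed, key)),
            warning = function(w) {
              note("attribution", sprintf("%s: %s", key, conditionMessage(w)))
              invokeRestart("muffleWarning")
            })
          emit_csv("attribution", sprintf("importance_%s.csv", key),
                   sm$importance)
          emit_csv("attribution", sprintf("shap_values_%s.csv", key),
                   sm$values)
          results$attribution[[key]] <- sm
        }
      }
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = results))
}
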