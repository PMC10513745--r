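# End-to-end orchestration: simulate -> terrain -> detect -> species ->
# index -> zonal -> evaluate, with validated configuration and a run
# manifest so a fixed seed reproduces byte-identical artifacts.

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Root seed (drives the scenario and the evaluation sampling).
#' @param scenario Named list of [scenario_config()] overrides, or NULL to
#'   use paths from `inputs` instead of simulating.
#' @param inputs Named list of input paths (`dem`, `t0`, `t1`, `species`,
#'   `pas`, `zones`) used for stages whose inputs are not produced by an
#'   earlier enabled stage.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param human_codes Land-cover codes counted as human.
#' @param grid_km Analysis-grid cell size (km).
#' @param pa_cutoff_year PA establishment-year cutoff (exclusive).
#' @param eval_interval_km Minimum sampling distance (km).
#' @param eval_n Target evaluation sample size.
#' @param verbose Log stage progress.
#' @return A validated `ts_run_config` list.
#' @export
run_config <- function(out_dir,
                       seed = 1,
                       scenario = list(),
                       inputs = list(),
                       stages = c("simulate", "terrain", "detect", "species",
                                  "index", "zonal", "evaluate"),
                       human_codes = HUMAN_CODES,
                       grid_km = 1,
                       pa_cutoff_year = 2000,
                       eval_interval_km = 3,
                       eval_n = 1000,
                       verbose = TRUE) {
  cfg <- as.list(environment())
  known <- c("simulate", "terrain", "detect", "species", "index", "zonal",
             "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  cfg$stages <- known[known %in% stages]
  class(cfg) <- "ts_run_config"
  validate_run_config(cfg)
  cfg
}

# Every enabled stage's inputs must be resolvable from an earlier enabled
# stage, from `inputs` paths, or from artifacts already in out_dir.
validate_run_config <- function(cfg) {
  produced <- character(0)
  if ("simulate" %in% cfg$stages)
    produced <- c("dem", "t0", "t1", "species", "pas", "zones")
  needs <- list(terrain = "dem", detect = c("t0", "t1"), species = "species",
                index = c("mask", "species"), zonal = c("td", "levels", "pas",
                                                        "zones", "relief"),
                evaluate = c("td", "densities"))
  makes <- list(terrain = c("slope", "relief"), detect = "mask",
                species = "species_filtered",
                index = c("densities", "td", "levels"))
  on_disk <- function(key) {
    f <- file.path(cfg$out_dir, paste0(key, c(".tif", ".geojson", "_n.tif")))
    any(file.exists(f))
  }
  for (st in cfg$stages) {
    for (req in needs[[st]] %||% character(0)) {
      ok <- req %in% produced || !is.null(cfg$inputs[[req]]) || on_disk(req)
      if (req == "species_filtered") ok <- ok || "species" %in% produced ||
          !is.null(cfg$inputs$species)
      if (req == "densities") ok <- ok || "index" %in% cfg$stages
      if (!ok)
        stop(sprintf("stage '%s' needs input '%s': enable the producing stage or set inputs$%s",
                     st, req, req))
    }
    produced <- c(produced, makes[[st]] %||% character(0))
  }
  invisible(TRUE)
}

#' Run the threat-degree pipeline
#'
#' Executes the enabled stages in order, writing every artifact under
#' `cfg$out_dir` (GeoTIFF rasters, GeoJSON vectors, TSV tables, JSON
#' reports) plus a `manifest.json` recording parameters and artifact
#' checksums. Re-running with the same configuration reproduces the
#' artifacts byte for byte.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "ts_run_config"))
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (cfg$verbose) message(sprintf(...))
  out <- function(f) file.path(cfg$out_dir, f)
  res <- list()

  if ("simulate" %in% cfg$stages) {
    say("[simulate] seed %d", cfg$seed)
    scfg <- do.call(scenario_config, utils::modifyList(list(seed = cfg$seed),
                                                       cfg$scenario))
    sc <- simulate_scenario(scfg, grid_km = cfg$grid_km)
    write_raster(sc$dem, out("dem.tif"))
    write_raster(sc$t0, out("t0.tif"))
    write_raster(sc$t1, out("t1.tif"))
    write_species(sc$species, out("species.geojson"))
    write_vector(sc$pas, out("pas.geojson"))
    write_vector(sc$zones, out("zones.geojson"))
    res$scenario <- sc
    say("[simulate] %d planted patches, %d species records, %d PAs",
        nrow(sc$truth$patches), length(sc$species), length(sc$pas))
  }

  get_raster <- function(key, file) {
    if (!is.null(res$scenario[[key]])) res$scenario[[key]]
    else read_raster(cfg$inputs[[key]] %||% out(file))
  }

  if ("terrain" %in% cfg$stages) {
    dem <- get_raster("dem", "dem.tif")
    say("[terrain] slope + relief on %d x %d DEM", nrow(dem$values), ncol(dem$values))
    slope <- compute_slope(dem)
    relief <- classify_relief(dem, slope)
    write_raster(slope, out("slope.tif"))
    write_raster(relief, out("relief.tif"))
    res$slope <- slope; res$relief <- relief
  }

  if ("detect" %in% cfg$stages) {
    t0 <- get_raster("t0", "t0.tif"); t1 <- get_raster("t1", "t1.tif")
    mask <- detect_expansion(t0, t1, cfg$human_codes, quiet = !cfg$verbose)
    patches <- extract_patches(mask)
    write_raster(mask, out("mask.tif"))
    write_raster(patches$label_raster, out("labels.tif"))
    write_patches(patches, out("patches.geojson"))
    res$mask <- mask; res$patches <- patches
    say("[detect] %d patches, %.4f km2", nrow(patches$patches),
        sum(patches$patches$area_km2))
  }

  if ("species" %in% cfg$stages) {
    raw <- if (!is.null(res$scenario)) res$scenario$species
           else read_species(cfg$inputs$species %||% out("species.geojson"))
    thr <- filter_threatened(raw, quiet = !cfg$verbose)
    write_species(thr, out("species_threatened.geojson"))
    res$species <- thr
  }

  if ("index" %in% cfg$stages) {
    mask <- res$mask %||% read_raster(cfg$inputs$mask %||% out("mask.tif"))
    if (is.null(res$patches)) res$patches <- extract_patches(mask)
    thr <- res$species %||% filter_threatened(
      read_species(cfg$inputs$species %||% out("species.geojson")),
      quiet = !cfg$verbose)
    grid <- build_grid(raster_extent(mask), cell_size_km = cfg$grid_km)
    dens <- compute_density_surfaces(grid, res$patches, thr, valid = mask)
    td <- threat_degree(normalize_surface(dens$N), normalize_surface(dens$A),
                        normalize_surface(dens$T))
    cls <- classify_threat(td)
    write_raster(dens$N, out("density_n.tif"))
    write_raster(dens$A, out("density_a.tif"))
    write_raster(dens$T, out("density_t.tif"))
    write_raster(td, out("td.tif"))
    write_raster(cls$levels, out("levels.tif"))
    jsonlite::write_json(cls$thresholds, out("thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    res$grid <- grid; res$densities <- dens; res$td <- td
    res$classification <- cls
    say("[index] %d threatened cells; mean TD %.2f%%, cuts %.2f / %.2f",
        cls$thresholds$n, cls$thresholds$mean, cls$thresholds$low_cut,
        cls$thresholds$high_cut)
  }

  if ("zonal" %in% cfg$stages) {
    td <- res$td %||% read_raster(out("td.tif"))
    levels <- res$classification$levels %||% read_raster(out("levels.tif"))
    relief <- res$relief %||% read_raster(cfg$inputs$relief %||% out("relief.tif"))
    grid <- res$grid %||% build_grid(raster_extent(td), cell_size_km = cfg$grid_km)
    zones <- if (!is.null(res$scenario)) res$scenario$zones
             else read_vector(cfg$inputs$zones %||% out("zones.geojson"))
    pas_raw <- if (!is.null(res$scenario)) res$scenario$pas
               else read_vector(cfg$inputs$pas %||% out("pas.geojson"),
                                geometry = "any")
    hl <- grid_highland(relief, grid)
    pas <- filter_pas(pas_raw, cutoff_year = cfg$pa_cutoff_year,
                      quiet = !cfg$verbose)
    continental <- zonal_summary(td, levels, NULL, grid, hl)
    countries <- zonal_summary(td, levels, zones, grid, hl)
    pa_sum <- if (length(pas$features) > 0)
      zonal_summary(td, levels, pas, grid, hl) else NULL
    write_tsv <- function(df, f) utils::write.table(
      df, out(f), sep = "\t", row.names = FALSE, quote = FALSE)
    write_tsv(continental, "zonal_continent.tsv")
    write_tsv(countries, "zonal_countries.tsv")
    if (!is.null(pa_sum)) write_tsv(pa_sum, "zonal_pas.tsv")
    write_vector(pas, out("pas_filtered.geojson"))
    res$zonal <- list(continent = continental, countries = countries,
                      pas = pa_sum, pas_filtered = pas, highland = hl)
    say("[zonal] continent mean TD %.2f%%, %d zones, %d merged PAs",
        continental$mean_td[1], nrow(countries), length(pas$features))
  }

  if ("evaluate" %in% cfg$stages) {
    td <- res$td %||% read_raster(out("td.tif"))
    grid <- res$grid %||% build_grid(raster_extent(td), cell_size_km = cfg$grid_km)
    dens <- res$densities %||% list(N = read_raster(out("density_n.tif")),
                                    A = read_raster(out("density_a.tif")),
                                    T = read_raster(out("density_t.tif")))
    samples <- sample_surfaces(td, dens, grid,
                               interval_km = cfg$eval_interval_km,
                               n_target = cfg$eval_n, seed = cfg$seed)
    report <- correlation_report(samples)
    utils::write.table(samples, out("samples.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(pairs = report$pairs,
                              avg_index_corr = report$avg_index_corr,
                              avg_component_corr = report$avg_component_corr,
                              n = report$n),
                         out("correlations.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    res$evaluation <- report
    say("[evaluate] n=%d, avg index correlation %.3f (components %.3f)",
        report$n, report$avg_index_corr, report$avg_component_corr)
  }

  # manifest: parameters + artifact checksums (no timestamps, so reruns match)
  arts <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(
    package = "threatscape",
    version = as.character(utils::packageVersion("threatscape")),
    seed = cfg$seed, stages = cfg$stages,
    parameters = list(grid_km = cfg$grid_km,
                      human_codes = unname(cfg$human_codes),
                      pa_cutoff_year = cfg$pa_cutoff_year,
                      eval_interval_km = cfg$eval_interval_km,
                      eval_n = cfg$eval_n,
                      scenario = cfg$scenario),
    artifacts = as.list(tools::md5sum(file.path(cfg$out_dir, arts))))
  names(manifest$artifacts) <- arts
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}
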