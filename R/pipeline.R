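# End-to-end orchestration: simulate -> segment -> geometry -> SI -> metrics
# as a single reproducible run driven by one config, with a provenance
# manifest. The numbered scripts under analysis/ are thin drivers over the
# same stage functions.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults; supplied configs are merged over
#' this (see [run_pipeline()]), so a config only needs the fields it changes.
#'
#' @return Nested list of stage parameters.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    map = list(n_x = 7L, n_y = 8L, pattern = "segregated_halves",
               mix_fraction = 0.5, widths = NULL,
               droplet_diameter = 110, pitch = 110),
    scene = list(density = 1e8, rotation = 0, n_debris = 0,
                 pixel_size = 1.515,
                 noise = list(background = 0.05, gradient = 0.05, sd = 0.02),
                 growth = list(median_diameter = 15, sdlog = 0.55)),
    segment = list(smooth_sigma = 2, ridge_sigma = 3, seed_tolerance = 0.1,
                   min_area = 10),
    geometry = list(margin_factor = 1.15, n_angles = 360L),
    si = list(spans_px = c(5L, 10L, 20L, 50L, 66L, 100L))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full printed-array quantification pipeline
#'
#' Stages: (1) simulate a synthetic scene from the configured printing map;
#' (2) segment microcolonies in 2D and extract features; (3) isolate and
#' register the print and compute neighbour distances; (4) assign pixel
#' genotypes and compute the SI(h) profile, compared against the printing
#' map's reference; (5) compute the area-basis genotype frequencies. When
#' `config$out_dir` is set, every stage writes its outputs there (TIFF
#' image, ground-truth and colony CSVs, geometry and metrics JSON,
#' SI-profile CSV, a log, and a manifest with the seed and full config);
#' rerunning the same config reproduces deterministic outputs identically.
#'
#' @param config Nested list (or path to a YAML file) merged over
#'   [default_pipeline_config()].
#' @return List with `scene`, `labels`, `colonies`, `geometry`, `si`
#'   (profile + reference comparison), `metrics`, and `config` (the fully
#'   merged configuration).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  out_dir <- cfg$out_dir
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("simulate: pattern %s, seed %d", cfg$map$pattern, cfg$seed)
  map <- stage("simulate", make_printing_map(
    cfg$map$n_x, cfg$map$n_y, cfg$map$pattern,
    mix_fraction = cfg$map$mix_fraction, widths = cfg$map$widths,
    droplet_diameter = cfg$map$droplet_diameter, pitch = cfg$map$pitch))
  scene <- stage("simulate", render_scene(
    map, growth = cfg$scene$growth, noise = cfg$scene$noise,
    rotation = cfg$scene$rotation, n_debris = cfg$scene$n_debris,
    seed = cfg$seed, density = cfg$scene$density,
    pixel_size = cfg$scene$pixel_size))

  say("segment2d: %d x %d px", nrow(scene$image$ch1), ncol(scene$image$ch1))
  labels <- stage("segment2d", segment_microcolonies_2d(
    scene$image, smooth_sigma = cfg$segment$smooth_sigma,
    ridge_sigma = cfg$segment$ridge_sigma,
    seed_tolerance = cfg$segment$seed_tolerance,
    min_area = cfg$segment$min_area))
  colonies <- stage("segment2d",
                    call_colony_genotypes(
                      extract_colony_features(labels, scene$image)))
  say("segment2d: %d colonies", labels$n)

  geom <- stage("geometry", print_geometry(
    colonies, margin_factor = cfg$geometry$margin_factor,
    n_angles = cfg$geometry$n_angles))
  say("geometry: L = %.0f um, theta = %.2f deg", geom$summary$L,
      geom$summary$theta_deg)

  gmask <- stage("si", assign_pixel_genotypes(scene$image))
  prof <- stage("si", si_profile(gmask, spans_px = cfg$si$spans_px))
  ref <- stage("si", compare_to_reference(prof, map,
                                          pixel_size = cfg$scene$pixel_size,
                                          seed = cfg$seed))
  say("si: SI(%d px) = %.3f (reference %.3f)",
      prof$span_px[nrow(prof)], prof$si[nrow(prof)],
      ref$comparison$si_reference[nrow(prof)])

  f_A <- stage("metrics", frequency_from_mask(gmask))
  metrics <- list(frequency = c(A = f_A, B = 1 - f_A), basis = "area_um2")
  say("metrics: f_A = %.3f (area basis)", f_A)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scene(scene, file.path(out_dir, "scene"))
    write_label_mask(labels, file.path(out_dir, "labels.tif"))
    write_colony_table(colonies, file.path(out_dir, "colonies.csv"))
    jsonlite::write_json(geom$summary, file.path(out_dir, "geometry.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    utils::write.csv(ref$comparison, file.path(out_dir, "si_profile.csv"),
                     row.names = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    manifest <- list(seed = cfg$seed,
                     config_md5 = unname(tools::md5sum(cfg_path)),
                     r_version = R.version.string,
                     package_version =
                       as.character(utils::packageVersion("printarray")),
                     files = c("scene.tif", "scene_truth.csv", "scene.json",
                               "labels.tif", "colonies.csv", "geometry.json",
                               "si_profile.csv", "metrics.json",
                               "config.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  invisible(list(scene = scene, labels = labels, colonies = colonies,
                 geometry = geom,
                 si = list(profile = prof, reference = ref),
                 metrics = metrics, config = cfg))
}
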