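# End-to-end pipeline orchestration: simulate -> reconstruct -> segment ->
# featurize -> analyze, with a run manifest; plus the microfluidic
# shear-stress utility.

#' Fluid shear stress in the culture channel
#'
#' \deqn{T = \frac{5 \mu Q}{w h^2}} for viscosity mu (Pa s), volumetric
#' flow rate Q (m^3/s), channel width w and height h (m).  Reported in Pa
#' and in dyn/cm^2 (1 Pa = 10 dyn/cm^2); organoid-safe designs keep the
#' stress well below 1 dyn/cm^2 (the literature bound is printed with
#' incomplete units, "cm^-2", presumably dyn/cm^2).
#'
#' @param viscosity_pa_s dynamic viscosity, Pa s.
#' @param flow_rate_m3_s volumetric flow rate, m^3/s.
#' @param width_m,height_m channel width and height, m.
#' @return list with `pa` and `dyn_cm2`.
#' @export
shear_stress <- function(viscosity_pa_s = 1e-3, flow_rate_m3_s = 1.667e-9,
                         width_m = 2e-3, height_m = 2.5e-3) {
  if (width_m <= 0 || height_m <= 0 || viscosity_pa_s <= 0)
    stopf("viscosity and channel dimensions must be positive")
  if (flow_rate_m3_s < 0) stopf("flow rate must be non-negative")
  t_pa <- 5 * viscosity_pa_s * flow_rate_m3_s / (width_m * height_m^2)
  list(pa = t_pa, dyn_cm2 = t_pa * 10)
}

#' Default pipeline run configuration
#'
#' @param seed global seed; per-stage seeds are derived as
#'   `(seed + stage index) mod 2^31 - 1`.
#' @param cohort a [cohort_spec()] (its seed is overridden by the derived
#'   stage seed).
#' @param acquisition an [acquisition_spec()].
#' @param recon a [recon_config()].
#' @param optics an [optical_config()].
#' @param tiles a [tile_config()].
#' @param ri_threshold high-RI segmentation threshold.
#' @param stages character vector of stages to run, in order.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_spec(),
                       acquisition = acquisition_spec(snr_db = 20),
                       recon = recon_config(),
                       optics = optical_config(),
                       tiles = tile_config(families = "fractal"),
                       ri_threshold = 1.46,
                       stages = c("simulate", "reconstruct", "segment",
                                  "morphometrics", "features", "analyze")) {
  structure(list(seed = as.integer(seed), cohort = cohort,
                 acquisition = acquisition, recon = recon, optics = optics,
                 tiles = tiles, ri_threshold = ri_threshold, stages = stages),
            class = "run_config")
}

stage_seed <- function(seed, stage_index) as.integer((seed + stage_index) %% 2147483647)

#' Run the full analysis pipeline on a simulated cohort
#'
#' Stages: `simulate` generates the cohort phantoms; `reconstruct` images
#' each phantom through the qOBM forward model and recovers phase;
#' `segment` converts to refractive index and tracks the high-RI fraction;
#' `morphometrics` computes whole-organoid shape metrics and rosette
#' counts from the ground-truth masks; `features` extracts the tile
#' feature table; `analyze` runs the longitudinal group comparisons.
#' Outputs (CSV/JSON, and a manifest with seeds and checksums) are written
#' under `output_dir`.  A stage consuming a disabled stage's output fails
#' with an error naming the missing dependency.
#'
#' @param config a [run_config()].
#' @param output_dir directory for outputs (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config(), output_dir = tempfile("oqpi_run_"),
                         quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list()
  files <- character(0)
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stopf("stage '%s' requires output of disabled stage '%s'", stage, what)
    res[[what]]
  }

  if ("simulate" %in% config$stages) {
    say("stage simulate")
    cs <- config$cohort
    cs$seed <- stage_seed(config$seed, 1L)
    res$simulate <- generate_two_group_cohort(cs)
    f <- file.path(output_dir, "cohort_metadata.csv")
    utils::write.csv(res$simulate$metadata, f, row.names = FALSE)
    files <- c(files, f)
  }

  if ("reconstruct" %in% config$stages) {
    cohort <- need("simulate", "reconstruct")
    say("stage reconstruct (%d phantoms)", length(cohort$phantoms))
    sseed <- stage_seed(config$seed, 2L)
    res$reconstruct <- lapply(seq_along(cohort$phantoms), function(i) {
      raw <- simulate_qobm_acquisition(cohort$phantoms[[i]], config$acquisition,
                                       seed = stage_seed(sseed, i))
      reconstruct_phase(compute_dpc(raw), config$acquisition$model,
                        config$recon, dz_um = config$acquisition$dz_um)
    })
  }

  if ("segment" %in% config$stages) {
    cohort <- need("simulate", "segment")
    phases <- need("reconstruct", "segment")
    say("stage segment")
    fr <- vapply(seq_along(phases), function(i) {
      ri <- phase_to_ri(phases[[i]], config$optics)
      segment_high_ri(ri, organoid_mask(cohort$phantoms[[i]]),
                      threshold = config$ri_threshold)$area_fraction
    }, numeric(1))
    tab <- cbind(cohort$metadata, fraction = fr)
    res$segment <- list(fractions = tab, summary = track_fraction(tab))
    f <- file.path(output_dir, "high_ri_fractions.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }

  if ("morphometrics" %in% config$stages) {
    cohort <- need("simulate", "morphometrics")
    say("stage morphometrics")
    mm <- do.call(rbind, lapply(seq_along(cohort$phantoms), function(i) {
      ph <- cohort$phantoms[[i]]
      sm <- compute_shape_metrics(organoid_mask(ph), ph$spec$pixel_size)
      data.frame(cohort$metadata[i, c("organoid", "group", "week")],
                 area_um2 = sm$area_um2,
                 equivalent_diameter_um = sm$equivalent_diameter_um,
                 circularity = sm$circularity, solidity = sm$solidity,
                 aspect_ratio = sm$aspect_ratio,
                 rosette_count = count_rosettes(ph))
    }))
    res$morphometrics <- mm
    f <- file.path(output_dir, "morphometrics.csv")
    utils::write.csv(mm, f, row.names = FALSE)
    files <- c(files, f)
  }

  if ("features" %in% config$stages) {
    cohort <- need("simulate", "features")
    phases <- need("reconstruct", "features")
    say("stage features")
    imgs <- lapply(phases, function(p) p$phase)
    res$features <- extract_feature_table(
      imgs, cohort$metadata[, c("organoid", "group", "week")],
      pixel_size = cohort$spec$base_phantom$pixel_size, config = config$tiles)
    f <- file.path(output_dir, "feature_table.csv")
    utils::write.csv(res$features, f, row.names = FALSE)
    files <- c(files, f)
  }

  if ("analyze" %in% config$stages) {
    ftab <- need("features", "analyze")
    say("stage analyze")
    res$analyze <- longitudinal_compare(ftab,
                                        switch_week = config$cohort$switch_week)
    f <- file.path(output_dir, "per_week_comparisons.csv")
    utils::write.csv(res$analyze$per_week, f, row.names = FALSE)
    files <- c(files, f)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("organoidqpi")),
    seed = config$seed,
    stages = config$stages,
    ri_threshold = config$ri_threshold,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res$output_dir <- output_dir
  invisible(res)
}

#' Write / read a run configuration as YAML
#'
#' The YAML round trip `read_run_config(write_run_config(x))` reproduces
#' the configuration exactly.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  to_plain <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), to_plain))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  cls <- lapply(config, function(x) class(x)[1])
  yaml::write_yaml(list(config = to_plain(unclass(config)), classes = cls), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- y$config
  for (nm in names(y$classes)) {
    cl <- y$classes[[nm]]
    if (is.list(cfg[[nm]]) && !cl %in% c("list", "numeric", "integer", "character"))
      class(cfg[[nm]]) <- cl
  }
  # restore nested spec classes and named vectors lost in YAML
  if (!is.null(cfg$cohort$base_phantom)) {
    bp <- cfg$cohort$base_phantom
    bp$compartment_ri <- unlist(bp$compartment_ri)
    for (f in c("organoid_axes", "rosette_radius_range", "droplet_diameter_range"))
      bp[[f]] <- as.numeric(unlist(bp[[f]]))
    class(bp) <- "phantom_spec"
    cfg$cohort$base_phantom <- bp
  }
  if (!is.null(cfg$acquisition$model))
    class(cfg$acquisition$model) <- "phase_transfer_model"
  if (!is.null(cfg$tiles)) {
    cfg$tiles$fractal_bands <- lapply(cfg$tiles$fractal_bands, as.numeric)
    cfg$tiles$glcm_offsets <- lapply(cfg$tiles$glcm_offsets, as.numeric)
    for (f in c("curve_band_um", "circle_band_um2"))
      cfg$tiles[[f]] <- as.numeric(unlist(cfg$tiles[[f]]))
  }
  class(cfg) <- "run_config"
  cfg
}
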