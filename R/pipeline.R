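#' Default pipeline run configuration
#'
#' Returns the fully-populated nested configuration the pipeline understands;
#' [run_pipeline()] merges a user config (e.g. from YAML) over these
#' defaults. Stage toggles under `stages`, stage parameters under their
#' stage name, all lengths in mm, sigmas in voxels.
#'
#' @param out_dir output directory for all stage products.
#' @return Nested list.
#' @export
default_run_config <- function(out_dir = "cartistrain_run") {
  list(
    out_dir = out_dir,
    seed = 1L,
    stages = list(simulate = TRUE, unwrap = TRUE, strain = TRUE,
                  project = TRUE, stepoff = TRUE),
    phantom = list(compression = 0.5, noise_snr = 30,
                   stepoff_mean = 0.0, stepoff_amplitude = 0.5),
    unwrap = list(lambda = 1.0, sigma_complex = c(1, 1, 1),
                  sigma_displacement = c(1, 0.5, 0.5), dilate_vox = 3L),
    strain = list(method = "grid", edge_mm = 0.75),
    project = list(p = 95),
    stepoff = list(offset_mm = NULL, epsilon = 1e-6))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config configuration list for writing.
#' @return Configuration list (read) or `path` (write).
#' @export
read_run_config <- function(path) {
  merge_config(default_run_config(), yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_run_config <- function(config) {
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(is.character(config$out_dir) && nzchar(config$out_dir),
       "out_dir: must be a non-empty path")
  need(is.numeric(config$seed) && length(config$seed) == 1,
       "seed: must be a single integer")
  lam <- config$unwrap$lambda
  need(is.numeric(lam) && length(lam) == 1 && is.finite(lam) && lam > 0,
       "unwrap.lambda: encoding wavelength (mm) is required and must be > 0")
  need(all(config$unwrap$sigma_complex >= 0) &&
         length(config$unwrap$sigma_complex) == 3,
       "unwrap.sigma_complex: three non-negative voxel sigmas required")
  need(all(config$unwrap$sigma_displacement >= 0) &&
         length(config$unwrap$sigma_displacement) == 3,
       "unwrap.sigma_displacement: three non-negative voxel sigmas required")
  need(config$strain$method %in% c("grid", "mesh"),
       "strain.method: must be 'grid' or 'mesh'")
  need(is.numeric(config$strain$edge_mm) && config$strain$edge_mm > 0,
       "strain.edge_mm: mesh edge length (mm) must be > 0")
  need(is.numeric(config$project$p) && config$project$p >= 0 &&
         config$project$p <= 100,
       "project.p: percentile must be in [0, 100]")
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(config)
}

stage_log <- function(manifest, name, t0, outputs) {
  hashes <- tools::md5sum(outputs[file.exists(outputs)])
  manifest$stages[[name]] <- list(
    wall_time_s = round(as.numeric(Sys.time()) - t0, 3),
    outputs = as.list(hashes))
  manifest
}

#' Run the full pipeline: simulate, unwrap, strain, project, step-off
#'
#' Executes the enabled stages in order on a synthetic phantom dataset (the
#' simulate stage) or previously written stage products in `out_dir`. Each
#' stage writes its outputs plus a manifest (`manifest.json`: configuration,
#' package version, per-stage wall time and output MD5 hashes). Failures
#' abort with the stage name after writing the partial manifest.
#'
#' @param config nested configuration list (see [default_run_config()]), or
#'   a path to a YAML file.
#' @param phantom optionally, a pre-built [generate_phantom()] dataset to use
#'   instead of simulating (the simulate stage then only writes it out).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), phantom = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config)
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("cartistrain")),
                   config = config, seed = config$seed, stages = list())
  env <- new.env()
  env$phantom <- phantom
  p <- function(...) file.path(config$out_dir, paste0(...))

  run_stage <- function(name, fun, outputs) {
    t0 <- as.numeric(Sys.time())
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      manifest <<- stage_log(manifest, name, t0, outputs)
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest <<- stage_log(manifest, name, t0, outputs)
  }

  if (isTRUE(config$stages$simulate)) {
    run_stage("simulate", function() {
      if (is.null(env$phantom)) {
        ph_args <- config$phantom
        ph_args$seed <- config$seed
        env$phantom <- generate_phantom(do.call(phantom_spec, ph_args),
                                        truth_highres = FALSE)
      }
      ds <- env$phantom
      write_volume(grid_with_values(ds$labels,
                                    array(as.numeric(ds$labels$values),
                                          grid_shape(ds$labels))),
                   p("labels.nii.gz"))
      write_volume(ds$magnitude, p("magnitude.nii.gz"))
      for (d in 1:3)
        write_complex_volume(ds$encoded[[d]],
                             p("enc_", d, "_real.nii.gz"),
                             p("enc_", d, "_imag.nii.gz"))
      write_volume(grid_with_values(ds$mask_lowres,
                                    array(as.numeric(ds$mask_lowres$values),
                                          grid_shape(ds$mask_lowres))),
                   p("mask_lowres.nii.gz"))
      write_volume(grid_with_values(ds$ref_region_lowres,
                                    array(as.numeric(ds$ref_region_lowres$values),
                                          grid_shape(ds$ref_region_lowres))),
                   p("ref_region.nii.gz"))
      write_run_config(config, p("config.yaml"))
    }, c(p("labels.nii.gz"), p("magnitude.nii.gz"),
         p("enc_1_real.nii.gz"), p("enc_1_imag.nii.gz"),
         p("enc_2_real.nii.gz"), p("enc_2_imag.nii.gz"),
         p("enc_3_real.nii.gz"), p("enc_3_imag.nii.gz"),
         p("mask_lowres.nii.gz"), p("ref_region.nii.gz"), p("config.yaml")))
  }

  if (isTRUE(config$stages$unwrap)) {
    run_stage("unwrap", function() {
      lam <- config$unwrap$lambda
      enc <- lapply(1:3, function(d) read_complex_volume(
        p("enc_", d, "_real.nii.gz"), p("enc_", d, "_imag.nii.gz"), d, lam))
      mask <- read_volume(p("mask_lowres.nii.gz"))
      mask <- grid_with_values(mask, array(mask$values > 0.5, grid_shape(mask)))
      ref <- read_volume(p("ref_region.nii.gz"))
      ref <- array(ref$values > 0.5, grid_shape(ref))
      dmask <- dilate_mask(mask, config$unwrap$dilate_vox)
      disp <- recover_displacement(enc, dmask, ref,
                                   config$unwrap$sigma_complex,
                                   config$unwrap$sigma_displacement)
      env$disp <- disp
      env$mask_lowres <- mask
      write_volume(disp$grid, p("disp.nii.gz"))
    }, p("disp.nii.gz"))
  }

  if (isTRUE(config$stages$strain)) {
    run_stage("strain", function() {
      labels <- read_volume(p("labels.nii.gz"))
      cart <- grid_with_values(labels,
                               array(labels$values %in% c(1, 3),
                                     grid_shape(labels)))
      env$labels <- labels
      env$cart_highres <- cart
      disp_hr <- upsample_trilinear(env$disp, cart, extrapolate = "clamp")
      dfield <- structure(list(grid = disp_hr, mask = as_mask_array(cart)),
                          class = "displacement_field")
      env$disp_highres <- dfield
      sf_grid <- grid_strain_oracle(dfield)
      ps <- principal_strains(sf_grid)
      env$e_min <- principal_outcome_volume(ps, "E_min")
      env$e_maxshear <- principal_outcome_volume(ps, "E_maxshear")
      write_volume(env$e_min, p("E_min.nii.gz"))
      write_volume(env$e_maxshear, p("E_maxshear.nii.gz"))
      if (config$strain$method == "mesh") {
        surf <- extract_surface_mesh(cart,
                                     target_edge_mm = config$strain$edge_mm * 0.4,
                                     smoothing_iters = 8L)
        write_mesh_stl(surf, p("cartilage_surface.stl"))
        mesh <- tet_mesh_from_mask(cart, edge_mm = config$strain$edge_mm)
        sf_mesh <- mesh_strain(dfield, mesh)
        psn <- principal_strains(sf_mesh)
        write_mesh_vtu(sf_mesh$mesh, p("strain.vtu"),
                       point_data = list(
                         displacement = sf_mesh$mesh$displacement,
                         strain = sf_mesh$tensors,
                         E_min = psn$E_min, E_maxshear = psn$E_maxshear))
      }
    }, c(p("E_min.nii.gz"), p("E_maxshear.nii.gz"), p("strain.vtu"),
         p("cartilage_surface.stl")))
  }

  if (isTRUE(config$stages$project)) {
    run_stage("project", function() {
      m <- as_mask_array(env$cart_highres)
      for (nm in c("e_min", "e_maxshear")) {
        f <- env[[nm]]
        f <- grid_with_values(f, abs(f$values))
        pm <- percentile_projection(f, m, axis = 1L, p = config$project$p)
        write_table(tidy.projection_map(pm),
                    p("topview_", toupper(nm), ".csv"))
      }
    }, c(p("topview_E_MIN.csv"), p("topview_E_MAXSHEAR.csv")))
  }

  if (isTRUE(config$stages$stepoff)) {
    run_stage("stepoff", function() {
      labels_int <- grid_with_values(env$labels,
                                     array(as.integer(round(env$labels$values)),
                                           grid_shape(env$labels)))
      tab <- stepoff_table(labels_int, env$e_min, env$e_maxshear,
                           offset_mm = config$stepoff$offset_mm,
                           epsilon = config$stepoff$epsilon)
      write_table(tab, p("stepoff.csv"))
      sc <- stepoff_scatter(tab)
      write_table(sc$fits, p("stepoff_fits.csv"))
    }, c(p("stepoff.csv"), p("stepoff_fits.csv")))
  }

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
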