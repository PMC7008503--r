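#' Read a photon-count image stack from a multi-page TIFF
#'
#' Pixel data come from the TIFF; acquisition metadata (pixel pitch,
#' z-spacing, bit depth) come from a JSON sidecar, since TIFF containers
#' routinely store 12-bit counts in 16-bit samples.
#'
#' @param path Path to a multi-page TIFF with integer pixels.
#' @param sidecar Path to the JSON sidecar; default `<path>.json`. Must
#'   contain `pixel_pitch_um`, `z_spacing_um` and `bit_depth`.
#'
#' @return An [image_stack()].
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (!file.exists(sidecar)) abort(sprintf("missing sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("pixel_pitch_um", "z_spacing_um", "bit_depth")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0("sidecar is missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  for (i in seq_along(dims)) {
    if (!identical(dims[[i]], dims[[1]])) {
      abort(sprintf("ragged TIFF: page %d has different dimensions.", i))
    }
  }
  st <- image_stack(lapply(pages, function(p) matrix(as.numeric(p), nrow(p))),
                    pixel_pitch_um = meta$pixel_pitch_um,
                    z_spacing_um = meta$z_spacing_um,
                    bit_depth = meta$bit_depth)
  if (!is.null(meta$z_origin_um)) st$z_origin_um <- meta$z_origin_um
  st
}

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Counts are stored as 16-bit samples; the true bit depth and the
#' physical metadata go to the sidecar.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#'
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$planes)[3]
  pages <- lapply(seq_len(nz), function(k) stack$planes[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_pitch_um = stack$pixel_pitch_um,
               z_spacing_um = stack$z_spacing_um,
               bit_depth = stack$bit_depth)
  if (!is.null(stack$z_origin_um)) meta$z_origin_um <- stack$z_origin_um
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

pipeline_stages <- c("simulate", "directionality", "packing")

validate_pipeline_config <- function(config) {
  if (is.null(config$stages) || length(config$stages) == 0) {
    abort("`config$stages` must name at least one stage.")
  }
  unknown <- setdiff(config$stages, pipeline_stages)
  if (length(unknown) > 0) {
    abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed)) abort("`config$seed` is required.")
  if ("simulate" %in% config$stages) {
    sim <- config$simulate
    need <- c("R", "depths_um", "thickness_cm", "mus", "g", "n_photons")
    missing <- setdiff(need, names(sim))
    if (length(missing) > 0) {
      abort(paste0("simulate config is missing: ",
                   paste(missing, collapse = ", ")))
    }
  }
  if ("directionality" %in% config$stages) {
    dirc <- config$directionality
    if (is.null(dirc$optics) &&
        !("simulate" %in% config$stages && !is.null(config$simulate$mus))) {
      abort("directionality needs `optics` (mus, g, wavelength_nm) or an upstream simulate stage.")
    }
    if (!("simulate" %in% config$stages) &&
        (is.null(dirc$forward_tif) || is.null(dirc$backward_tif))) {
      abort("directionality needs input stacks or an upstream simulate stage.")
    }
  }
  if ("packing" %in% config$stages && !("simulate" %in% config$stages) &&
      is.null(config$packing$stack_tif)) {
    abort("packing needs `stack_tif` or an upstream simulate stage.")
  }
  invisible(config)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order (`simulate`,
#' `directionality`, `packing`), writing CSV/JSON results and a run
#' manifest into `out_dir`. All randomness flows from `config$seed`; no
#' stage mutates its inputs, and deterministic stages reproduce their
#' outputs bit-identically when rerun from the same configuration. The
#' configuration is validated in full before any stage executes.
#'
#' @param config A list: `stages` (character vector), `seed`, and
#'   per-stage blocks (`simulate`, `directionality`, `packing`); see the
#'   package vignette for the fields.
#' @param out_dir Output directory (created; must be fresh or contain
#'   only prior run outputs).
#'
#' @return A list of per-stage results, invisibly, with the manifest path
#'   attached as an attribute.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  stages <- intersect(pipeline_stages, config$stages) # dependency order
  sim_out <- NULL

  for (stage in stages) {
    if (stage == "simulate") {
      sim <- config$simulate
      phantom <- fiber_phantom_config(
        image_size = sim$image_size %||% 64,
        n_fibers = sim$n_fibers %||% 15,
        seed = child_seed(config$seed, 1)
      )
      optics <- optical_properties(sim$wavelength_nm %||% 445, sim$mus, sim$g)
      sim_out <- make_depth_stack(
        phantom, sim$R, optics,
        slab_geometry(sim$thickness_cm),
        detection_geometry(),
        depths_um = sim$depths_um,
        mc = mc_config(sim$n_photons, seed = child_seed(config$seed, 2))
      )
      write_stack(sim_out$pair$forward, file.path(out_dir, "forward.tif"))
      write_stack(sim_out$pair$backward, file.path(out_dir, "backward.tif"))
      jsonlite::write_json(
        sim_out$ground_truth[c("R", "depths_um", "fb_simulated")],
        file.path(out_dir, "ground_truth.json"),
        auto_unbox = TRUE, digits = NA
      )
      results$simulate <- sim_out$ground_truth
    } else if (stage == "directionality") {
      dirc <- config$directionality %||% list()
      if (!is.null(sim_out)) {
        pair <- sim_out$pair
        optics <- sim_out$ground_truth$optics
        thickness <- config$simulate$thickness_cm
      } else {
        fwd <- read_stack(dirc$forward_tif)
        bwd <- read_stack(dirc$backward_tif)
        pair <- fb_stack_pair(fwd, bwd, dirc$eff_f %||% 1, dirc$eff_b %||% 1)
        optics <- optical_properties(dirc$optics$wavelength_nm,
                                     dirc$optics$mus, dirc$optics$g)
        thickness <- dirc$thickness_cm
      }
      profile <- measure_fb_profile(pair,
                                    mask_threshold = dirc$mask_threshold %||% 15)
      fit <- extract_creation_ratio(
        profile, optics, slab_geometry(thickness), detection_geometry(),
        mc_config(dirc$n_photons %||% 2e4, seed = child_seed(config$seed, 3)),
        grid = dirc$grid %||% seq(1, 5, by = 0.25)
      )
      utils::write.csv(fit$profile, file.path(out_dir, "fb_profile.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(fb_creation = fit$fb_creation, reduced_chi2 = fit$reduced_chi2,
             boundary = fit$boundary),
        file.path(out_dir, "directionality.json"),
        auto_unbox = TRUE, digits = NA
      )
      results$directionality <- fit
    } else if (stage == "packing") {
      stack <- if (!is.null(sim_out)) {
        sim_out$pair$forward
      } else {
        read_stack(config$packing$stack_tif)
      }
      pk <- packing_efficiency(stack,
                               threshold = config$packing$threshold %||% 15)
      jsonlite::write_json(
        list(fraction = pk$fraction, threshold = pk$threshold,
             n_pixels_on = pk$n_pixels_on,
             n_pixels_total = pk$n_pixels_total),
        file.path(out_dir, "packing.json"), auto_unbox = TRUE, digits = NA
      )
      results$packing <- pk
    }
  }

  inputs <- character(0)
  for (f in c(config$directionality$forward_tif,
              config$directionality$backward_tif,
              config$packing$stack_tif)) {
    if (!is.null(f)) inputs[f] <- unname(tools::md5sum(f))
  }
  manifest <- list(
    tool = "shgoptics",
    version = as.character(utils::packageVersion("shgoptics")),
    config = config, seed = config$seed,
    input_digests = as.list(inputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  attr(results, "manifest") <- manifest_path
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
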