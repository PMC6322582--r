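#' Pipeline run configuration
#'
#' Bundles every tunable of the simulate/reconstruct/extract chain into one
#' serializable object, so a run is reproducible from its config plus seed.
#'
#' @param seed Integer seed for the phantom, noise and renderer.
#' @param pixel_size Reconstructed pixel size, mm.
#' @param image_size Slice grid side, px.
#' @param n_projections,angle_step Scan protocol (defaults: 380 x 0.6 deg,
#'   the 228-degree limited-angle protocol).
#' @param analysis_heights Two slice heights (mm) used for the size traits
#'   (reference = lower) and the angle computation.
#' @param noise_sd Additive Gaussian sinogram noise SD (0 = noiseless).
#' @param phantom Named list of [sample_plant()] arguments.
#' @param segmentation A [seg_config()]. The default derives the
#'   small-particle cutoff from physical scale: particles under 6 mm^2
#'   (converted to pixels at `pixel_size`) are discarded — far below the
#'   smallest plausible culm section (~16 mm^2 for a 4.5 mm culm) and far
#'   above the bright leaf-blade remnants that can survive thresholding.
#' @param render Named list of [render_side_view()] arguments.
#' @param max_shift Matching gate for [match_tillers()], mm.
#' @param interval Days between time points for growth rates.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1, pixel_size = 0.2, image_size = 544,
                       n_projections = 380, angle_step = 0.6,
                       analysis_heights = c(50, 55), noise_sd = 0,
                       phantom = list(),
                       segmentation = seg_config(
                         min_area = max(20, round(6 / pixel_size^2))),
                       render = list(), max_shift = 10, interval = 3) {
  stopifnot(length(analysis_heights) == 2, diff(analysis_heights) > 0)
  structure(list(seed = as.integer(seed), pixel_size = pixel_size,
                 image_size = as.integer(image_size),
                 n_projections = as.integer(n_projections),
                 angle_step = angle_step,
                 analysis_heights = analysis_heights, noise_sd = noise_sd,
                 phantom = phantom, segmentation = unclass(segmentation),
                 render = render, max_shift = max_shift, interval = interval),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to read or write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config A `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (n in intersect(names(raw), names(cfg))) cfg[[n]] <- raw[[n]]
  cfg$segmentation <- as.list(cfg$segmentation)
  cfg$analysis_heights <- as.numeric(cfg$analysis_heights)
  cfg
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_run_config(config, f)
  unname(tools::md5sum(f))
}

scanner_from_config <- function(config) {
  scanner_geometry(n_projections = config$n_projections,
                   angle_step = config$angle_step,
                   pixel_size = config$pixel_size)
}

#' Simulate a plant and write its acquisition bundle
#'
#' Samples a phantom, simulates the projection stack for the two analysis
#' heights under the configured limited-angle protocol, renders the RGB side
#' view, and writes everything to `dir`: numbered 16-bit grayscale projection
#' TIFFs (one per angle; row i is the detector row of analysis height i), an
#' `angles.txt` sidecar, `view.png`, `ground_truth.csv`, a `meta.yaml` with
#' the intensity scale, and an echo of the config (`config.yaml`).
#'
#' @param config A [run_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  geom <- scanner_from_config(config)
  plant <- do.call(sample_plant, c(list(seed = config$seed), config$phantom))
  angles <- scan_angles(geom)
  sinos <- lapply(seq_along(config$analysis_heights), function(i) {
    sl <- rasterize_slice(plant, config$analysis_heights[i], geom,
                          size = config$image_size)
    forward_project(sl, angles, noise_sd = config$noise_sd,
                    seed = config$seed + i)
  })
  scale <- max(1e-12, max(vapply(sinos, function(s) max(s$data), numeric(1))))
  nd <- ncol(sinos[[1]]$data)
  for (a in seq_along(angles)) {
    proj <- do.call(rbind, lapply(sinos, function(s) s$data[a, ]))
    tiff::writeTIFF(pmin(pmax(proj / scale, 0), 1),
                    file.path(dir, sprintf("proj_%04d.tif", a)),
                    bits.per.sample = 16)
  }
  writeLines(format(angles, trim = TRUE), file.path(dir, "angles.txt"))
  view <- do.call(render_side_view,
                  c(list(plant = plant, seed = config$seed), config$render))
  png::writePNG(view$image, file.path(dir, "view.png"))
  gt <- ground_truth(plant, config$analysis_heights)
  write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  yaml::write_yaml(list(scale = scale, heights = config$analysis_heights,
                        n_projections = length(angles),
                        image_size = config$image_size,
                        pixel_size = config$pixel_size,
                        seed = config$seed,
                        config_hash = config_hash(config)),
                   file.path(dir, "meta.yaml"))
  write_run_config(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read an acquisition bundle from disk
#'
#' @param dir Directory written by [simulate_bundle()].
#' @return List: `stack` (projection matrices, physical scale restored, with
#'   the angle list attached), `angles`, `meta`, `config`.
#' @export
read_bundle <- function(dir) {
  files <- sort(list.files(dir, pattern = "^proj_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no projection stack found in ", dir)
  for (f in c("angles.txt", "meta.yaml"))
    if (!file.exists(file.path(dir, f))) stop("missing bundle file: ", f)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  angles <- as.numeric(readLines(file.path(dir, "angles.txt")))
  if (length(angles) != length(files))
    stop("angle sidecar length does not match stack size")
  stack <- lapply(files, function(f) {
    m <- tiff::readTIFF(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * meta$scale
  })
  attr(stack, "angles") <- angles
  cfgf <- file.path(dir, "config.yaml")
  list(stack = stack, angles = angles, meta = meta,
       config = if (file.exists(cfgf)) read_run_config(cfgf) else run_config())
}

# canonical 75-trait column order (CT raw traits, then RGB raw traits)
ct_trait_names <- function() {
  c("MAXTTA", "MEANTTA", "SDTTA", "MAXTAPR", "MEANTAPR", "SDTAPR", "CHA",
    "THR", "TCR", "TTA", "TN", "MEANTD", "MAXTD", "SDTD",
    "MEANTA", "MAXTA", "SDTA")
}

rgb_trait_names <- function() {
  c("GCV", "GPA", "TPA", "GPAR", paste0("PC", 1:6), "PAR", "W", "H", "FDNIC",
    "TBR", "HWR", "FDIC", paste0("F", 1:20), "M", "SE", "S", "MU3", "U", "E",
    paste0("T", 1:15))
}

#' Extract CT tiller traits from a bundle
#'
#' Reconstructs the two analysis-height slices from the projection stack by
#' filtered back-projection, segments and measures the tiller sections, and
#' assembles the plant-level CT trait record (reference slice = lower
#' height) with the angle statistics from centroid displacement between the
#' two heights.
#'
#' @param bundle A directory path or the result of [read_bundle()].
#' @param config Optional [run_config()] override (default: the bundle's).
#' @return One-row data frame: the 17 CT trait columns plus `EFFTN`
#'   (effective tiller count).
#' @export
extract_ct_traits <- function(bundle, config = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  if (is.null(config)) config <- bundle$config
  heights <- as.numeric(bundle$meta$heights)
  px <- bundle$meta$pixel_size
  scfg <- do.call(seg_config, config$segmentation)
  slices <- lapply(seq_along(heights), function(i) {
    sino <- extract_sinogram(bundle$stack, i, angles = bundle$angles,
                             detector_pixel = px)
    sino$height <- heights[i]
    fbp_reconstruct(sino, output_size = bundle$meta$image_size)
  })
  labs <- lapply(slices, segment_tillers, cfg = scfg)
  regs <- lapply(labs, measure_regions)
  ord <- order(heights)
  st <- slice_traits(regs[[ord[1]]], labs[[ord[1]]], height = heights[ord[1]])
  plant <- plant_ct_traits(list(st))
  m <- match_tillers(regs[[ord[1]]], regs[[ord[2]]],
                     max_shift = config$max_shift)
  ast <- angle_stats(tiller_angle(m, dz = diff(heights[ord])))
  out <- cbind(plant[setdiff(ct_trait_names(), names(ast))],
               as.data.frame(as.list(ast)))
  out$EFFTN <- plant$effective_TN
  out[c(ct_trait_names(), "EFFTN")]
}

#' Extract RGB traits from a bundle
#'
#' @param dir Bundle directory containing `view.png`.
#' @return One-row data frame with the 58 RGB trait columns.
#' @export
extract_rgb_traits <- function(dir) {
  f <- file.path(dir, "view.png")
  if (!file.exists(f)) stop("missing bundle file: view.png")
  img <- png::readPNG(f)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  rgb_traits(img)[rgb_trait_names()]
}

#' Extract the full 75-trait record of a bundle
#'
#' @param dir Bundle directory.
#' @param plant_id Identifier for the output row.
#' @param out_csv Optional path to also write the record as CSV.
#' @return One-row data frame: `plant_id`, the 75 raw trait columns (17 CT +
#'   58 RGB, Table-style abbreviations), then `EFFTN`.
#' @export
extract_traits <- function(dir, plant_id = basename(dir), out_csv = NULL) {
  ct <- extract_ct_traits(dir)
  rgb <- extract_rgb_traits(dir)
  out <- cbind(data.frame(plant_id = plant_id),
               ct[ct_trait_names()], rgb, EFFTN = ct$EFFTN)
  rownames(out) <- NULL
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE, na = "")
  out
}

#' Derived growth traits and model comparison across time points
#'
#' Joins per-time-point trait tables by plant, emits per-interval absolute
#' and relative growth rates (CT traits indexed i = 2..9, RGB traits
#' i = 1..8, per the trait-table naming convention), a six-family growth
#' model comparison for the requested series, and tiller senescence when
#' effective tiller counts are present at the last time point.
#'
#' @param tables List of per-time-point data frames (time order), each with a
#'   `plant_id` column and trait columns.
#' @param interval Days between time points.
#' @param model_traits Trait columns to run the model comparison on.
#' @return List: `rates` (one row per plant), `models` (per plant and trait,
#'   a [compare_growth_models()] table), `senescence` (or `NULL`).
#' @export
growth_table <- function(tables, interval = 3, model_traits = c("TTA", "TPA")) {
  stopifnot(length(tables) >= 2)
  ids <- lapply(tables, function(d) sort(as.character(d$plant_id)))
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
    all_ids <- sort(unique(unlist(ids)))
    missing <- vapply(seq_along(tables), function(i)
      paste(setdiff(all_ids, ids[[i]]), collapse = ","), character(1))
    stop("inconsistent plant IDs across time points; missing per time point: ",
         paste(sprintf("t%d:[%s]", seq_along(tables), missing),
               collapse = " "))
  }
  tables <- lapply(tables, function(d) d[order(as.character(d$plant_id)), ])
  plants <- as.character(tables[[1]]$plant_id)
  ct_rate_traits <- intersect(c("TTA", "TN"), names(tables[[1]]))
  rgb_rate_traits <- intersect(c("TPA", "H"), names(tables[[1]]))
  rates <- do.call(rbind, lapply(seq_along(plants), function(pi) {
    row <- list(plant_id = plants[pi])
    for (tr in c(ct_rate_traits, rgb_rate_traits)) {
      org <- if (tr %in% ct_rate_traits) 2 else 1
      x <- vapply(tables, function(d) as.numeric(d[[tr]][pi]), numeric(1))
      row <- c(row, as.list(absolute_growth_rate(x, interval, tr, org)),
               as.list(relative_growth_rate(x, interval, tr, org)))
    }
    as.data.frame(row, check.names = FALSE)
  }))
  models <- list()
  tt <- interval * seq_along(tables) # days, time point i at i * interval
  for (tr in intersect(model_traits, names(tables[[1]]))) {
    for (pi in seq_along(plants)) {
      y <- vapply(tables, function(d) as.numeric(d[[tr]][pi]), numeric(1))
      if (all(is.finite(y)))
        models[[paste(plants[pi], tr, sep = ":")]] <-
          compare_growth_models(tt, y)
    }
  }
  sen <- NULL
  last <- tables[[length(tables)]]
  if (all(c("TN", "EFFTN") %in% names(last))) {
    ok <- is.finite(last$TN) & last$TN > 0 & is.finite(last$EFFTN)
    sen <- data.frame(plant_id = plants[ok], TN_9 = last$TN[ok],
                      TN_effective = last$EFFTN[ok],
                      senescence = (last$TN[ok] - last$EFFTN[ok]) / last$TN[ok])
  }
  list(rates = rates, models = models, senescence = sen)
}
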