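# pipeline orchestration: simulate -> reconstruct -> evaluate, with on-disk
# artifacts, manifests and a thin CLI (inst/cli/lungeit.R)

#' Write a pixel image as plain text
#'
#' 32x32 (or grid_size^2) matrix, one row per line, tab separated, full
#' double precision, masked pixels as NA.
#' @param image an \code{eit_image}
#' @param path output file
#' @export
write_pixel_image <- function(image, path) {
  v <- unclass(image)
  lines <- apply(v, 1, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pixel_image
#' @export
read_pixel_image <- function(path) {
  lines <- readLines(path)
  v <- do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), function(x) {
    x[x == "NA"] <- NA_character_
    as.numeric(x)
  }))
  if (nrow(v) != ncol(v)) stop("malformed pixel image file: ", path)
  mask <- !is.na(v)
  structure(v, mask = mask, pixel_area = NULL,
            class = c("eit_image", "matrix"))
}

simulate_config_defaults <- function() {
  list(n_subjects = 8, master_seed = 1, mesh_density = 8,
       n_electrodes = 16, phantom = unclass(phantom_config()))
}

read_simulate_config <- function(path) {
  if (!file.exists(path)) stop("usage error: config file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  defs <- simulate_config_defaults()
  bad <- setdiff(names(obj), names(defs))
  if (length(bad)) stop("invalid config: unknown field(s) ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defs, obj)
  pb <- setdiff(names(cfg$phantom), names(unclass(phantom_config())))
  if (length(pb)) stop("invalid config: unknown phantom field(s) ", paste(pb, collapse = ", "))
  cfg$phantom$splits <- unlist(cfg$phantom$splits)
  cfg$phantom <- do.call(phantom_config, cfg$phantom)
  cfg
}

#' Simulate a phantom ensemble to disk
#'
#' Generates the ensemble and writes one frame-sequence file per recording
#' plus a run manifest (config hash, per-recording seeds and file hashes)
#' sufficient to reproduce the output bit for bit.
#'
#' @param config path to a JSON configuration file, or a configuration list
#'   (fields: n_subjects, master_seed, mesh_density, n_electrodes, phantom);
#'   NULL for defaults
#' @param out_dir output directory
#' @return the manifest, invisibly
#' @export
run_simulate <- function(config = NULL, out_dir) {
  cfg <- if (is.null(config)) {
    d <- simulate_config_defaults(); d$phantom <- do.call(phantom_config, d$phantom); d
  } else if (is.character(config)) read_simulate_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- build_mesh(density = cfg$mesh_density, n_electrodes = cfg$n_electrodes)
  protocol <- make_adjacent_protocol(cfg$n_electrodes)
  ens <- simulate_ensemble(mesh, protocol, cfg$phantom,
                           n_subjects = cfg$n_subjects,
                           master_seed = cfg$master_seed)
  inventory <- list()
  for (si in seq_along(ens$subjects)) {
    for (cond in names(ens$subjects[[si]]$recordings)) {
      fs <- ens$subjects[[si]]$recordings[[cond]]
      fn <- sprintf("seq_s%02d_%s.tsv", si, cond)
      write_frames(fs, file.path(out_dir, fn))
      inventory[[length(inventory) + 1]] <-
        list(file = fn, subject = si, condition = cond, seed = fs$meta$seed,
             md5 = unname(tools::md5sum(file.path(out_dir, fn))))
    }
  }
  manifest <- list(
    tool = "lungeit", stage = "simulate",
    version = as.character(utils::packageVersion("lungeit")),
    config = list(n_subjects = cfg$n_subjects, master_seed = cfg$master_seed,
                  mesh_density = cfg$mesh_density,
                  n_electrodes = cfg$n_electrodes,
                  phantom = unclass(cfg$phantom)),
    config_hash = model_cache_key_raw(cfg),
    files = inventory)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Reconstruct tidal images for a simulated ensemble on disk
#'
#' Builds (or retrieves from cache) the NF-calibrated model for the preset,
#' then for every recording detects breaths and writes the tidal pixel
#' image. Logs every default that stands in for an unreported study
#' parameter (NF target, ROI threshold, NOSER exponent, lung contrast, tau).
#'
#' @param data_dir directory produced by \code{\link{run_simulate}}
#' @param preset algorithm preset name (see \code{\link{list_presets}})
#' @param out_dir output directory for tidal images and the manifest
#' @param nf_target noise-figure target (default 0.5)
#' @param recon_density reconstruction mesh density (default 6, a coarse
#'   mesh distinct from the simulation mesh)
#' @param cache_dir calibration cache directory (NULL disables caching)
#' @param verbose print progress and parameter log
#' @return invisibly, a data.frame of written images
#' @export
run_reconstruct <- function(data_dir, preset = "A0", out_dir,
                            nf_target = 0.5, recon_density = 6,
                            cache_dir = NULL, verbose = TRUE) {
  man_path <- file.path(data_dir, "manifest.json")
  if (!file.exists(man_path)) stop("usage error: no manifest.json in ", data_dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  config <- preset_config(preset)
  mesh <- build_mesh(density = recon_density,
                     n_electrodes = man$config$n_electrodes)
  protocol <- make_adjacent_protocol(man$config$n_electrodes)
  spec <- nf_spec(nf_target = nf_target)
  files <- man$files
  frames0 <- read_frames(file.path(data_dir, files$file[1]))
  model <- build_reconstructor(config, mesh, protocol, spec,
                               frames = frames0, cache_dir = cache_dir)
  if (verbose) {
    hit <- isTRUE(model$provenance$cache_hit)
    message(sprintf("preset %s: NF = %.4g (target %.3g)%s", preset,
                    model$provenance$noise_figure, nf_target,
                    if (hit) " [calibration cache hit]" else ""))
    message(sprintf("defaults in effect: NF target %.3g, ROI threshold 0.2, NOSER p %.2g, lung contrast %.2g, tau %.2g",
                    nf_target, config$noser_p, config$lung_contrast, config$tau))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_rows <- list()
  for (i in seq_len(nrow(files))) {
    fs <- read_frames(file.path(data_dir, files$file[i]))
    ev <- detect_breaths(fs)
    ti <- tidal_image(fs, ev, model)
    fn <- sprintf("tidal_s%02d_%s.txt", files$subject[i], files$condition[i])
    write_pixel_image(ti, file.path(out_dir, fn))
    out_rows[[i]] <- data.frame(file = fn, subject = files$subject[i],
                                condition = files$condition[i],
                                stringsAsFactors = FALSE)
  }
  inv <- do.call(rbind, out_rows)
  manifest <- list(tool = "lungeit", stage = "reconstruct",
                   version = as.character(utils::packageVersion("lungeit")),
                   preset = preset, nf_target = nf_target,
                   achieved_nf = model$provenance$noise_figure,
                   hyperparameter = if (!is.null(model$provenance$lambda))
                     model$provenance$lambda else model$provenance$k,
                   recon_density = recon_density,
                   source_manifest = man$config_hash,
                   files = inv)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(inv)
}

#' Evaluate reconstructed tidal images into the battery report
#'
#' Reads the tidal images of one or more presets, computes per-subject lung
#' ROIs, V_T and CoV, runs the statistical battery and renders the
#' hypotheses x algorithms grid.
#'
#' @param images_dirs named character vector of directories produced by
#'   \code{\link{run_reconstruct}} (names = algorithm labels; unnamed
#'   directories use their manifest's preset)
#' @param out_dir optional directory for the battery table (TSV) and report
#' @param roi_threshold ROI threshold fraction
#' @return list with \code{results} (functional table), \code{battery} and
#'   \code{grid}
#' @export
run_evaluate <- function(images_dirs, out_dir = NULL, roi_threshold = 0.2) {
  all_rows <- list()
  nf_log <- list()
  for (k in seq_along(images_dirs)) {
    dir <- images_dirs[k]
    man_path <- file.path(dir, "manifest.json")
    if (!file.exists(man_path)) stop("usage error: no manifest.json in ", dir)
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    label <- if (!is.null(names(images_dirs)) && nzchar(names(images_dirs)[k]))
      names(images_dirs)[k] else man$preset
    nf_log[[label]] <- man$achieved_nf
    files <- man$files
    subjects <- unique(files$subject)
    for (si in subjects) {
      sub <- files[files$subject == si, ]
      vents <- list()
      for (i in seq_len(nrow(sub))) {
        path <- file.path(dir, sub$file[i])
        im <- tryCatch(read_pixel_image(path),
                       error = function(e) stop("malformed image file: ", path))
        vents[[sub$condition[i]]] <- ventilation_signal(im)
      }
      roi <- lung_roi(vents, threshold_fraction = roi_threshold)
      for (cond in names(vents)) {
        all_rows[[length(all_rows) + 1]] <- data.frame(
          subject = si, condition = cond, algorithm = label,
          vt = compute_vt(vents[[cond]], roi),
          cov = compute_cov(vents[[cond]], roi), stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, all_rows)
  battery <- run_battery(results)
  grid <- battery_grid(battery)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(battery, file.path(out_dir, "battery.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(results, file.path(out_dir, "functional_results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    rep <- c("lungeit functional evaluation report",
             sprintf("algorithms: %s", paste(names(nf_log), collapse = ", ")),
             sprintf("achieved noise figures: %s",
                     paste(sprintf("%s=%.4g", names(nf_log),
                                   unlist(nf_log)), collapse = ", ")),
             "", "p-value grid (rows = hypotheses):",
             utils::capture.output(print(grid, digits = 4)))
    writeLines(rep, file.path(out_dir, "report.txt"))
  }
  list(results = results, battery = battery, grid = grid,
       achieved_nf = nf_log)
}
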