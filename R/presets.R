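#' Reconstruction configuration and named algorithm presets
#'
#' A \code{recon_config} fixes one choice on each design axis of the
#' compared algorithm family:
#' \itemize{
#'   \item data type: normalized difference vs plain difference data;
#'   \item background: homogeneous vs bilateral-lung conductivity (the
#'     sensitivity matrix is recomputed at the lung background);
#'   \item prior: NOSER amplitude-diagonal, spatial high-pass, or TSVD;
#'   \item data noise model: uniform, reciprocity-weighted, or
#'     movement-augmented covariance;
#'   \item data norm: quadratic or robust L1 (iterative);
#'   \item model norm: quadratic or total variation (iterative).
#' }
#' The named presets are: \code{A0} the baseline one-step Gauss-Newton
#' solver (normalized difference data, homogeneous background, NOSER prior,
#' uniform noise, quadratic norms) and single-axis variants \code{F2} (plain
#' difference data), \code{F3-2D} (lung background), \code{F4} (electrode
#' movement noise), \code{I1} (reciprocity weighting), \code{I2} (robust
#' data norm), \code{I3} (high-pass prior), \code{I4} (TSVD), \code{I5}
#' (total variation).
#'
#' @param preset preset name, see \code{\link{list_presets}}
#' @param ... named overrides of individual config fields
#' @return list of class \code{recon_config}
#' @export
preset_config <- function(preset = "A0", ...) {
  if (!preset %in% list_presets())
    stop("unknown preset '", preset, "'; available: ",
         paste(list_presets(), collapse = ", "))
  cfg <- list(
    preset = preset,
    data_type = "normalized",     # normalized | difference
    background = "homogeneous",   # homogeneous | lung
    prior = "noser",              # noser | hpf | tsvd
    noise_model = "uniform",      # uniform | reciprocity | movement
    data_norm = "quadratic",      # quadratic | l1
    model_norm = "quadratic",     # quadratic | tv
    noser_p = 0.5,
    hpf_cutoff = 0.1,
    lung_contrast = 0.2,
    tau = 0.1,
    movement_scale = "auto",      # "auto" = calibrated to the base covariance
    tol = 1e-6,
    max_iter = 50
  )
  switch(preset,
    "A0" = NULL,
    "F2" = { cfg$data_type <- "difference" },
    "F3-2D" = { cfg$background <- "lung" },
    "F4" = { cfg$noise_model <- "movement" },
    "I1" = { cfg$noise_model <- "reciprocity" },
    "I2" = { cfg$data_norm <- "l1" },
    "I3" = { cfg$prior <- "hpf" },
    "I4" = { cfg$prior <- "tsvd" },
    "I5" = { cfg$model_norm <- "tv" })
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config field '", nm, "'")
    cfg[[nm]] <- dots[[nm]]
  }
  validate_recon_config(cfg)
  structure(cfg, class = "recon_config")
}

validate_recon_config <- function(cfg) {
  stopifnot(cfg$data_type %in% c("normalized", "difference"),
            cfg$background %in% c("homogeneous", "lung"),
            cfg$prior %in% c("noser", "hpf", "tsvd"),
            cfg$noise_model %in% c("uniform", "reciprocity", "movement"),
            cfg$data_norm %in% c("quadratic", "l1"),
            cfg$model_norm %in% c("quadratic", "tv"))
  if (cfg$tol <= 0) stop("configuration error: tol must be > 0")
  invisible(cfg)
}

#' @rdname preset_config
#' @export
list_presets <- function() c("A0", "F2", "F3-2D", "F4", "I1", "I2", "I3", "I4", "I5")

#' @export
print.recon_config <- function(x, ...) {
  cat(sprintf("recon_config [%s]: %s data, %s background, %s prior, %s noise, %s/%s norms\n",
              x$preset, x$data_type, x$background, x$prior, x$noise_model,
              x$data_norm, x$model_norm))
  invisible(x)
}

#' Serialize / restore a reconstruction configuration
#'
#' Flat JSON round trip of a \code{recon_config}.
#' @param cfg a \code{recon_config}
#' @param path file path
#' @export
write_recon_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_recon_config
#' @export
read_recon_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(preset_config, c(list(preset = obj$preset),
                           obj[setdiff(names(obj), "preset")]))
}

#' Build and NF-calibrate a reconstruction model from a configuration
#'
#' Assembles the sensitivity matrix, prior, and data weighting prescribed by
#' the configuration and calibrates the hyperparameter (or TSVD rank) to the
#' noise-figure target, so that all presets are compared at matched noise
#' performance.
#'
#' @param config a \code{recon_config} (or preset name)
#' @param mesh reconstruction mesh
#' @param protocol an \code{eit_protocol}
#' @param spec an \code{\link{nf_spec}}
#' @param frames optional \code{eit_frames} of raw voltages; required for the
#'   reciprocity noise model (preset I1)
#' @param contact_impedance forward-model contact impedance
#' @param cache_dir optional directory for on-disk caching of calibrated
#'   models, keyed by (mesh, preset, NF spec)
#' @return calibrated \code{eit_model}; provenance records the config,
#'   achieved NF and hyperparameter
#' @export
build_reconstructor <- function(config, mesh, protocol, spec = nf_spec(),
                                frames = NULL, contact_impedance = 0.01,
                                cache_dir = NULL) {
  if (is.character(config)) config <- preset_config(config)
  validate_recon_config(config)

  if (!is.null(cache_dir)) {
    key <- model_cache_key(config, mesh, spec)
    cache_file <- file.path(cache_dir, paste0("model-", key, ".rds"))
    if (file.exists(cache_file)) {
      model <- readRDS(cache_file)
      model$provenance$cache_hit <- TRUE
      return(model)
    }
  }

  normalized <- config$data_type == "normalized"
  sigma0 <- if (config$background == "lung") {
    lung_background_model(mesh, contrast = config$lung_contrast)
  } else {
    conductivity_field(1, mesh)
  }
  J <- conductivity_jacobian(mesh, sigma0, protocol, normalized = normalized,
                             contact_impedance = contact_impedance)
  v_ref <- attr(J, "v_ref")

  W <- switch(config$noise_model,
    uniform = 1,
    reciprocity = {
      if (is.null(frames))
        stop("the reciprocity noise model needs a frame sequence (frames = ...)")
      reciprocity_weights(frames, tau = config$tau)
    },
    movement = {
      M <- movement_jacobian(mesh, sigma0, protocol,
                             contact_impedance = contact_impedance)
      if (normalized) M <- M / v_ref
      # scale M so its structured term is commensurate with unit channel noise
      sc <- if (identical(config$movement_scale, "auto"))
        calibrate_movement_scale(1, M) else as.numeric(config$movement_scale)
      Sig <- movement_augmented_covariance(1, M, sc)
      solve(Sig)
    })

  R <- switch(config$prior,
    noser = noser_prior(J, p = config$noser_p),
    hpf = hpf_prior(mesh, cutoff_fraction = config$hpf_cutoff),
    tsvd = NULL)

  prov <- list(preset = config$preset, config = unclass(config),
               normalized = normalized,
               contact_impedance = contact_impedance)

  if (config$prior == "tsvd") {
    sv <- svd(J)
    tol <- max(dim(J)) * .Machine$double.eps * sv$d[1]
    rank <- sum(sv$d > tol)
    builder <- function(k) tsvd_model(J, k, provenance = prov, sv = sv)
    model <- calibrate_hyperparameter(builder, J, mesh, spec,
                                      discrete = seq_len(rank))
  } else if (config$data_norm == "l1") {
    builder <- function(l) {
      B0 <- gn_one_step(J, R, W, l)$B   # shared quadratic initializer
      new_eit_model(
        solve_fun = function(y) as.numeric(
          robust_reconstruct(J, R, W, l, y, tol = config$tol,
                             max_iter = config$max_iter,
                             x0 = B0 %*% as.numeric(y))),
        kind = "iterative",
        provenance = c(list(solver = "robust_l1", lambda = l), prov))
    }
    model <- calibrate_hyperparameter(builder, J, mesh, spec)
  } else if (config$model_norm == "tv") {
    edges <- mesh_interior_edges(mesh)
    builder <- function(l) {
      new_eit_model(
        solve_fun = function(y) as.numeric(
          tv_reconstruct(J, W, l, mesh, y, tol = config$tol,
                         max_iter = config$max_iter, edges = edges)),
        kind = "iterative",
        provenance = c(list(solver = "tv", lambda = l), prov))
    }
    model <- calibrate_hyperparameter(builder, J, mesh, spec)
  } else {
    builder <- function(l) gn_one_step(J, R, W, l, provenance = prov)
    model <- calibrate_hyperparameter(builder, J, mesh, spec)
  }
  model$J <- J
  model$mesh <- mesh

  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(model, cache_file)
  }
  model
}

# content hash for the calibration cache: mesh generation parameters,
# config, and NF spec
model_cache_key <- function(config, mesh, spec) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(mp = mesh$params, radius = mesh$radius,
               n_el = mesh$n_electrodes, cfg = unclass(config),
               spec = unclass(spec)),
          tf, version = 2)
  unname(tools::md5sum(tf))
}
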