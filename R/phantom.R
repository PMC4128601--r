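# synthetic ventilated-thorax phantom: multi-subject, multi-condition frame
# sequences with the acquisition's statistical structure

#' Phantom configuration
#'
#' Describes the simulated ventilated thorax and acquisition. Defaults
#' emulate the study protocol: 16-electrode adjacent acquisition at 13
#' frames/s for 60 s per recording, respiratory rate 20/min with a raised
#' cosine breath of inspiration:expiration 1:2, six recordings per subject
#' (stages Z21a, P21a, Z100, P100, Z21b, P21b), bilateral elliptic lungs,
#' and condition-dependent dorsoventral ventilation splits with the total
#' tidal amplitude conserved across conditions ("V_T does not change").
#' Acquisition imperfections: per-channel multiplicative gains (fixed within
#' a recording), additive Gaussian channel noise, and optional
#' breathing-synchronized electrode movement (applied to first order through
#' the movement sensitivity matrix).
#'
#' Dorsoventral splits (dorsal fraction of total tidal amplitude):
#' ZEEP-21 0.5; PEEP adds +0.1 dorsal (recruitment of dependent lung);
#' ZEEP-100 shifts to 0.35 (absorption atelectasis of dependent lung);
#' PEEP-100 returns to 0.5. Effect sizes are free parameters of the phantom
#' (the study reports only p-values), chosen to be detectable at n = 8 with
#' the battery margins.
#'
#' @param frame_rate frames per second (default 13)
#' @param duration recording length in seconds (default 60)
#' @param breath_rate breaths per minute (default 20)
#' @param tidal_depth mean fractional conductivity modulation of lung tissue
#'   at end-inspiration (default 0.15)
#' @param splits named vector of dorsal tidal fractions per condition
#' @param lung_contrast baseline lung/background conductivity ratio
#' @param noise_sd additive channel noise SD as a fraction of the mean
#'   absolute channel voltage (default 0.001)
#' @param gain_sd per-channel gain SD (default 0.01)
#' @param movement_amplitude electrode displacement amplitude in radius
#'   units at end-inspiration (default 0, no movement)
#' @param geometry_jitter_sd per-subject relative jitter of lung geometry
#'   (default 0.05)
#' @param split_jitter_sd per-subject SD of the dorsal fraction (default 0.02)
#' @param amplitude_jitter_sd per-subject relative SD of total tidal
#'   amplitude (default 0.1)
#' @return list of class \code{phantom_config}
#' @export
phantom_config <- function(frame_rate = 13, duration = 60, breath_rate = 20,
                           tidal_depth = 0.15,
                           splits = c(Z21a = 0.5, P21a = 0.6, Z100 = 0.35,
                                      P100 = 0.5, Z21b = 0.5, P21b = 0.6),
                           lung_contrast = 0.2, noise_sd = 0.001,
                           gain_sd = 0.01, movement_amplitude = 0,
                           geometry_jitter_sd = 0.05, split_jitter_sd = 0.02,
                           amplitude_jitter_sd = 0.1) {
  if (any(splits < 0 | splits > 1)) stop("configuration error: splits must be in [0, 1]")
  if (tidal_depth <= 0 || tidal_depth >= 1)
    stop("configuration error: tidal_depth must be in (0, 1)")
  if (frame_rate <= 0 || duration <= 0 || breath_rate <= 0)
    stop("configuration error: rates and duration must be > 0")
  structure(list(frame_rate = frame_rate, duration = duration,
                 breath_rate = breath_rate, tidal_depth = tidal_depth,
                 splits = splits, lung_contrast = lung_contrast,
                 noise_sd = noise_sd, gain_sd = gain_sd,
                 movement_amplitude = movement_amplitude,
                 geometry_jitter_sd = geometry_jitter_sd,
                 split_jitter_sd = split_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd),
            class = "phantom_config")
}

#' Raised-cosine breath waveform with 1:2 inspiration:expiration
#'
#' s(t) in [0, 1]: 0 at end-expiration, 1 at end-inspiration; inspiration
#' occupies the first third of the breath period, expiration the remaining
#' two thirds (ventilator setting I:E = 1:2).
#'
#' @param t time in seconds (vectorized)
#' @param breath_rate breaths per minute
#' @export
breath_waveform <- function(t, breath_rate = 20) {
  period <- 60 / breath_rate
  ti <- period / 3                 # inspiration duration
  ph <- t %% period
  ifelse(ph < ti,
         (1 - cos(pi * ph / ti)) / 2,
         (1 + cos(pi * (ph - ti) / (period - ti))) / 2)
}

#' Simulate one EIT recording of the ventilated-thorax phantom
#'
#' Solves the forward problem with the lung conductivity modulated by the
#' breath waveform, sigma_lung(t) = sigma_lung * (1 - a_region * s(t)),
#' where the regional amplitudes realize the condition's dorsoventral split
#' with the total tidal amplitude conserved across conditions. Per-channel
#' gains (fixed within the recording), additive Gaussian noise and optional
#' breathing-synchronized electrode movement are then applied. Fully
#' deterministic given the seed.
#'
#' @param mesh simulation mesh
#' @param protocol an \code{eit_protocol}
#' @param config a \code{phantom_config}
#' @param condition one of the stage labels in \code{names(config$splits)}
#' @param seed integer seed for this recording
#' @param subject_params optional per-subject parameters from
#'   \code{\link{simulate_ensemble}} (lung geometry, split and amplitude
#'   jitter); defaults to the nominal geometry
#' @param contact_impedance forward-model contact impedance
#' @return an \code{eit_frames} with metadata (condition, seed, ground-truth
#'   regional amplitudes)
#' @export
simulate_recording <- function(mesh, protocol, config, condition, seed,
                               subject_params = NULL, contact_impedance = 0.01) {
  if (!condition %in% names(config$splits))
    stop("unknown condition '", condition, "'; expected one of ",
         paste(names(config$splits), collapse = ", "))
  sp <- subject_params
  if (is.null(sp)) {
    sp <- list(lung_regions = default_lung_regions(),
               split_shift = 0, amp_factor = 1)
  }
  sigma0 <- lung_background_model(mesh, lung_regions = sp$lung_regions,
                                  contrast = config$lung_contrast)
  lung <- sigma0$labels != "background"
  if (!any(lung)) stop("phantom mesh has no lung elements")
  # dorsal/ventral partition of the lung at the lung elements' median height
  ymed <- stats::median(mesh$centroids[lung, 2])
  dorsal <- lung & mesh$centroids[, 2] < ymed
  ventral <- lung & !dorsal
  a_dor <- sum(mesh$areas[dorsal]); a_ven <- sum(mesh$areas[ventral])
  if (a_dor == 0 || a_ven == 0) stop("degenerate dorsal/ventral lung partition")

  f_dorsal <- min(max(config$splits[[condition]] + sp$split_shift, 0), 1)
  total <- config$tidal_depth * (a_dor + a_ven) * sp$amp_factor
  amp <- numeric(nrow(mesh$tris))
  amp[dorsal] <- f_dorsal * total / a_dor
  amp[ventral] <- (1 - f_dorsal) * total / a_ven
  if (any(amp >= 1))
    stop("configuration error: split implies non-positive lung conductivity")

  n_frames <- round(config$duration * config$frame_rate)
  t <- (seq_len(n_frames) - 1) / config$frame_rate
  s <- breath_waveform(t, config$breath_rate)

  # the noise-free signal depends on t only through s(t); solve each unique
  # phase once and tile (exact for the periodic waveform)
  su <- unique(s)
  vmat_u <- matrix(0, nrow = length(su), ncol = nrow(protocol))
  need_move <- config$movement_amplitude > 0
  M <- if (need_move)
    movement_jacobian(mesh, sigma0, protocol, contact_impedance = contact_impedance)
  for (k in seq_along(su)) {
    sig <- sigma0$values * (1 - amp * su[k])
    v <- as.numeric(solve_forward(mesh, sig, protocol,
                                  contact_impedance = contact_impedance))
    if (need_move) {
      # breathing-synchronized radial-tangential chest expansion: all
      # electrodes displaced tangentially toward the ventral midline,
      # amplitude proportional to s(t) (first-order model)
      ctrs <- mesh$params$electrode_centers
      disp <- config$movement_amplitude * su[k] *
        c(-sin(ctrs), cos(ctrs)) * sign(cos(ctrs))
      v <- v + as.numeric(M %*% disp)
    }
    vmat_u[k, ] <- v
  }
  vmat <- vmat_u[match(s, su), , drop = FALSE]

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  gains <- 1 + stats::rnorm(ncol(vmat), 0, config$gain_sd)
  noise_scale <- config$noise_sd * mean(abs(vmat))
  noise <- matrix(stats::rnorm(length(vmat), 0, noise_scale),
                  nrow = nrow(vmat))
  vmat <- sweep(vmat, 2, gains, "*") + noise

  frame_sequence(vmat, config$frame_rate, protocol,
                 meta = list(condition = condition, seed = seed,
                             f_dorsal = f_dorsal, total_amplitude = total,
                             gain_sd = config$gain_sd,
                             noise_sd = config$noise_sd))
}

#' Simulate a multi-subject phantom ensemble
#'
#' Generates \code{n_subjects} subjects, each with jittered lung geometry
#' and ventilation parameters, and six recordings per subject covering the
#' stage sequence Z21a, P21a, Z100, P100, Z21b, P21b (the repeated
#' ZEEP-21/PEEP-21 stages support the reproducibility tests). Per-subject
#' and per-recording seeds are derived deterministically from the master
#' seed.
#'
#' @inheritParams simulate_recording
#' @param n_subjects number of subjects (default 8)
#' @param master_seed master RNG seed
#' @return list of class \code{eit_ensemble}: per-subject lists of
#'   \code{eit_frames} keyed by condition, plus subject parameters
#' @export
simulate_ensemble <- function(mesh, protocol, config = phantom_config(),
                              n_subjects = 8, master_seed = 1,
                              contact_impedance = 0.01) {
  if (n_subjects < 2) stop("need n_subjects >= 2")
  conditions <- names(config$splits)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(master_seed)
  sub_seeds <- sample.int(2^30, n_subjects)
  subjects <- vector("list", n_subjects)
  for (si in seq_len(n_subjects)) {
    set.seed(sub_seeds[si])
    base <- default_lung_regions()
    jit <- function(x) x * (1 + stats::rnorm(1, 0, config$geometry_jitter_sd))
    regions <- lapply(base, function(rg) {
      rg$center <- rg$center + stats::rnorm(2, 0, config$geometry_jitter_sd * 0.5) *
        c(0.1, 0.1)
      rg$rx <- jit(rg$rx); rg$ry <- jit(rg$ry)
      rg
    })
    sp <- list(lung_regions = regions,
               split_shift = stats::rnorm(1, 0, config$split_jitter_sd),
               amp_factor = 1 + stats::rnorm(1, 0, config$amplitude_jitter_sd))
    rec_seeds <- sample.int(2^30, length(conditions))
    recs <- vector("list", length(conditions))
    names(recs) <- conditions
    for (ci in seq_along(conditions)) {
      recs[[ci]] <- simulate_recording(mesh, protocol, config, conditions[ci],
                                       seed = rec_seeds[ci],
                                       subject_params = sp,
                                       contact_impedance = contact_impedance)
      recs[[ci]]$meta$subject <- si
    }
    subjects[[si]] <- list(recordings = recs, params = sp, seed = sub_seeds[si])
  }
  structure(list(subjects = subjects, config = config,
                 master_seed = master_seed,
                 conditions = conditions),
            class = "eit_ensemble")
}

#' @export
print.eit_ensemble <- function(x, ...) {
  ns <- length(x$subjects)
  cat(sprintf("eit_ensemble: %d subjects x %d conditions (%s), master seed %d\n",
              ns, length(x$conditions), paste(x$conditions, collapse = ", "),
              x$master_seed))
  invisible(x)
}

#' Evaluate an ensemble with a reconstruction model
#'
#' Runs the functional pipeline on every recording: breath detection, tidal
#' image, per-subject lung ROI aggregated over the six recordings, then V_T
#' and CoV. Returns the functional-results table consumed by
#' \code{\link{run_battery}}.
#'
#' @param ensemble an \code{eit_ensemble}
#' @param model a calibrated \code{eit_model}
#' @param algorithm label stored in the results (defaults to the model's
#'   preset)
#' @param roi_threshold ROI threshold fraction (default 0.2)
#' @return data.frame with columns subject, condition, algorithm, vt, cov
#' @export
evaluate_ensemble <- function(ensemble, model, algorithm = NULL,
                              roi_threshold = 0.2) {
  if (is.null(algorithm))
    algorithm <- if (!is.null(model$provenance$preset)) model$provenance$preset else "model"
  rows <- list()
  for (si in seq_along(ensemble$subjects)) {
    sub <- ensemble$subjects[[si]]
    vents <- lapply(sub$recordings, function(fs) {
      ev <- detect_breaths(fs)
      ventilation_signal(tidal_image(fs, ev, model))
    })
    roi <- lung_roi(vents, threshold_fraction = roi_threshold)
    for (cond in names(vents)) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = si, condition = cond, algorithm = algorithm,
        vt = compute_vt(vents[[cond]], roi),
        cov = compute_cov(vents[[cond]], roi),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
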