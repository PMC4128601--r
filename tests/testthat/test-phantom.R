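# synthetic ventilated-thorax generator

test_that("recordings are seed-deterministic and conserve total tidal amplitude", {
  m <- fixture("mesh8"); p <- fixture("proto")
  cfg <- phantom_config()
  fs1 <- simulate_recording(m, p, cfg, "Z21a", seed = 7)
  fs2 <- simulate_recording(m, p, cfg, "Z21a", seed = 7)
  expect_identical(fs1$frames, fs2$frames)
  fs3 <- simulate_recording(m, p, cfg, "Z21a", seed = 8)
  expect_false(identical(fs1$frames, fs3$frames))
  # the total tidal conductivity amplitude is identical across conditions
  # ("no change" in V_T), while the dorsal share follows the intervention
  metas <- lapply(names(cfg$splits), function(cond)
    simulate_recording(m, p, cfg, cond, seed = 1)$meta)
  totals <- vapply(metas, `[[`, numeric(1), "total_amplitude")
  expect_equal(totals, rep(totals[1], length(totals)), tolerance = 1e-12)
  f_dor <- vapply(metas, `[[`, numeric(1), "f_dorsal")
  names(f_dor) <- names(cfg$splits)
  expect_gt(f_dor[["P21a"]], f_dor[["Z21a"]])     # PEEP recruits dependent lung
  expect_gt(f_dor[["P100"]], f_dor[["Z100"]])
  expect_lt(f_dor[["Z100"]], f_dor[["Z21a"]])     # absorption atelectasis
  expect_error(simulate_recording(m, p, cfg, "nope", seed = 1), "unknown condition")
  # an extreme split concentrating a deep breath in the dorsal region
  # would drive the lung conductivity non-positive
  expect_error(simulate_recording(m, p,
                                  phantom_config(tidal_depth = 0.8,
                                                 splits = c(Z21a = 1)),
                                  "Z21a", seed = 1),
               "configuration error")
})

test_that("noise-free phantom data inherit forward-model reciprocity", {
  fs <- fixture("quiet_recording")
  viol <- apply(fs$frames[c(1, 7, 20), ], 1, reciprocity_violation,
                protocol = fs$protocol)
  expect_lt(max(viol), 1e-8)
})

test_that("the dorsoventral split moves the reconstructed CoV as intended", {
  m <- fixture("mesh8"); p <- fixture("proto")
  cfg <- phantom_config(noise_sd = 0, gain_sd = 0)
  mod <- fixture("model_A0")
  cov_of <- function(cond) {
    fs <- simulate_recording(m, p, cfg, cond, seed = 5)
    vent <- ventilation_signal(tidal_image(fs, detect_breaths(fs), mod))
    compute_cov(vent, lung_roi(vent))
  }
  expect_lt(cov_of("P100"), cov_of("Z100"))   # PEEP shifts ventilation dorsally
  expect_gt(cov_of("Z100"), cov_of("Z21a"))   # pure O2 shifts it ventrally
})

test_that("ensembles have the full stage structure with distinct subjects", {
  m <- fixture("mesh6"); p <- fixture("proto")
  cfg <- phantom_config(duration = 15)   # shortened: structure test only
  ens <- simulate_ensemble(m, p, cfg, n_subjects = 3, master_seed = 2)
  expect_length(ens$subjects, 3)
  conds <- unlist(lapply(ens$subjects, function(s) names(s$recordings)))
  expect_equal(sort(unique(conds)),
               sort(c("Z21a", "P21a", "Z100", "P100", "Z21b", "P21b")))
  expect_equal(length(conds), 18)
  expect_true(all(table(conds) == 3))
  # distinct subjects differ (geometry jitter and sub-seeds)
  f1 <- ens$subjects[[1]]$recordings$Z21a$frames
  f2 <- ens$subjects[[2]]$recordings$Z21a$frames
  expect_false(identical(f1, f2))
  # reproducible from the master seed
  ens2 <- simulate_ensemble(m, p, cfg, n_subjects = 3, master_seed = 2)
  expect_identical(ens2$subjects[[2]]$recordings$P100$frames,
                   ens$subjects[[2]]$recordings$P100$frames)
  expect_error(simulate_ensemble(m, p, cfg, n_subjects = 1), "n_subjects")
})

test_that("breathing-synchronized electrode movement perturbs the data", {
  m <- fixture("mesh6"); p <- fixture("proto")
  quiet <- phantom_config(noise_sd = 0, gain_sd = 0, duration = 15)
  moving <- phantom_config(noise_sd = 0, gain_sd = 0, duration = 15,
                           movement_amplitude = 5e-3)
  f0 <- simulate_recording(m, p, quiet, "Z21a", seed = 4)
  f1 <- simulate_recording(m, p, moving, "Z21a", seed = 4)
  expect_false(identical(f0$frames, f1$frames))
  # movement is breathing-synchronized: zero at end-expiration frames
  s <- breath_waveform((seq_len(nrow(f0$frames)) - 1) / 13)
  at_exp <- which(s < 1e-12)
  expect_equal(f1$frames[at_exp, ], f0$frames[at_exp, ], tolerance = 1e-12)
})
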