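# rasterization, breath detection, tidal images, ROI, V_T and CoV

test_that("rasterization interpolates constants exactly and preserves integrals", {
  m <- fixture("mesh6")
  im <- rasterize(rep(2.5, nrow(m$tris)), m)
  msk <- attr(im, "mask")
  expect_equal(unname(im[msk]), rep(2.5, sum(msk)), tolerance = 1e-12)
  expect_true(is.na(im[1, 1]) && is.na(im[32, 32]))  # corners outside disc
  # area-weighted integral preserved within 1%
  f <- sin(2 * m$centroids[, 1]) + m$centroids[, 2]^2
  imf <- rasterize(f, m)
  int_pix <- sum(imf[msk] * attr(imf, "pixel_area")[msk])
  int_el <- sum(f * m$areas)
  expect_lt(abs(int_pix - int_el) / abs(int_el), 0.01)
  expect_error(rasterize(f[-1], m), "element count")
})

make_sine_frames <- function(amp_fun, n = 780, rate = 13) {
  p <- fixture("proto")
  t <- (seq_len(n) - 1) / rate
  vref <- abs(as.numeric(solve_forward(fixture("mesh6"), 1, p)))
  g <- amp_fun(t)
  frame_sequence(outer(1 + g, vref), rate, p)
}

test_that("a 20/min sinusoid at 13 Hz for 60 s yields exactly 20 inspirations", {
  fs <- make_sine_frames(function(t) 0.05 * sin(2 * pi * t / 3))
  ev <- detect_breaths(fs)
  expect_length(ev$inspiration, 20)
  expect_true(all(diff(ev$inspiration) > 0))
  # inspiration and expiration events interleave
  typ <- rep(c("i", "e"), c(length(ev$inspiration), length(ev$expiration)))
  ord <- order(c(ev$inspiration, ev$expiration))
  expect_false(any(typ[ord][-1] == typ[ord][-length(typ)]))
})

test_that("implausible tidal amplitudes are rejected, flat signals error", {
  fs <- make_sine_frames(function(t) 0.05 * sin(2 * pi * t / 3))
  spike_at <- which.max(fs$frames[, 1])   # an end-inspiration frame
  fs$frames[spike_at, ] <- fs$frames[spike_at, ] * 1.25  # ~5x tidal amplitude
  ev <- detect_breaths(fs)
  expect_true(spike_at %in% ev$rejected$index)
  expect_false(spike_at %in% ev$inspiration)
  expect_error(detect_breaths(make_sine_frames(function(t) 0 * t)),
               "no breaths")
})

test_that("tidal images commute with averaging for linear models and vanish without ventilation", {
  fs <- fixture("quiet_recording")
  ev <- detect_breaths(fs)
  mod <- fixture("model_A0")
  ti <- tidal_image(fs, ev, mod)
  msk <- attr(ti, "mask")
  # ventilated phantom: lung pixels show a conductivity decrease
  expect_lt(min(ti[msk]), 0)
  expect_lt(sum(ti[msk]), 0)
  # linearity: mean of per-breath difference images equals image of mean data
  vref <- colMeans(fs$frames[ev$expiration, , drop = FALSE])
  per_breath <- vapply(seq_along(ev$inspiration), function(k) {
    nb <- ev$expiration[which.min(abs(ev$expiration - ev$inspiration[k]))]
    y <- difference_data(fs$frames[ev$inspiration[k], ], vref) -
      difference_data(fs$frames[nb, ], vref)
    reconstruct(mod, y)
  }, numeric(nrow(fixture("mesh6")$tris)))
  y_mean <- difference_data(colMeans(fs$frames[ev$inspiration, , drop = FALSE]), vref) -
    difference_data(colMeans(fs$frames[ev$expiration, , drop = FALSE]), vref)
  x_mean <- reconstruct(mod, y_mean)
  # same up to the pairing of breaths (all expirations enter both averages)
  expect_equal(rasterize(rowMeans(per_breath), fixture("mesh6")),
               rasterize(x_mean, fixture("mesh6")), tolerance = 1e-6)
  # zero ventilation: constant frames reconstruct to the zero image
  fs0 <- frame_sequence(matrix(rep(fs$frames[1, ], 10), nrow = 10, byrow = TRUE),
                        13, fs$protocol)
  ev0 <- structure(list(inspiration = c(2L, 6L), expiration = c(4L, 8L)),
                   class = "breath_events")
  t0 <- tidal_image(fs0, ev0, mod)
  expect_equal(max(abs(t0[attr(t0, "mask")])), 0, tolerance = 1e-12)
  expect_error(tidal_image(fs, structure(list(inspiration = integer(0),
                                              expiration = integer(0)),
                                         class = "breath_events"), mod),
               "empty")
})

test_that("lung ROI thresholding is monotone and unions across recordings", {
  fs <- fixture("quiet_recording")
  ev <- detect_breaths(fs)
  vent <- ventilation_signal(tidal_image(fs, ev, fixture("model_A0")))
  msk <- attr(vent, "mask")
  roi1 <- lung_roi(vent, 0.2)
  expect_true(all(which(roi1) %in% which(msk)))  # subset of the disc
  expect_gt(sum(roi1), 0)
  # raising the threshold never grows the ROI
  roi_hi <- lung_roi(vent, 0.5)
  expect_true(all(roi_hi[roi1 == FALSE] == FALSE))
  expect_lte(sum(roi_hi), sum(roi1))
  # uniform image puts every inside pixel in the ROI
  u <- vent; u[msk] <- 1
  expect_equal(sum(lung_roi(u, 0.2)), sum(msk))
  # union ROI contains each single-recording ROI
  vent2 <- ventilation_signal(tidal_image(fs, ev, fixture("model_F2")))
  roi_u <- lung_roi(list(vent, vent2), 0.2)
  expect_true(all(roi_u[roi1]))
  expect_true(all(roi_u[lung_roi(vent2, 0.2)]))
  z <- vent; z[msk] <- 0
  expect_error(lung_roi(z, 0.2), "all-zero")
  expect_error(lung_roi(vent, 1.2), "configuration error")
})

test_that("V_T is linear in amplitude and CoV follows the coordinate convention", {
  fs <- fixture("quiet_recording")
  ev <- detect_breaths(fs)
  vent <- ventilation_signal(tidal_image(fs, ev, fixture("model_A0")))
  roi <- lung_roi(vent, 0.2)
  vt <- compute_vt(vent, roi)
  expect_gt(vt, 0)
  # doubling amplitude doubles V_T; full-mask ROI sums the whole image
  v2 <- vent; v2[] <- 2 * unclass(vent)
  attributes(v2) <- attributes(vent)
  expect_equal(compute_vt(v2, roi), 2 * vt, tolerance = 1e-12)
  msk <- attr(vent, "mask")
  full <- structure(msk, class = c("eit_roi", "matrix"))
  expect_equal(compute_vt(vent, full), sum(vent[msk]), tolerance = 1e-12)
  # CoV invariance to global scaling
  expect_equal(compute_cov(v2, roi), compute_cov(vent, roi), tolerance = 1e-12)

  # synthetic images pin the CoV convention
  blank <- matrix(0, 32, 32)
  mk <- function(vals) structure(vals, mask = msk,
                                 class = c("eit_image", "matrix"))
  sym <- blank; sym[16, 14] <- 1; sym[17, 14] <- 1   # mirror rows about midline
  expect_equal(compute_cov(mk(sym), full), 0, tolerance = 1e-12)
  ventral <- blank; ventral[1, which(msk[1, ])] <- 1
  expect_equal(compute_cov(mk(ventral), full), 1 - 1 / 32)
  # moving amplitude ventrally strictly increases CoV
  shift <- blank; shift[10, 16] <- 0.6; shift[20, 16] <- 0.4
  shift2 <- blank; shift2[10, 16] <- 0.7; shift2[20, 16] <- 0.3
  expect_gt(compute_cov(mk(shift2), full), compute_cov(mk(shift), full))
  expect_error(compute_cov(mk(blank), full), "zero total")
})
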