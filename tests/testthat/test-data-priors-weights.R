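# difference data, regularization priors, data-noise weighting

test_that("difference data modes follow their closed forms", {
  vref <- c(1, -2, 0.5, 4)
  expect_equal(difference_data(vref, vref, TRUE), rep(0, 4))
  expect_equal(difference_data(vref, vref, FALSE), rep(0, 4))
  expect_equal(difference_data(1.1 * vref, vref, TRUE), rep(0.1, 4))
  # identical per-channel gains cancel in normalized but not plain data
  g <- c(1.02, 0.97, 1.01, 0.99)
  v <- vref * c(1.3, 0.8, 1.1, 1.0)
  expect_equal(difference_data(g * v, g * vref, TRUE),
               difference_data(v, vref, TRUE))
  expect_false(isTRUE(all.equal(difference_data(g * v, g * vref, FALSE),
                                difference_data(v, vref, FALSE))))
  expect_error(difference_data(c(1, 1), c(1, 0), TRUE), "channel\\(s\\) 2")
})

test_that("NOSER prior is diagonal with the stated homogeneity", {
  J <- fixture("J6n")
  R <- noser_prior(J, p = 0.5)
  expect_true(all(R[upper.tri(R)] == 0) && all(R[lower.tri(R)] == 0))
  expect_true(all(diag(R) > 0))
  # scaling J by c scales the prior by c^(2p)
  expect_equal(noser_prior(3 * J, p = 0.5), 3 * R, tolerance = 1e-12)
  expect_equal(noser_prior(2 * J, p = 0.25), 2^0.5 * noser_prior(J, 0.25),
               tolerance = 1e-12)
  # orthonormal columns with p = 0.5 give the identity
  Q <- qr.Q(qr(matrix(rnorm(30), 6, 5)))
  expect_equal(noser_prior(Q, 0.5), diag(5), tolerance = 1e-12)
  expect_error(noser_prior(cbind(J, 0)), "all-zero")
})

test_that("high-pass prior annihilates DC and penalizes oscillation", {
  m <- fixture("mesh6")
  R <- hpf_prior(m)
  ne <- nrow(m$tris)
  const <- rep(1, ne)
  set.seed(2)
  rnd <- rnorm(ne)
  q_const <- drop(const %*% R %*% const) / sum(const^2)
  q_rnd <- drop(rnd %*% R %*% rnd) / sum(rnd^2)
  expect_lt(q_const / q_rnd, 1e-6)
  # oscillating image scores a higher penalty than a smooth ramp of equal norm
  osc <- ifelse(seq_len(ne) %% 2 == 0, 1, -1)
  ramp <- m$centroids[, 1]
  ramp <- ramp / sqrt(sum(ramp^2)) * sqrt(sum(osc^2))
  expect_gt(drop(osc %*% R %*% osc), drop(ramp %*% R %*% ramp))
  # symmetric PSD
  expect_equal(R, t(R), tolerance = 1e-12)
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(hpf_prior(m, 1.5), "configuration error")
})

test_that("reciprocity weights react to reciprocal mismatch only", {
  p <- fixture("proto")
  v <- as.numeric(solve_forward(fixture("mesh6"), 1, p))
  fs <- frame_sequence(rbind(v, v, v), 13, p)
  w <- reciprocity_weights(fs)
  expect_equal(w, rep(1, 208), tolerance = 1e-10)   # perfectly reciprocal
  # corrupting one reciprocal pair lowers exactly those weights
  r <- attr(p, "reciprocal")
  ch <- 5
  v2 <- v
  v2[ch] <- v2[ch] + 0.5 * max(abs(v))
  fs2 <- frame_sequence(rbind(v2, v2), 13, p)
  w2 <- reciprocity_weights(fs2)
  bad <- c(ch, r[ch])
  expect_true(all(w2[bad] < min(w2[-bad])))
  # invariant to global data scaling
  fs3 <- frame_sequence(rbind(v2, v2) * 100, 13, p)
  expect_equal(reciprocity_weights(fs3), w2, tolerance = 1e-10)
  expect_error(reciprocity_weights(fs, tau = 0), "configuration error")
})

test_that("movement-augmented covariance adds a PSD term", {
  m <- fixture("mesh6"); p <- fixture("proto")
  M <- movement_jacobian(m, 1, p)
  S0 <- diag(208)
  expect_equal(movement_augmented_covariance(S0, M, 0), S0)
  sc <- calibrate_movement_scale(S0, M)
  S1 <- movement_augmented_covariance(S0, M, sc)
  expect_equal(S1, t(S1))
  ev <- eigen(S1 - S0, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  # calibrated scale equates the traces of the two terms
  expect_equal(sum(diag(S1 - S0)), sum(diag(S0)), tolerance = 1e-8)
  expect_error(movement_augmented_covariance(S0, M, -1), ">= 0")
})
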