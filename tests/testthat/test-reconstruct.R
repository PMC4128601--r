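# one-step and iterative reconstruction solvers

test_that("gn_one_step equals the dense ridge brute force and is linear", {
  J <- fixture("J6n")
  ne <- ncol(J)
  lam <- 0.1
  mod <- gn_one_step(J, diag(ne), W = 1, lambda = lam)
  set.seed(5)
  y1 <- rnorm(nrow(J), 0, 0.01)
  y2 <- rnorm(nrow(J), 0, 0.01)
  ridge <- solve(crossprod(J) + lam^2 * diag(ne), crossprod(J, y1))
  expect_equal(reconstruct(mod, y1), as.numeric(ridge), tolerance = 1e-8)
  # linearity to machine precision
  expect_equal(reconstruct(mod, 2 * y1 - 3 * y2),
               2 * reconstruct(mod, y1) - 3 * reconstruct(mod, y2),
               tolerance = 1e-12)
  # weighted case against the generalized ridge formula
  w <- runif(nrow(J), 0.5, 2)
  modw <- gn_one_step(J, fixture("R6"), W = w, lambda = lam)
  brute <- solve(crossprod(J, w * J) + lam^2 * fixture("R6"),
                 crossprod(J, w * y1))
  expect_equal(reconstruct(modw, y1), as.numeric(brute), tolerance = 1e-8)
})

test_that("regularization dominance collapses the image as lambda grows", {
  J <- fixture("J6n"); R <- fixture("R6")
  set.seed(6)
  y <- rnorm(nrow(J), 0, 0.01)
  x1 <- reconstruct(gn_one_step(J, R, 1, 1), y)
  x2 <- reconstruct(gn_one_step(J, R, 1, 1e6), y)
  expect_lt(sqrt(sum(x2^2)) / sqrt(sum(x1^2)), 1e-6)
  expect_error(gn_one_step(J, R, 1, lambda = -1), "lambda")
})

test_that("TSVD model matches the SVD oracle", {
  J <- fixture("J6n")
  sv <- svd(J)
  rk <- sum(sv$d > max(dim(J)) * .Machine$double.eps * sv$d[1])
  set.seed(7)
  y <- rnorm(nrow(J), 0, 0.01)
  # full rank equals the Moore-Penrose pseudo-inverse solution
  xp <- sv$v[, 1:rk] %*% ((t(sv$u[, 1:rk]) %*% y) / sv$d[1:rk])
  expect_equal(reconstruct(tsvd_model(J, rk), y), as.numeric(xp),
               tolerance = 1e-8)
  # k = 1 equals the rank-1 closed form
  x1 <- as.numeric(sv$v[, 1] * sum(sv$u[, 1] * y) / sv$d[1])
  expect_equal(reconstruct(tsvd_model(J, 1), y), x1, tolerance = 1e-10)
  # retained singular values are non-increasing
  m5 <- tsvd_model(J, 5)
  expect_true(all(diff(m5$provenance$singular_values) <= 0))
  expect_error(tsvd_model(J, 0), "configuration error")
  expect_error(tsvd_model(J, rk + 1), "configuration error")
})

test_that("robust solver is monotone, has the Huber quadratic limit, and resists outliers", {
  m <- fixture("mesh6"); J <- fixture("J6n"); R <- fixture("R6")
  xt <- point_target(m)
  y0 <- as.numeric(J %*% xt)
  set.seed(8)
  yg <- y0 + rnorm(length(y0), 0, 0.02 * stats::sd(y0))
  modR <- fixture("model_I2")
  lam <- modR$provenance$lambda
  xr <- robust_reconstruct(J, R, 1, lam, yg)
  obj <- attr(xr, "objective")
  expect_true(all(diff(obj) <= 1e-10 * abs(obj[1])))
  expect_true(attr(xr, "converged"))
  # smoothing far above the residual scale makes the loss quadratic: the
  # IRLS minimizer must match gn_one_step at the equivalent hyperparameter
  eps_big <- 30 * stats::sd(yg)
  x_h <- robust_reconstruct(J, R, 1, lam, yg, smoothing = eps_big)
  x_eq <- reconstruct(gn_one_step(J, R, 1, lam * sqrt(2 * eps_big)), yg)
  expect_lt(sqrt(sum((x_h - x_eq)^2)) / sqrt(sum(x_eq^2)), 0.05)
  # a gross single-channel outlier hurts the NF-matched quadratic model more
  modA <- fixture("model_A0")
  yo <- yg
  yo[37] <- yo[37] + 20 * stats::sd(y0)
  err_of <- function(mod) {
    x_clean <- suppressWarnings(reconstruct(mod, y0))
    x_dirty <- suppressWarnings(reconstruct(mod, yo))
    sqrt(sum((x_dirty - x_clean)^2)) / sqrt(sum(x_clean^2))
  }
  expect_lt(err_of(modR), err_of(modA))
})

test_that("TV functional and solver behave as a sharpness-preserving prior", {
  m <- fixture("mesh6"); J <- fixture("J6n")
  expect_equal(total_variation(rep(3, ncol(J)), m), 0)
  # piecewise-constant two-disc phantom
  xt <- as.numeric((sqrt((m$centroids[, 1] - 0.4)^2 + m$centroids[, 2]^2) < 0.25) |
                   (sqrt((m$centroids[, 1] + 0.4)^2 + m$centroids[, 2]^2) < 0.25))
  y <- as.numeric(J %*% xt)
  set.seed(10)
  y <- y + rnorm(length(y), 0, 0.01 * stats::sd(y))
  mtv <- build_reconstructor("I5", m, fixture("proto"))
  mhp <- build_reconstructor("I3", m, fixture("proto"))
  x_tv <- suppressWarnings(reconstruct(mtv, y))
  obj <- attr(suppressWarnings(
    tv_reconstruct(J, 1, mtv$provenance$lambda, m, y)), "objective")
  expect_true(all(diff(obj) <= 1e-8 * abs(obj[1])))
  x_hp <- reconstruct(mhp, y)
  # at matched NF, TV concentrates the image gradient on fewer edges
  ed <- lungeit:::mesh_interior_edges(m)
  conc <- function(x) {
    g <- sort(abs(x[ed$e1] - x[ed$e2]), decreasing = TRUE)
    sum(g[seq_len(ceiling(0.1 * length(g)))]) / sum(g)
  }
  expect_gt(conc(x_tv), conc(x_hp))
})

test_that("lung background model labels and reduces to homogeneous at contrast 1", {
  m <- fixture("mesh6"); p <- fixture("proto")
  s1 <- lung_background_model(m, contrast = 1)
  expect_equal(s1$values, rep(1, nrow(m$tris)))
  J1 <- conductivity_jacobian(m, s1, p, normalized = TRUE)
  expect_equal(unclass(J1), unclass(fixture("J6n")), tolerance = 1e-12,
               ignore_attr = TRUE)
  s02 <- lung_background_model(m, contrast = 0.2)
  expect_setequal(unique(s02$labels), c("background", "lung_left", "lung_right"))
  expect_length(s02$labels, nrow(m$tris))   # every element exactly one label
  expect_true(all(s02$values[s02$labels != "background"] == 0.2))
  expect_error(lung_background_model(m, contrast = 0), "configuration error")
  expect_error(lung_background_model(
    m, lung_regions = list(list(center = c(0.9, 0), rx = 0.5, ry = 0.5)),
    contrast = 0.2), "outside")
})

test_that("lung-background reconstruction separates the lungs more deeply", {
  # bilateral phantom reconstructed with homogeneous vs lung background:
  # the inter-lung valley of the midline ventilation profile is deeper
  # under the lung background (which boosts sensitivity inside the lungs)
  m8 <- fixture("mesh8"); m6 <- fixture("mesh6"); p <- fixture("proto")
  fs <- fixture("quiet_recording")
  ev <- detect_breaths(fs)
  mod_h <- fixture("model_A0")
  mod_l <- build_reconstructor("F3-2D", m6, p)
  valley <- function(model) {
    vent <- ventilation_signal(tidal_image(fs, ev, model))
    prof <- vent[16, ] / max(vent[attr(vent, "mask")])  # left-right profile
    min(prof[13:20], na.rm = TRUE)   # between the two lung peaks
  }
  expect_lt(valley(mod_l), valley(mod_h))
})
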