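#' One-step regularized Gauss-Newton reconstruction model
#'
#' Builds the linear reconstruction operator
#' \code{B = (J' W J + lambda^2 R)^{-1} J' W} that maps a difference data
#' vector to a per-element conductivity-change image. The operator is
#' precomputed once and reused across frames.
#'
#' @param J sensitivity matrix (channels x elements)
#' @param R regularization matrix (elements x elements); e.g.
#'   \code{\link{noser_prior}} or \code{\link{hpf_prior}}
#' @param W data weighting matrix (channels x channels, the inverse channel
#'   noise covariance), a per-channel weight vector, or a scalar; default
#'   identity
#' @param lambda regularization hyperparameter (> 0)
#' @param provenance optional named list stored with the model (preset name,
#'   achieved noise figure, ...)
#' @return an \code{eit_model} with the reconstruction matrix in \code{$B}
#' @export
gn_one_step <- function(J, R, W = 1, lambda, provenance = list()) {
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  W <- as_weight_matrix(W, nrow(J))
  JtW <- crossprod(J, W)
  A <- JtW %*% J + lambda^2 * R
  B <- tryCatch(solve(A, JtW),
                error = function(e)
                  stop("normal matrix numerically singular; try a larger lambda (",
                       conditionMessage(e), ")"))
  new_eit_model(B = B, kind = "linear",
                provenance = c(list(solver = "gn_one_step", lambda = lambda),
                               provenance))
}

as_weight_matrix <- function(W, nc) {
  if (is.matrix(W)) {
    if (!all(dim(W) == c(nc, nc))) stop("W dimensions do not match J")
    W
  } else if (length(W) == nc) {
    diag(as.numeric(W), nc)
  } else if (length(W) == 1) {
    diag(as.numeric(W), nc)
  } else stop("W must be a scalar, per-channel vector, or channels x channels matrix")
}

new_eit_model <- function(B = NULL, solve_fun = NULL, kind, provenance = list()) {
  structure(list(B = B, solve_fun = solve_fun, kind = kind,
                 provenance = provenance), class = "eit_model")
}

#' @export
print.eit_model <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("eit_model (%s): %s", x$kind,
              if (!is.null(pv$solver)) pv$solver else "custom"))
  if (!is.null(pv$preset)) cat(sprintf(", preset %s", pv$preset))
  if (!is.null(pv$lambda)) cat(sprintf(", lambda = %.4g", pv$lambda))
  if (!is.null(pv$k)) cat(sprintf(", k = %d", pv$k))
  if (!is.null(pv$noise_figure)) cat(sprintf(", NF = %.4g", pv$noise_figure))
  cat("\n")
  if (!is.null(x$B))
    cat(sprintf("  reconstruction matrix: %d elements x %d channels\n",
                nrow(x$B), ncol(x$B)))
  invisible(x)
}

#' Apply a reconstruction model to difference data
#'
#' @param model an \code{eit_model}
#' @param y difference data vector (or matrix with one column per frame for
#'   linear models)
#' @return per-element conductivity change image(s)
#' @export
reconstruct <- function(model, y) {
  if (model$kind == "linear") {
    x <- model$B %*% as.matrix(y)
    if (ncol(x) == 1) as.numeric(x) else x
  } else {
    if (is.matrix(y) && ncol(y) > 1)
      return(apply(y, 2, model$solve_fun))
    model$solve_fun(as.numeric(y))
  }
}

#' @export
predict.eit_model <- function(object, y, ...) reconstruct(object, y)

#' Truncated SVD reconstruction model
#'
#' Pseudo-inverse of J keeping only the k largest singular values; the
#' truncation rank plays the role of the regularization hyperparameter.
#'
#' @param J sensitivity matrix
#' @param k truncation rank, 1 <= k <= rank(J)
#' @param sv optional precomputed \code{svd(J)} (reused during rank search)
#' @inheritParams gn_one_step
#' @export
tsvd_model <- function(J, k, provenance = list(), sv = NULL) {
  if (is.null(sv)) sv <- svd(J)
  tol <- max(dim(J)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  if (!is.numeric(k) || k < 1 || k > r)
    stop("configuration error: truncation rank k must be in [1, rank(J) = ", r, "]")
  k <- as.integer(k)
  B <- sv$v[, seq_len(k), drop = FALSE] %*%
    (t(sv$u[, seq_len(k), drop = FALSE]) / sv$d[seq_len(k)])
  new_eit_model(B = B, kind = "linear",
                provenance = c(list(solver = "tsvd", k = k,
                                    singular_values = sv$d[seq_len(k)]),
                               provenance))
}

#' Robust (L1 data norm) iterative reconstruction
#'
#' Minimizes \code{sum_i w_i sqrt(r_i^2 + eps^2) + lambda^2 x' R x} (a
#' smoothed L1 data misfit with quadratic prior) by iteratively reweighted
#' least squares. Gross outliers on single channels are downweighted instead
#' of dominating the solution as they do under the quadratic norm.
#'
#' @inheritParams gn_one_step
#' @param y difference data vector
#' @param tol relative objective-change convergence tolerance
#' @param max_iter maximum IRLS iterations
#' @param x0 optional starting image (defaults to the quadratic solution;
#'   pass it precomputed when solving many data vectors with one operator)
#' @param smoothing optional absolute smoothing scale eps; the default
#'   (NULL) uses 1e-4 times the median absolute residual, which keeps the
#'   loss essentially exact L1. A smoothing well above the residual scale
#'   turns the loss Huber-quadratic, recovering \code{gn_one_step} at the
#'   equivalent hyperparameter lambda*sqrt(2*eps).
#' @return per-element image with attributes \code{iterations},
#'   \code{objective} (per-iteration values) and \code{converged}
#' @export
robust_reconstruct <- function(J, R, W = 1, lambda, y, tol = 1e-6, max_iter = 50,
                               x0 = NULL, smoothing = NULL) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  W <- as_weight_matrix(W, nrow(J))
  w <- diag(W)
  y <- as.numeric(y)
  # initialize from the quadratic solution; smoothing eps fixed from its
  # residual scale (safeguards IRLS monotonicity)
  x <- if (is.null(x0)) as.numeric(gn_one_step(J, R, W, lambda)$B %*% y)
       else as.numeric(x0)
  r <- as.numeric(J %*% x - y)
  # floor by the data scale so near-perfect fits cannot drive the IRLS
  # weights (and the system's condition number) unbounded
  eps <- if (is.null(smoothing))
    1e-4 * max(stats::median(abs(r)), 1e-6 * mean(abs(y)),
               .Machine$double.eps)
  else as.numeric(smoothing)
  obj <- function(x, r) sum(w * sqrt(r^2 + eps^2)) + lambda^2 * sum(x * (R %*% x))
  objs <- obj(x, r)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- w / sqrt(r^2 + eps^2)           # IRLS weights (majorizer)
    A <- crossprod(J, d * J) + 2 * lambda^2 * R
    x_new <- as.numeric(solve(A, crossprod(J, d * y)))
    r_new <- as.numeric(J %*% x_new - y)
    o_new <- obj(x_new, r_new)
    objs <- c(objs, o_new)
    rel <- abs(objs[it] - o_new) / max(abs(objs[it]), .Machine$double.eps)
    x <- x_new; r <- r_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("robust_reconstruct did not converge in ", max_iter,
            " iterations; returning best iterate")
  structure(x, iterations = length(objs) - 1, objective = objs,
            converged = converged)
}

#' Total variation iterative reconstruction
#'
#' Minimizes \code{|W^(1/2)(Jx - y)|^2 + lambda * TV(x)} with
#' \code{TV(x) = sum_edges len_ij * sqrt((x_i - x_j)^2 + beta^2)} (smoothed,
#' edge-length weighted total variation over interior mesh edges), by lagged
#' diffusivity iteratively reweighted least squares. Favours piecewise
#' constant images with sharp boundaries.
#'
#' @inheritParams robust_reconstruct
#' @param mesh the mesh (for the interior edge graph)
#' @param edges optional precomputed \code{mesh_interior_edges(mesh)}
#' @export
tv_reconstruct <- function(J, W = 1, lambda, mesh, y, tol = 1e-6, max_iter = 50,
                           x0 = NULL, edges = NULL) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  W <- as_weight_matrix(W, nrow(J))
  y <- as.numeric(y)
  ne <- ncol(J)
  ed <- if (is.null(edges)) mesh_interior_edges(mesh) else edges
  D <- Matrix::sparseMatrix(i = rep(seq_len(nrow(ed)), 2),
                            j = c(ed$e1, ed$e2),
                            x = rep(c(1, -1), each = nrow(ed)),
                            dims = c(nrow(ed), ne))
  JtW <- crossprod(J, W)
  JtWJ <- JtW %*% J
  Jty <- as.numeric(JtW %*% y)
  # initialize from a mildly Tikhonov-regularized quadratic solution
  x <- if (is.null(x0))
    as.numeric(solve(JtWJ + lambda * diag(mean(diag(JtWJ)) * 1e-2, ne), Jty))
  else as.numeric(x0)
  beta <- 1e-4 * max(diff(range(x)), .Machine$double.eps)
  tv_of <- function(dx) sum(ed$len * sqrt(dx^2 + beta^2))
  obj <- function(x) {
    r <- as.numeric(J %*% x - y)
    sum(r * (W %*% r)) + lambda * tv_of(as.numeric(D %*% x))
  }
  objs <- obj(x)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dx <- as.numeric(D %*% x)
    wtv <- ed$len / sqrt(dx^2 + beta^2)
    Ltv <- Matrix::crossprod(D, wtv * D)    # weighted graph Laplacian
    A <- JtWJ + (lambda / 2) * as.matrix(Ltv)
    x_new <- as.numeric(solve(A, Jty))
    o_new <- obj(x_new)
    objs <- c(objs, o_new)
    rel <- abs(objs[it] - o_new) / max(abs(objs[it]), .Machine$double.eps)
    x <- x_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("tv_reconstruct did not converge in ", max_iter,
            " iterations; returning best iterate")
  structure(x, iterations = length(objs) - 1, objective = objs,
            converged = converged)
}

#' Total variation of a per-element image
#'
#' Edge-length weighted sum of absolute differences across interior mesh
#' edges (the unsmoothed TV functional).
#' @param x per-element image
#' @param mesh the mesh
#' @export
total_variation <- function(x, mesh) {
  ed <- mesh_interior_edges(mesh)
  sum(ed$len * abs(x[ed$e1] - x[ed$e2]))
}

#' Bilateral-lung background conductivity model
#'
#' Builds the non-homogeneous background field with lung regions at
#' \code{contrast} times the background conductivity (lungs are poorly
#' conducting); the sensitivity matrix is then recomputed at this background.
#'
#' @param mesh an \code{eit_mesh}
#' @param lung_regions list of ellipse specs, each a list with \code{center}
#'   (x, y), \code{rx}, \code{ry}; defaults to a bilateral pair typical for a
#'   supine thorax section
#' @param contrast lung-to-background conductivity ratio in (0, 1]; default
#'   0.2
#' @param background background conductivity (default 1)
#' @return an \code{eit_sigma} with labels "background", "lung_left",
#'   "lung_right" (or "lung_<i>")
#' @export
lung_background_model <- function(mesh, lung_regions = default_lung_regions(),
                                  contrast = 0.2, background = 1) {
  if (!is.numeric(contrast) || contrast <= 0 || contrast > 1)
    stop("configuration error: contrast must be in (0, 1]")
  m <- nrow(mesh$tris)
  vals <- rep(background, m)
  labs <- rep("background", m)
  for (i in seq_along(lung_regions)) {
    rg <- lung_regions[[i]]
    if (rg$rx <= 0 || rg$ry <= 0) stop("degenerate lung region geometry")
    if (sqrt(sum(rg$center^2)) + max(rg$rx, rg$ry) > mesh$radius * 1.001)
      stop("lung region extends outside the disc")
    inside <- ((mesh$centroids[, 1] - rg$center[1]) / rg$rx)^2 +
              ((mesh$centroids[, 2] - rg$center[2]) / rg$ry)^2 <= 1
    if (!any(inside)) stop("degenerate lung region geometry: no elements inside")
    vals[inside] <- background * contrast
    labs[inside] <- if (!is.null(rg$label)) rg$label else paste0("lung_", i)
  }
  conductivity_field(vals, mesh, labels = labs)
}

#' Default bilateral lung ellipses (supine thorax section, +y ventral)
#' @export
default_lung_regions <- function() {
  list(list(center = c(-0.42, 0), rx = 0.26, ry = 0.48, label = "lung_left"),
       list(center = c(0.42, 0), rx = 0.26, ry = 0.48, label = "lung_right"))
}
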