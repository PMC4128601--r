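#' Conductivity sensitivity matrix (adjoint method)
#'
#' Computes the Jacobian of channel voltages with respect to per-element
#' conductivity at a background field \code{sigma0}, using the adjoint
#' (measurement-field) identity: for drive field u_d and unit-current
#' measurement field u_m, dv/dsigma_k = -area_k * grad(u_d) . grad(u_m) on
#' element k. Under the adjacent protocol every measurement pair is also a
#' drive pair, so the same field solves serve both roles.
#'
#' With \code{normalized = TRUE} each row i is divided by the reference
#' voltage v_i(sigma0), matching the normalized difference data
#' y_i = (v_i - v_ref_i)/v_ref_i.
#'
#' @inheritParams solve_forward
#' @param sigma0 background conductivity (field or scalar)
#' @param normalized scale rows by reference voltages at \code{sigma0}
#' @return matrix (channels x elements) with attributes \code{normalized} and
#'   \code{v_ref} (the reference voltages at \code{sigma0})
#' @export
conductivity_jacobian <- function(mesh, sigma0, protocol, normalized = FALSE,
                                  contact_impedance = 0.01) {
  ff <- forward_fields(mesh, sigma0, protocol, contact_impedance)
  v_ref <- channel_voltages(ff$U, protocol)
  g <- element_gradients(mesh)
  tr <- mesh$tris
  # per-element gradient components of each stimulation field
  Gx <- g$b[, 1] * ff$u[tr[, 1], , drop = FALSE] +
        g$b[, 2] * ff$u[tr[, 2], , drop = FALSE] +
        g$b[, 3] * ff$u[tr[, 3], , drop = FALSE]
  Gy <- g$c[, 1] * ff$u[tr[, 1], , drop = FALSE] +
        g$c[, 2] * ff$u[tr[, 2], , drop = FALSE] +
        g$c[, 3] * ff$u[tr[, 3], , drop = FALSE]
  cur <- attr(protocol, "current")
  nc <- nrow(protocol)
  J <- matrix(0, nrow = nc, ncol = nrow(tr))
  for (i in seq_len(nc)) {
    d <- protocol$stim[i]
    m <- protocol$meas_pos[i]  # measurement field = stimulation field m / current
    J[i, ] <- -mesh$areas * (Gx[, d] * Gx[, m] + Gy[, d] * Gy[, m]) / cur
  }
  if (normalized) {
    if (any(v_ref == 0))
      stop("zero reference voltage on channel(s) ",
           paste(which(v_ref == 0), collapse = ", "),
           "; cannot build normalized-data Jacobian")
    J <- J / v_ref
  }
  structure(J, normalized = normalized, v_ref = as.numeric(v_ref))
}

#' Electrode-movement sensitivity matrix
#'
#' Central finite differences of channel voltages with respect to each
#' electrode centre coordinate. Electrodes are constrained to the circular
#' boundary, so a Cartesian displacement acts through its tangential
#' projection: column x_l is (dv/ds_l) * t_x(l), column y_l is
#' (dv/ds_l) * t_y(l), with s arc length and t the boundary tangent at the
#' electrode centre. Each perturbed geometry is remeshed with the same
#' topology (only node positions move).
#'
#' @inheritParams conductivity_jacobian
#' @param step finite-difference arc-length step in radius units
#'   (default 1e-4)
#' @return matrix (channels x 2*n_electrodes); columns ordered
#'   (x_1..x_n, y_1..y_n)
#' @export
movement_jacobian <- function(mesh, sigma0, protocol, step = 1e-4,
                              contact_impedance = 0.01) {
  n <- mesh$n_electrodes
  centers <- mesh$params$electrode_centers
  dtheta <- step / mesh$radius
  gap_min <- min((diff(c(sort(centers), sort(centers)[1] + 2 * pi))) -
                 mesh$params$electrode_width)
  if (2 * dtheta >= gap_min)
    stop("movement step would overlap electrodes; reduce step")
  nc <- nrow(protocol)
  M <- matrix(0, nrow = nc, ncol = 2 * n)
  for (l in seq_len(n)) {
    for (sgn in c(-1, 1)) {
      ctr <- centers
      ctr[l] <- ctr[l] + sgn * dtheta
      mp <- build_mesh(radius = mesh$radius, n_electrodes = n,
                       electrode_width = mesh$params$electrode_width,
                       density = mesh$params$density, electrode_centers = ctr)
      vp <- as.numeric(solve_forward(mp, sigma0, protocol, contact_impedance))
      M[, l] <- M[, l] + sgn * vp
    }
    dvds <- M[, l] / (2 * step)
    tx <- -sin(centers[l]); ty <- cos(centers[l])
    M[, l] <- dvds * tx
    M[, n + l] <- dvds * ty
  }
  M
}
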