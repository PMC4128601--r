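#' Per-element conductivity field
#'
#' @param values strictly positive per-element conductivities (recycled if
#'   length 1)
#' @param mesh the mesh the field lives on
#' @param labels optional per-element region labels (e.g. "background",
#'   "lung_left", "lung_right")
#' @return object of class \code{eit_sigma}
#' @export
conductivity_field <- function(values, mesh, labels = NULL) {
  m <- nrow(mesh$tris)
  if (length(values) == 1) values <- rep(values, m)
  if (length(values) != m)
    stop("conductivity length (", length(values), ") does not match element count (", m, ")")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("conductivity must be finite and strictly positive")
  if (is.null(labels)) labels <- rep("background", m)
  if (length(labels) != m) stop("labels length must match element count")
  structure(list(values = as.numeric(values), labels = labels), class = "eit_sigma")
}

as_sigma_values <- function(sigma, mesh) {
  if (inherits(sigma, "eit_sigma")) return(sigma$values)
  m <- nrow(mesh$tris)
  if (length(sigma) == 1) sigma <- rep(sigma, m)
  if (length(sigma) != m) stop("conductivity length does not match element count")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("conductivity must be finite and strictly positive")
  as.numeric(sigma)
}

# per-element linear shape-function gradient coefficients:
# grad(u)|_e = (b %*% u_e, c %*% u_e), constant on each triangle
element_gradients <- function(mesh) {
  tr <- mesh$tris
  x <- matrix(mesh$nodes[tr, 1], ncol = 3)
  y <- matrix(mesh$nodes[tr, 2], ncol = 3)
  a2 <- 2 * mesh$areas
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / a2
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / a2
  list(b = b, c = cc)
}

# assemble the complete electrode model system
# unknowns: node potentials (N), electrode potentials (L), one Lagrange
# multiplier enforcing sum(U) = 0
cem_system <- function(mesh, sigma_values, contact_impedance) {
  N <- nrow(mesh$nodes)
  L <- mesh$n_electrodes
  g <- element_gradients(mesh)
  tr <- mesh$tris
  m <- nrow(tr)
  # stiffness triplets: sigma * area * (b_i b_j + c_i c_j)
  ii <- jj <- integer(9 * m); xx <- numeric(9 * m)
  k <- 0L
  w <- sigma_values * mesh$areas
  for (a in 1:3) for (b in 1:3) {
    idx <- k * m + seq_len(m)
    ii[idx] <- tr[, a]
    jj[idx] <- tr[, b]
    xx[idx] <- w * (g$b[, a] * g$b[, b] + g$c[, a] * g$c[, b])
    k <- k + 1L
  }
  zi <- rep(contact_impedance, length.out = L)
  for (l in seq_len(L)) {
    ed <- mesh$electrodes[[l]]$edges
    n1 <- ed[, 1]; n2 <- ed[, 2]
    len <- sqrt(rowSums((mesh$nodes[n1, , drop = FALSE] -
                         mesh$nodes[n2, , drop = FALSE])^2))
    z <- zi[l]
    # boundary mass terms (1/z) * int phi_i phi_j ds
    ii <- c(ii, n1, n2, n1, n2)
    jj <- c(jj, n1, n2, n2, n1)
    xx <- c(xx, len / (3 * z), len / (3 * z), len / (6 * z), len / (6 * z))
    # node-electrode coupling -(1/z) * int phi_i ds
    ecol <- N + l
    ii <- c(ii, n1, n2, rep(ecol, 2 * length(len)))
    jj <- c(jj, rep(ecol, 2 * length(len)), n1, n2)
    xx <- c(xx, rep(-len / (2 * z), 2), rep(-len / (2 * z), 2))
    # electrode self term |e_l| / z
    ii <- c(ii, ecol); jj <- c(jj, ecol); xx <- c(xx, sum(len) / z)
  }
  # grounding: sum of electrode potentials = 0 via Lagrange multiplier
  lag <- N + L + 1L
  ii <- c(ii, rep(lag, L), N + seq_len(L))
  jj <- c(jj, N + seq_len(L), rep(lag, L))
  xx <- c(xx, rep(1, 2 * L))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(lag, lag))
}

# solve the CEM forward problem for all stimulations; returns node and
# electrode potentials (columns = stimulations)
forward_fields <- function(mesh, sigma, protocol, contact_impedance = 0.01) {
  sv <- as_sigma_values(sigma, mesh)
  N <- nrow(mesh$nodes)
  L <- mesh$n_electrodes
  if (attr(protocol, "n_electrodes") != L)
    stop("protocol electrode count does not match mesh")
  A <- cem_system(mesh, sv, contact_impedance)
  stims <- unique(protocol[, c("stim", "drive_pos", "drive_neg")])
  ns <- nrow(stims)
  B <- matrix(0, nrow = N + L + 1, ncol = ns)
  cur <- attr(protocol, "current")
  for (s in seq_len(ns)) {
    B[N + stims$drive_pos[s], s] <- cur
    B[N + stims$drive_neg[s], s] <- -cur
  }
  sol <- tryCatch(as.matrix(Matrix::solve(A, B)),
                  error = function(e) stop("numerical error solving the forward system ",
                                           "(mesh disconnected or degenerate): ",
                                           conditionMessage(e)))
  list(u = sol[seq_len(N), , drop = FALSE],
       U = sol[N + seq_len(L), , drop = FALSE],
       stim_index = stims$stim)
}

#' Solve the EIT forward problem (complete electrode model)
#'
#' Computes the voltage for every protocol channel on the given mesh and
#' conductivity field, using linear triangular finite elements and the
#' complete electrode model with finite-width boundary electrodes and fixed
#' contact impedance.
#'
#' @param mesh an \code{eit_mesh}
#' @param sigma an \code{eit_sigma} or numeric per-element conductivity
#' @param protocol an \code{eit_protocol}
#' @param contact_impedance electrode contact impedance (model units,
#'   default 0.01)
#' @param timestamp optional frame timestamp in seconds
#' @return numeric vector of channel voltages (class \code{eit_frame}, with
#'   the timestamp as attribute)
#' @export
solve_forward <- function(mesh, sigma, protocol, contact_impedance = 0.01,
                          timestamp = 0) {
  ff <- forward_fields(mesh, sigma, protocol, contact_impedance)
  v <- channel_voltages(ff$U, protocol)
  structure(v, timestamp = timestamp, class = "eit_frame")
}

channel_voltages <- function(U, protocol) {
  scol <- match(protocol$stim, seq_len(ncol(U)))
  U[cbind(protocol$meas_pos, scol)] - U[cbind(protocol$meas_neg, scol)]
}

#' @export
print.eit_frame <- function(x, ...) {
  cat(sprintf("eit_frame: %d channels, t = %g s, range [%.3g, %.3g]\n",
              length(x), attr(x, "timestamp"), min(x), max(x)))
  invisible(x)
}
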