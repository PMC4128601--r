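#' Build a circular 2D finite element mesh with boundary electrodes
#'
#' Constructs a deterministic triangulation of a disc with \code{n_electrodes}
#' equally spaced finite-width electrode arcs on the boundary, the geometry
#' used by the complete electrode model forward solver. The mesh is built from
#' concentric rings of nodes whose boundary ring is aligned with the electrode
#' arc endpoints, so every electrode covers a whole number of boundary edges.
#'
#' Coordinate convention: the y-axis is the dorsoventral axis with +y ventral.
#' Electrode 1 is centred on +y and numbering proceeds clockwise (as seen in
#' the usual display of thoracic EIT images).
#'
#' @param radius disc radius (model units; reconstruction is scale-free).
#' @param n_electrodes number of boundary electrodes (>= 4).
#' @param electrode_width angular width of each electrode arc in radians.
#' @param density mesh refinement level: the number of concentric node rings.
#'   The default (16) gives roughly 1500 elements; 6 gives a coarse ~200
#'   element mesh suitable for brute-force oracles.
#' @param electrode_centers optional vector of electrode centre angles
#'   (radians, mathematical convention); defaults to the equally spaced
#'   clockwise-from-ventral layout. Used internally to displace electrodes
#'   for the movement Jacobian.
#' @return an object of class \code{eit_mesh}: list with \code{nodes} (n x 2),
#'   \code{tris} (m x 3, counterclockwise), \code{areas}, \code{centroids},
#'   \code{electrodes} (per electrode: centre angle, width, ordered boundary
#'   node indices and edge list), \code{radius}, \code{n_electrodes}.
#' @export
build_mesh <- function(radius = 1, n_electrodes = 16, electrode_width = 0.15,
                       density = 16, electrode_centers = NULL) {
  if (!is.numeric(n_electrodes) || length(n_electrodes) != 1 || n_electrodes < 4)
    stop("configuration error: n_electrodes must be >= 4")
  if (radius <= 0) stop("configuration error: radius must be > 0")
  if (electrode_width <= 0 || electrode_width * n_electrodes >= 2 * pi)
    stop("configuration error: electrodes overlap (electrode_width * n_electrodes must be < 2*pi)")
  if (density < 2) stop("configuration error: density must be >= 2")
  n_el <- as.integer(n_electrodes)

  if (is.null(electrode_centers)) {
    # electrode 1 at +y (pi/2), clockwise numbering
    electrode_centers <- (pi / 2 - (seq_len(n_el) - 1) * 2 * pi / n_el) %% (2 * pi)
  } else {
    if (length(electrode_centers) != n_el)
      stop("configuration error: electrode_centers length must equal n_electrodes")
    electrode_centers <- electrode_centers %% (2 * pi)
  }
  # check non-overlap for arbitrary centres
  ord <- order(electrode_centers)
  cs <- electrode_centers[ord]
  gaps <- diff(c(cs, cs[1] + 2 * pi))
  if (any(gaps <= electrode_width))
    stop("configuration error: electrodes overlap")

  R <- as.integer(density)
  sub <- max(1L, as.integer(round(density / 5)))
  e_sub <- sub
  g_sub <- sub

  # boundary angles: walk electrodes in increasing-angle order, subdividing
  # each electrode arc into e_sub edges and each gap into g_sub edges
  bnd_ang <- numeric(0)
  elec_of <- integer(0)  # electrode id of each boundary node (0 = gap)
  for (k in seq_len(n_el)) {
    a <- cs[k] - electrode_width / 2
    b <- cs[k] + electrode_width / 2
    ea <- seq(a, b, length.out = e_sub + 1)
    bnd_ang <- c(bnd_ang, ea)
    elec_of <- c(elec_of, rep(ord[k], e_sub + 1))
    nb <- cs[if (k == n_el) 1 else k + 1] + (if (k == n_el) 2 * pi else 0) - electrode_width / 2
    if (g_sub > 1) {
      ga <- seq(b, nb, length.out = g_sub + 1)[2:g_sub]
      bnd_ang <- c(bnd_ang, ga)
      elec_of <- c(elec_of, rep(0L, g_sub - 1))
    }
  }
  bnd_ang <- bnd_ang %% (2 * pi)
  o <- order(bnd_ang)
  bnd_ang <- bnd_ang[o]
  elec_of <- elec_of[o]
  n_bnd <- length(bnd_ang)

  # rings: radius fractions i/R; node counts grow with radius
  ring_n <- integer(R)
  for (i in seq_len(R)) ring_n[i] <- max(8L, as.integer(round(n_bnd * i / R)))
  ring_n[R] <- n_bnd

  nodes <- matrix(0, nrow = 1, ncol = 2)  # centre node (index 1)
  ring_idx <- vector("list", R)
  ring_ang <- vector("list", R)
  for (i in seq_len(R)) {
    ri <- radius * i / R
    if (i < R) {
      ang <- 2 * pi * (seq_len(ring_n[i]) - 1) / ring_n[i]
    } else {
      ang <- bnd_ang
    }
    idx <- nrow(nodes) + seq_along(ang)
    nodes <- rbind(nodes, cbind(ri * cos(ang), ri * sin(ang)))
    ring_idx[[i]] <- idx
    ring_ang[[i]] <- ang
  }

  tris <- matrix(0L, nrow = 0, ncol = 3)
  # centre fan
  i1 <- ring_idx[[1]]
  k1 <- length(i1)
  tris <- rbind(tris, cbind(1L, i1, i1[c(2:k1, 1)]))
  # annuli
  for (i in seq_len(R - 1)) {
    tris <- rbind(tris, annulus_tris(ring_idx[[i]], ring_ang[[i]],
                                     ring_idx[[i + 1]], ring_ang[[i + 1]]))
  }

  # enforce counterclockwise orientation
  a2 <- signed_areas(nodes, tris)
  flip <- a2 < 0
  if (any(flip)) tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
  areas <- abs(a2)
  if (any(areas <= 0)) stop("mesh generation produced a degenerate element")

  centroids <- (nodes[tris[, 1], , drop = FALSE] +
                nodes[tris[, 2], , drop = FALSE] +
                nodes[tris[, 3], , drop = FALSE]) / 3

  # electrode boundary nodes and edges
  bidx <- ring_idx[[R]]
  electrodes <- vector("list", n_el)
  for (l in seq_len(n_el)) {
    sel <- which(elec_of == l)
    # order along the arc (handle wrap across 0)
    aa <- bnd_ang[sel]
    ctr <- electrode_centers[l]
    rel <- ((aa - ctr + pi) %% (2 * pi)) - pi
    sel <- sel[order(rel)]
    nd <- bidx[sel]
    edges <- cbind(nd[-length(nd)], nd[-1])
    electrodes[[l]] <- list(center_angle = ctr, width = electrode_width,
                            nodes = nd, edges = edges)
  }

  structure(list(nodes = nodes, tris = tris, areas = areas,
                 centroids = centroids, electrodes = electrodes,
                 radius = radius, n_electrodes = n_el,
                 boundary_nodes = bidx,
                 params = list(electrode_width = electrode_width,
                               density = as.integer(density),
                               electrode_centers = electrode_centers)),
            class = "eit_mesh")
}

# triangulate the annulus between two concentric node rings by an angular
# merge sweep; returns (ni + no) triangles
annulus_tris <- function(I, ai, O, ao) {
  ni <- length(I); no <- length(O)
  # rotate outer ring so its first node is angularly closest to inner[1]
  d0 <- abs(((ao - ai[1] + pi) %% (2 * pi)) - pi)
  j0 <- which.min(d0)
  rot <- function(x, k) if (k == 1) x else c(x[k:length(x)], x[seq_len(k - 1)])
  Oc <- rot(O, j0); aoc <- rot(ao, j0)
  # unwrap both angle sequences to be non-decreasing, then extend one turn
  unwrap <- function(a) {
    for (k in seq_along(a)[-1]) if (a[k] < a[k - 1]) a[k] <- a[k] + 2 * pi
    a
  }
  aiu <- unwrap(ai); aou <- unwrap(aoc)
  # align start: shift outer by -2pi if it starts far ahead of inner
  if (aou[1] - aiu[1] > pi) aou <- aou - 2 * pi
  if (aiu[1] - aou[1] > pi) aou <- aou + 2 * pi
  I2 <- c(I, I); aiu2 <- c(aiu, aiu + 2 * pi)
  O2 <- c(Oc, Oc); aou2 <- c(aou, aou + 2 * pi)
  tris <- matrix(0L, nrow = ni + no, ncol = 3)
  i <- 1L; j <- 1L; ci <- 0L; co <- 0L
  for (s in seq_len(ni + no)) {
    adv_out <- co < no && (ci >= ni || aou2[j + 1] <= aiu2[i + 1])
    if (adv_out) {
      tris[s, ] <- c(I2[i], O2[j], O2[j + 1])
      j <- j + 1L; co <- co + 1L
    } else {
      tris[s, ] <- c(I2[i], O2[j], I2[i + 1])
      i <- i + 1L; ci <- ci + 1L
    }
  }
  tris
}

signed_areas <- function(nodes, tris) {
  x1 <- nodes[tris[, 1], 1]; y1 <- nodes[tris[, 1], 2]
  x2 <- nodes[tris[, 2], 1]; y2 <- nodes[tris[, 2], 2]
  x3 <- nodes[tris[, 3], 1]; y3 <- nodes[tris[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("eit_mesh: %d nodes, %d elements, %d electrodes (width %.3f rad), radius %g\n",
              nrow(x$nodes), nrow(x$tris), x$n_electrodes,
              x$params$electrode_width, x$radius))
  invisible(x)
}

#' Interior-edge list of a mesh
#'
#' Edges shared by two triangles, with edge lengths; used by the total
#' variation prior.
#' @param mesh an \code{eit_mesh}
#' @return data.frame with columns \code{e1}, \code{e2} (element indices) and
#'   \code{len} (edge length).
#' @keywords internal
mesh_interior_edges <- function(mesh) {
  tris <- mesh$tris
  m <- nrow(tris)
  ed <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  elem <- rep(seq_len(m), 3)
  key <- paste(ed[, 1], ed[, 2])
  sp <- split(elem, key)
  shared <- sp[lengths(sp) == 2]
  if (length(shared) == 0)
    return(data.frame(e1 = integer(0), e2 = integer(0), len = numeric(0)))
  e1 <- vapply(shared, `[`, integer(1), 1)
  e2 <- vapply(shared, `[`, integer(1), 2)
  nd <- do.call(rbind, strsplit(names(shared), " "))
  n1 <- as.integer(nd[, 1]); n2 <- as.integer(nd[, 2])
  len <- sqrt(rowSums((mesh$nodes[n1, , drop = FALSE] -
                       mesh$nodes[n2, , drop = FALSE])^2))
  data.frame(e1 = e1, e2 = e2, len = len)
}

#' Write / read a mesh as a self-describing JSON container
#'
#' Round-trips nodes, triangles and electrode segments at full double
#' precision.
#' @param mesh an \code{eit_mesh}
#' @param path file path
#' @return \code{read_mesh} returns the \code{eit_mesh}.
#' @export
write_mesh <- function(mesh, path) {
  obj <- list(
    format = "lungeit-mesh-1",
    radius = mesh$radius,
    n_electrodes = mesh$n_electrodes,
    electrode_width = mesh$params$electrode_width,
    density = mesh$params$density,
    electrode_centers = mesh$params$electrode_centers,
    nodes = mesh$nodes,
    tris = mesh$tris
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lungeit-mesh-1"))
    stop("not a lungeit mesh file: ", path)
  # rebuild deterministically from stored generation parameters and verify
  mesh <- build_mesh(radius = obj$radius, n_electrodes = obj$n_electrodes,
                     electrode_width = obj$electrode_width,
                     density = obj$density,
                     electrode_centers = obj$electrode_centers)
  if (!isTRUE(all.equal(unname(mesh$nodes), unname(obj$nodes), tolerance = 1e-12)) ||
      !identical(unname(mesh$tris), unname(matrix(as.integer(obj$tris), ncol = 3))))
    stop("mesh file inconsistent with its stored generation parameters: ", path)
  mesh
}
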