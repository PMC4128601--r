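# rasterization, breath detection, tidal images, lung ROI, V_T and CoV

.raster_cache <- new.env(parent = emptyenv())

#' Element-to-pixel interpolation matrix
#'
#' Area-weighted interpolation of per-element values onto a square pixel
#' grid covering [-radius, radius]^2, computed by dense sub-sampling (8x8
#' points per pixel located in the triangulation). Row i of the returned
#' matrix averages the elements overlapping pixel i; pixels with no
#' sub-sample inside the mesh are masked. Cached per (mesh, grid size).
#'
#' @param mesh an \code{eit_mesh}
#' @param grid_size pixels per side (default 32)
#' @return list with \code{P} (sparse grid_size^2 x elements, row-stochastic
#'   on unmasked rows), \code{mask} (grid_size x grid_size logical, TRUE
#'   inside the disc) and \code{pixel_area} (covered area per pixel)
#' @keywords internal
raster_matrix <- function(mesh, grid_size = 32) {
  key <- paste(model_cache_key_raw(mesh$params), mesh$radius, grid_size)
  if (!is.null(.raster_cache[[key]])) return(.raster_cache[[key]])
  gs <- as.integer(grid_size)
  sub <- 8L
  n <- gs * sub
  r <- mesh$radius
  xs <- -r + (seq_len(n) - 0.5) * 2 * r / n          # left -> right
  ys <- r - (seq_len(n) - 0.5) * 2 * r / n           # top (ventral) -> bottom
  owner <- matrix(0L, nrow = n, ncol = n)            # [row (y), col (x)]
  tr <- mesh$tris
  for (e in seq_len(nrow(tr))) {
    px <- mesh$nodes[tr[e, ], 1]; py <- mesh$nodes[tr[e, ], 2]
    jx <- which(xs >= min(px) & xs <= max(px))
    iy <- which(ys >= min(py) & ys <= max(py))
    if (!length(jx) || !length(iy)) next
    gx <- rep(xs[jx], each = length(iy))
    gy <- rep(ys[iy], times = length(jx))
    d <- (py[2] - py[3]) * (px[1] - px[3]) + (px[3] - px[2]) * (py[1] - py[3])
    l1 <- ((py[2] - py[3]) * (gx - px[3]) + (px[3] - px[2]) * (gy - py[3])) / d
    l2 <- ((py[3] - py[1]) * (gx - px[3]) + (px[1] - px[3]) * (gy - py[3])) / d
    l3 <- 1 - l1 - l2
    tol <- -1e-12
    inside <- l1 >= tol & l2 >= tol & l3 >= tol
    if (!any(inside)) next
    ii <- rep(iy, times = length(jx))[inside]
    jj <- rep(jx, each = length(iy))[inside]
    free <- owner[cbind(ii, jj)] == 0L   # first element claims a point
    owner[cbind(ii[free], jj[free])] <- e
  }
  pt <- which(owner > 0L)
  ii <- (pt - 1L) %% n + 1L         # subsample row
  jj <- (pt - 1L) %/% n + 1L        # subsample col
  pix_row <- (ii - 1L) %/% sub + 1L
  pix_col <- (jj - 1L) %/% sub + 1L
  pix <- (pix_row - 1L) * gs + pix_col
  P <- Matrix::sparseMatrix(i = pix, j = owner[pt], x = 1,
                            dims = c(gs * gs, nrow(tr)))
  cnt <- Matrix::rowSums(P)
  mask <- matrix(cnt > 0, nrow = gs, ncol = gs, byrow = TRUE)
  Pn <- P
  nz <- cnt > 0
  Pn[nz, ] <- P[nz, , drop = FALSE] / cnt[nz]
  pixel_area <- matrix(cnt / sub^2 * (2 * r / gs)^2, nrow = gs, byrow = TRUE)
  out <- list(P = Pn, mask = mask, pixel_area = pixel_area, grid_size = gs)
  .raster_cache[[key]] <- out
  out
}

model_cache_key_raw <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(obj, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Rasterize a per-element image onto a pixel grid
#'
#' Interpolates an element-space conductivity-change image onto the standard
#' 32x32 pixel grid. Pixels outside the disc are NA and excluded by the
#' mask. Rows are the dorsoventral axis: row 1 is the ventral (+y) edge.
#'
#' @param image per-element values (length = element count)
#' @param mesh the mesh the image lives on
#' @param grid_size pixels per side (default 32)
#' @return an \code{eit_image}: matrix of pixel values with attributes
#'   \code{mask} and \code{pixel_area}
#' @export
rasterize <- function(image, mesh, grid_size = 32) {
  image <- as.numeric(image)
  if (length(image) != nrow(mesh$tris))
    stop("image length does not match mesh element count")
  rm_ <- raster_matrix(mesh, grid_size)
  vals <- as.numeric(rm_$P %*% image)
  gs <- rm_$grid_size
  v <- matrix(vals, nrow = gs, ncol = gs, byrow = TRUE)
  v[!rm_$mask] <- NA_real_
  structure(v, mask = rm_$mask, pixel_area = rm_$pixel_area,
            class = c("eit_image", "matrix"))
}

#' @export
print.eit_image <- function(x, ...) {
  m <- attr(x, "mask")
  cat(sprintf("eit_image: %dx%d grid, %d pixels inside disc, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), sum(m), min(x[m]), max(x[m])))
  invisible(x)
}

#' Detect breath events in a frame sequence
#'
#' Identifies end-inspiration (maxima) and end-expiration (minima) events in
#' the global signal: the mean over channels of the normalized difference
#' data against the sequence-mean reference. Extrema closer than half the
#' expected breath period to a stronger extremum are suppressed, events are
#' forced to alternate, and candidates whose tidal amplitude falls outside
#' \code{plausibility} times the running median amplitude are rejected (the
#' automatic surrogate for a human operator's review of implausible events).
#'
#' @param fs an \code{eit_frames}
#' @param frame_rate frames per second (defaults to the sequence metadata)
#' @param expected_rate expected respiratory rate in breaths/min (default 20)
#' @param plausibility length-2 factor range of acceptable tidal amplitude
#'   relative to the running median (default c(0.5, 2))
#' @return list of class \code{breath_events} with strictly increasing
#'   \code{inspiration} and \code{expiration} frame indices and a
#'   \code{rejected} data.frame (index, type, reason)
#' @export
detect_breaths <- function(fs, frame_rate = NULL, expected_rate = 20,
                           plausibility = c(0.5, 2)) {
  if (is.null(frame_rate)) frame_rate <- fs$frame_rate
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  v <- fs$frames
  vref <- colMeans(v)
  if (any(vref == 0)) stop("zero mean reference voltage; cannot form global signal")
  g <- rowMeans(sweep(v, 2, vref, "/") - 1)
  nt <- length(g)
  period <- 60 / expected_rate * frame_rate        # frames per breath
  if (nt < period) stop("sequence shorter than one expected breath period")
  min_sep <- 0.5 * period

  local_extrema <- function(s) {
    d <- diff(s)
    which(c(FALSE, d[-length(d)] > 0 & d[-1] <= 0, FALSE) |
          c(FALSE, d[-length(d)] >= 0 & d[-1] < 0, FALSE))
  }
  prune <- function(idx, val) {
    keep <- logical(length(idx))
    for (o in order(-val)) {
      if (!any(keep & abs(idx - idx[o]) < min_sep)) keep[o] <- TRUE
    }
    sort(idx[keep])
  }
  mx <- local_extrema(g)
  mn <- local_extrema(-g)
  if (length(mx) == 0 || length(mn) == 0)
    stop("no breaths detected: global signal has no extrema")
  mx <- prune(mx, g[mx])
  mn <- prune(mn, -g[mn])

  # force alternation: within a run of same-type events keep the strongest
  ev <- rbind(data.frame(idx = mx, type = "insp", str = g[mx]),
              data.frame(idx = mn, type = "exp", str = -g[mn]))
  ev <- ev[order(ev$idx), ]
  keep <- rep(TRUE, nrow(ev))
  i <- 1
  while (i < nrow(ev)) {
    j <- i
    while (j < nrow(ev) && ev$type[j + 1] == ev$type[i]) j <- j + 1
    if (j > i) {
      run <- i:j
      keep[run] <- FALSE
      keep[run[which.max(ev$str[run])]] <- TRUE
    }
    i <- j + 1
  }
  ev <- ev[keep, ]

  # plausibility: tidal amplitude of each inspiration against the running
  # median of all candidate amplitudes
  insp <- ev$idx[ev$type == "insp"]
  expi <- ev$idx[ev$type == "exp"]
  rejected <- data.frame(index = integer(0), type = character(0),
                         reason = character(0))
  if (length(insp) >= 2 && length(expi) >= 1) {
    amp <- vapply(insp, function(k) {
      nb <- expi[which.min(abs(expi - k))]
      g[k] - g[nb]
    }, numeric(1))
    med <- stats::median(amp)
    bad <- amp < plausibility[1] * med | amp > plausibility[2] * med
    if (any(bad)) {
      rejected <- data.frame(index = insp[bad], type = "insp",
                             reason = sprintf("tidal amplitude %.3g outside [%g, %g] x median %.3g",
                                              amp[bad], plausibility[1],
                                              plausibility[2], med))
      insp <- insp[!bad]
    }
  }
  if (length(insp) == 0 || length(expi) == 0)
    stop("no breaths detected after plausibility review")
  structure(list(inspiration = insp, expiration = expi, rejected = rejected,
                 global_signal = g, frame_rate = frame_rate),
            class = "breath_events")
}

#' @export
print.breath_events <- function(x, ...) {
  cat(sprintf("breath_events: %d end-inspiration, %d end-expiration, %d rejected\n",
              length(x$inspiration), length(x$expiration), nrow(x$rejected)))
  invisible(x)
}

#' Tidal image of a recording
#'
#' Reconstructs the average tidal conductivity change: the difference
#' between the mean end-inspiratory and mean end-expiratory data scans,
#' referenced to the average end-expiration frame, reconstructed with the
#' given model and rasterized. Lung regions appear as a conductivity
#' decrease (negative values); use \code{\link{ventilation_signal}} for the
#' positive ventilation map.
#'
#' @param fs an \code{eit_frames}
#' @param events a \code{breath_events}
#' @param model a calibrated \code{eit_model} (carries its mesh and data
#'   type)
#' @param reference optional reference voltage frame; default is the mean of
#'   the end-expiration frames
#' @param grid_size pixel grid size (default 32)
#' @return an \code{eit_image} of conductivity change
#' @export
tidal_image <- function(fs, events, model, reference = NULL, grid_size = 32) {
  if (length(events$inspiration) == 0 || length(events$expiration) == 0)
    stop("empty breath event set")
  v <- fs$frames
  v_insp <- colMeans(v[events$inspiration, , drop = FALSE])
  v_exp <- colMeans(v[events$expiration, , drop = FALSE])
  if (is.null(reference)) reference <- v_exp
  normalized <- isTRUE(model$provenance$normalized) ||
    isTRUE(attr(model$J, "normalized"))
  y <- difference_data(v_insp, reference, normalized = normalized) -
       difference_data(v_exp, reference, normalized = normalized)
  x <- reconstruct(model, y)
  rasterize(x, model$mesh, grid_size)
}

#' Ventilation-signal image
#'
#' Negates a tidal conductivity-change image so that ventilated regions
#' (conductivity decrease at inspiration) carry a positive ventilation
#' signal, the convention under which ROI thresholding, V_T and CoV operate.
#'
#' @param image an \code{eit_image} from \code{\link{tidal_image}}
#' @export
ventilation_signal <- function(image) {
  out <- -unclass(image)
  attributes(out) <- attributes(image)
  out
}

#' Lung region of interest
#'
#' Per image, pixels whose absolute ventilation signal is at least
#' \code{threshold_fraction} of that image's maximum; the final ROI is the
#' union over all recordings of a subject, giving one lung ROI per subject
#' and algorithm.
#'
#' @param images an \code{eit_image} or list of them (ventilation signal)
#' @param threshold_fraction in (0, 1); default 0.2 (the 20\% convention)
#' @return an \code{eit_roi}: logical matrix with provenance attributes
#' @export
lung_roi <- function(images, threshold_fraction = 0.2) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("configuration error: threshold_fraction must be in (0, 1)")
  if (inherits(images, "eit_image")) images <- list(images)
  if (length(images) == 0) stop("need at least one image")
  mask <- attr(images[[1]], "mask")
  roi <- matrix(FALSE, nrow = nrow(mask), ncol = ncol(mask))
  for (im in images) {
    a <- abs(unclass(im))
    a[!attr(im, "mask")] <- NA
    mx <- max(a, na.rm = TRUE)
    if (mx == 0) stop("all-zero ventilation image; cannot form ROI")
    roi <- roi | (!is.na(a) & a >= threshold_fraction * mx)
  }
  if (!any(roi)) stop("empty lung ROI")
  structure(roi, threshold_fraction = threshold_fraction,
            n_recordings = length(images), class = c("eit_roi", "matrix"))
}

#' Tidal volume measure V_T
#'
#' Sum of ventilation-signal pixel values within the lung ROI. With the
#' ventilation-signal sign convention V_T is positive for air inflow and is
#' linear in the underlying tidal amplitude.
#'
#' @param image ventilation-signal \code{eit_image}
#' @param roi an \code{eit_roi}
#' @export
compute_vt <- function(image, roi) {
  if (!any(roi)) stop("empty ROI")
  v <- unclass(image)
  sum(v[roi & attr(image, "mask")], na.rm = TRUE)
}

#' Centre of ventilation (CoV)
#'
#' Amplitude-weighted mean of the dorsoventral pixel coordinate over the
#' lung ROI, scaled to [-1, 1] with the pixel-centre convention: row i of a
#' grid_size-row image has coordinate (grid_size + 1 - 2i)/grid_size, so the
#' image centre is 0, the most ventral row is +(1 - 1/grid_size) and the
#' most dorsal row its negative. A decrease in CoV is a shift of ventilation
#' towards the dependent (dorsal) lung.
#'
#' @inheritParams compute_vt
#' @export
compute_cov <- function(image, roi) {
  v <- unclass(image)
  gs <- nrow(v)
  sel <- roi & attr(image, "mask")
  w <- v
  w[!sel] <- 0
  w[is.na(w)] <- 0
  tot <- sum(w)
  if (tot == 0) stop("zero total ventilation weight in ROI")
  coord <- (gs + 1 - 2 * seq_len(gs)) / gs   # row coordinate, ventral = +
  sum(rowSums(w) * coord) / tot
}
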