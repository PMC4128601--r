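#' Time-difference EIT data
#'
#' Forms the difference data vector between a measurement frame and a
#' reference frame: \code{y = v - v_ref} (plain difference) or
#' \code{y = (v - v_ref)/v_ref} elementwise (normalized difference, the
#' standard choice for clinical time-difference imaging, which cancels fixed
#' per-channel gain factors).
#'
#' @param frame channel voltage vector (length = protocol channels)
#' @param reference reference channel voltage vector
#' @param normalized logical; use normalized difference data
#' @return numeric channel vector
#' @export
difference_data <- function(frame, reference, normalized = TRUE) {
  v <- as.numeric(frame); vr <- as.numeric(reference)
  if (length(v) != length(vr))
    stop("frame and reference have different channel counts")
  if (normalized) {
    z <- which(vr == 0)
    if (length(z) > 0)
      stop("zero reference voltage on channel(s) ",
           paste(z, collapse = ", "), "; cannot normalize")
    (v - vr) / vr
  } else {
    v - vr
  }
}

#' Frame sequence container
#'
#' A matrix of measurement frames (rows = frames, columns = channels) with
#' acquisition metadata.
#'
#' @param frames numeric matrix, rows = frames, columns = channels
#' @param frame_rate frames per second
#' @param protocol the \code{eit_protocol} the channels follow
#' @param meta optional named list of extra metadata (subject, condition,
#'   seed, ...)
#' @return object of class \code{eit_frames}
#' @export
frame_sequence <- function(frames, frame_rate, protocol, meta = list()) {
  frames <- as.matrix(frames)
  if (ncol(frames) != nrow(protocol))
    stop("frame width (", ncol(frames), ") does not match protocol channel count (",
         nrow(protocol), ")")
  if (any(!is.finite(frames))) stop("frames contain non-finite values")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  structure(list(frames = frames, frame_rate = frame_rate,
                 protocol = protocol, meta = meta),
            class = "eit_frames")
}

#' @export
print.eit_frames <- function(x, ...) {
  cat(sprintf("eit_frames: %d frames x %d channels at %g Hz (%.1f s)\n",
              nrow(x$frames), ncol(x$frames), x$frame_rate,
              nrow(x$frames) / x$frame_rate))
  if (length(x$meta)) {
    keys <- intersect(c("subject", "condition", "seed"), names(x$meta))
    if (length(keys))
      cat("  ", paste(sprintf("%s=%s", keys, unlist(x$meta[keys])), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a frame sequence as plain text
#'
#' The matrix is written as a tab-separated file (rows = frames, columns =
#' channels) at full double precision ("%.17g", bit-exact round trip), with a
#' JSON metadata sidecar (\code{<path>.meta.json}) holding the frame rate,
#' protocol parameters, units, and any extra metadata.
#'
#' @param fs an \code{eit_frames}
#' @param path data file path; the sidecar is \code{paste0(path, ".meta.json")}
#' @export
write_frames <- function(fs, path) {
  mat <- fs$frames
  lines <- apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  meta <- c(list(format = "lungeit-frames-1",
                 frame_rate = fs$frame_rate,
                 n_frames = nrow(mat), n_channels = ncol(mat),
                 units = "volts (model units)",
                 protocol = list(n_electrodes = attr(fs$protocol, "n_electrodes"),
                                 current = attr(fs$protocol, "current"),
                                 kind = "adjacent")),
            fs$meta)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "lungeit-frames-1"))
    stop("not a lungeit frame sequence: ", path)
  lines <- readLines(path)
  mat <- do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
  if (nrow(mat) != meta$n_frames || ncol(mat) != meta$n_channels)
    stop("frame file dimensions disagree with metadata sidecar: ", path)
  protocol <- make_adjacent_protocol(meta$protocol$n_electrodes, meta$protocol$current)
  extra <- meta[setdiff(names(meta), c("format", "frame_rate", "n_frames",
                                       "n_channels", "units", "protocol"))]
  frame_sequence(mat, meta$frame_rate, protocol, meta = extra)
}
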