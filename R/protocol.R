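#' Adjacent (Sheffield) stimulation and measurement protocol
#'
#' For n electrodes: current is driven through each adjacent pair
#' (e, e+1 mod n) in turn; for each drive, voltages are measured on every
#' adjacent pair (m, m+1) that shares no electrode with the drive pair,
#' giving n*(n-3) channels (208 for n = 16).
#'
#' @param n_electrodes number of electrodes (>= 4)
#' @param current drive current amplitude (model units; default 1, the
#'   physical 5 mA of the acquisition device is metadata only since the
#'   linear reconstruction is invariant to it)
#' @return an \code{eit_protocol}: data.frame of channels with columns
#'   \code{channel}, \code{stim} (stimulation index), \code{drive_pos},
#'   \code{drive_neg}, \code{meas_pos}, \code{meas_neg}, plus attributes
#'   \code{n_electrodes}, \code{current} and \code{reciprocal} (the channel
#'   index of each channel's reciprocity partner).
#' @export
make_adjacent_protocol <- function(n_electrodes = 16, current = 1) {
  if (!is.numeric(n_electrodes) || length(n_electrodes) != 1 || n_electrodes < 4)
    stop("configuration error: n_electrodes must be >= 4")
  n <- as.integer(n_electrodes)
  nxt <- function(e) (e %% n) + 1L
  rows <- vector("list", n)
  for (e in seq_len(n)) {
    drv <- c(e, nxt(e))
    ms <- setdiff(seq_len(n), NULL)
    keep <- vapply(ms, function(m) length(intersect(c(m, nxt(m)), drv)) == 0, logical(1))
    ms <- ms[keep]
    rows[[e]] <- data.frame(stim = e, drive_pos = e, drive_neg = nxt(e),
                            meas_pos = ms, meas_neg = nxt(ms))
  }
  tab <- do.call(rbind, rows)
  tab <- cbind(channel = seq_len(nrow(tab)), tab)
  stopifnot(nrow(tab) == n * (n - 3))
  # reciprocity partner: channel driving (m, m+1) and measuring (e, e+1)
  key <- paste(tab$drive_pos, tab$meas_pos)
  rkey <- paste(tab$meas_pos, tab$drive_pos)
  recip <- match(rkey, key)
  structure(tab, n_electrodes = n, current = current, reciprocal = recip,
            class = c("eit_protocol", "data.frame"))
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat(sprintf("eit_protocol: adjacent drive/measure, %d electrodes, %d channels, current %g\n",
              attr(x, "n_electrodes"), nrow(x), attr(x, "current")))
  invisible(x)
}

#' Number of channels of a protocol
#' @param protocol an \code{eit_protocol}
#' @export
n_channels <- function(protocol) nrow(protocol)
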