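#' Reciprocity-error data weights
#'
#' By reciprocity, channel (drive a-b, measure c-d) and its partner
#' (drive c-d, measure a-b) should record identical voltages; their observed
#' mismatch is a practical per-channel indicator of data quality (poor
#' electrode contact). For each channel the relative reciprocal mismatch
#' \code{e_i = mean_t |v_i - v_recip(i)| / (|v_i| + |v_recip(i)| + floor)}
#' is averaged over frames and mapped to a weight
#' \code{w_i = exp(-(e_i / tau)^2)} in (0, 1].
#'
#' @param fs an \code{eit_frames} (raw voltages)
#' @param tau mismatch scale of the Gaussian weight map (default 0.1)
#' @param floor small additive floor preventing division by zero
#' @return per-channel weight vector in (0, 1]
#' @export
reciprocity_weights <- function(fs, tau = 0.1, floor = 1e-12) {
  if (!is.numeric(tau) || tau <= 0) stop("configuration error: tau must be > 0")
  recip <- attr(fs$protocol, "reciprocal")
  if (is.null(recip) || any(is.na(recip)))
    stop("protocol has channels without a reciprocal partner")
  v <- fs$frames
  vr <- v[, recip, drop = FALSE]
  e <- colMeans(abs(v - vr) / (abs(v) + abs(vr) + floor))
  exp(-(e / tau)^2)
}

#' Movement-augmented data noise covariance
#'
#' Adds the structured noise induced by electrode movement to a base channel
#' noise covariance: \code{Sigma' = Sigma + M Sigma_m M'} with
#' \code{Sigma_m = movement_scale * I} (isotropic prior on electrode
#' displacement, units length^2).
#'
#' @param base_cov base channel covariance (channels x channels), or a scalar
#'   for a multiple of the identity
#' @param M movement sensitivity matrix (channels x 2*n_electrodes)
#' @param movement_scale variance of electrode displacement (>= 0)
#' @return symmetric covariance matrix
#' @export
movement_augmented_covariance <- function(base_cov, M, movement_scale) {
  if (movement_scale < 0) stop("movement_scale must be >= 0")
  nc <- nrow(M)
  if (length(base_cov) == 1) base_cov <- diag(as.numeric(base_cov), nc)
  if (!all(dim(base_cov) == c(nc, nc)))
    stop("base_cov dimensions do not match movement Jacobian")
  S <- base_cov + movement_scale * tcrossprod(M)
  (S + t(S)) / 2
}

#' Default movement scale calibrated to the base covariance
#'
#' Chooses \code{movement_scale} so that the movement term contributes the
#' same total variance as the base covariance:
#' \code{trace(movement_scale * M M') = trace(Sigma)}.
#'
#' @inheritParams movement_augmented_covariance
#' @return scalar movement_scale
#' @export
calibrate_movement_scale <- function(base_cov, M) {
  nc <- nrow(M)
  if (length(base_cov) == 1) base_cov <- diag(as.numeric(base_cov), nc)
  sum(diag(base_cov)) / sum(M^2)
}
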