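#' NOSER amplitude prior
#'
#' Diagonal regularization matrix with entries \code{diag(J'J)^p}. The
#' exponent defaults to 0.5 (the convention of the NOSER lineage), which
#' penalizes image amplitude in proportion to each element's sensitivity and
#' compensates the sensitivity fall-off away from the electrodes.
#'
#' @param J sensitivity matrix (channels x elements)
#' @param p exponent applied to the diagonal of J'J (default 0.5)
#' @return diagonal regularization matrix (elements x elements)
#' @export
noser_prior <- function(J, p = 0.5) {
  if (length(J) == 0) stop("empty Jacobian")
  d <- colSums(J^2)
  if (any(d == 0))
    stop("all-zero Jacobian column(s) ", paste(which(d == 0), collapse = ", "))
  diag(d^p, nrow = length(d))
}

#' Spatial high-pass prior
#'
#' Smoothing regularization realized as \code{R = F'F} with \code{F = I - G},
#' where G is a row-normalized Gaussian smoothing operator over element
#' centroids. The Gaussian width is set so that the filter's half-power
#' spatial wavelength equals \code{cutoff_fraction} of the medium diameter
#' (default 10%): spatial wavelengths below the cutoff are penalized, the DC
#' component is annihilated exactly.
#'
#' @param mesh an \code{eit_mesh}
#' @param cutoff_fraction cutoff wavelength as a fraction of the medium
#'   diameter, in (0, 1); default 0.1
#' @return symmetric positive semi-definite matrix (elements x elements)
#' @export
hpf_prior <- function(mesh, cutoff_fraction = 0.1) {
  if (!is.numeric(cutoff_fraction) || cutoff_fraction <= 0 || cutoff_fraction >= 1)
    stop("configuration error: cutoff_fraction must be in (0, 1)")
  ctr <- mesh$centroids
  w_c <- cutoff_fraction * 2 * mesh$radius
  # amplitude response of I - G at wavenumber k is 1 - exp(-k^2 s^2 / 2);
  # half power (|H|^2 = 1/2) at k = 2*pi/w_c fixes s
  k_c <- 2 * pi / w_c
  s <- sqrt(-2 * log(1 - sqrt(0.5))) / k_c
  d2 <- as.matrix(stats::dist(ctr))^2
  G <- exp(-d2 / (2 * s^2)) * mesh$areas[col(d2)]  # area-weighted kernel
  G <- G / rowSums(G)                              # exact DC preservation
  Fm <- diag(nrow(G)) - G
  R <- crossprod(Fm)
  (R + t(R)) / 2
}
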