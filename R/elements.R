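#' Mueller matrix of an ideal linear retarder
#'
#' Builds the 4x4 Mueller matrix of a homogeneous linear retarder with
#' scalar retardance `delta_deg` and optical-axis azimuth `theta_deg`.
#' The Stokes convention is (I, Q, U, V); the azimuth is measured
#' counterclockwise from the laboratory x-axis looking toward the source
#' and is 180-degree periodic.
#'
#' The element is constructed as `R(theta) %*% M0(delta) %*% R(-theta)`,
#' where `M0` rotates the (U, V) Stokes plane by `delta` and `R` is the
#' azimuthal rotation [rotation_mueller()]. With this handedness the
#' differential azimuth `atan2(p5, p4) / 2` and the Lu-Chipman azimuth
#' both recover `theta_deg` exactly.
#'
#' @param delta_deg scalar retardance in degrees.
#' @param theta_deg azimuth of the (fast) optical axis in degrees.
#' @return a 4x4 numeric Mueller matrix.
#' @examples
#' retarder_mueller(0, 0)            # identity
#' retarder_mueller(180, 0)          # half-wave plate: diag(1, 1, -1, -1)
#' @export
retarder_mueller <- function(delta_deg, theta_deg = 0) {
  d <- delta_deg * pi / 180
  M0 <- diag(4)
  M0[3, 3] <- cos(d); M0[3, 4] <- sin(d)
  M0[4, 3] <- -sin(d); M0[4, 4] <- cos(d)
  R <- rotation_mueller(theta_deg)
  R %*% M0 %*% rotation_mueller(-theta_deg)
}

#' Mueller matrix of an azimuthal frame rotation
#'
#' Rotation of the laboratory frame by `theta_deg` about the beam axis;
#' acts on the (Q, U) Stokes components with the doubled angle.
#'
#' @param theta_deg rotation angle in degrees.
#' @return a 4x4 numeric Mueller matrix.
#' @export
rotation_mueller <- function(theta_deg) {
  t2 <- 2 * theta_deg * pi / 180
  c2 <- cos(t2); s2 <- sin(t2)
  matrix(c(1, 0, 0, 0,
           0, c2, s2, 0,
           0, -s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Mueller matrix of a diagonal depolarizer
#'
#' `diag(1, a1, a2, a3)`: each polarized Stokes component is attenuated
#' by its own factor in `[0, 1]`. With `a1 = a2 = a3 = a` the element is
#' an isotropic partial depolarizer; `a = 0` is the ideal depolarizer.
#'
#' @param a1,a2,a3 diagonal transmission factors in `[0, 1]`; `a2`, `a3`
#'   default to `a1` (isotropic depolarizer).
#' @return a 4x4 numeric Mueller matrix.
#' @export
depolarizer_mueller <- function(a1, a2 = a1, a3 = a1) {
  a <- c(a1, a2, a3)
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    stop("depolarizer factors must lie in [0, 1]")
  diag(c(1, a))
}

.check_mueller <- function(M, arg = "M") {
  if (!is.matrix(M) || !all(dim(M) == c(4L, 4L)))
    stop(sprintf("'%s' must be a 4x4 matrix", arg))
  if (!all(is.finite(M)))
    stop(sprintf("'%s' contains non-finite entries", arg))
  invisible(M)
}

#' Normalize a Mueller matrix by its (1,1) element
#'
#' Divides all 16 elements by `m11` (the unpolarized transmittance), so
#' the result has element (1,1) equal to 1. All decompositions assume
#' m11-normalized input; in particular the isotropic-absorption term of
#' the differential decomposition vanishes only after normalization.
#'
#' @param M a 4x4 Mueller matrix with `M[1,1] > 0`.
#' @return the normalized 4x4 matrix.
#' @export
normalize_m11 <- function(M) {
  .check_mueller(M)
  if (M[1, 1] <= 0)
    stop("degenerate pixel: m11 <= 0, cannot normalize")
  M / M[1, 1]
}

#' Remove a reference (substrate) matrix from a measurement
#'
#' In transmission the light traverses the glass substrate within the
#' measured sequence, so the sample matrix is recovered by
#' right-multiplication with the inverse of the blank-substrate
#' reference: `M_meas %*% solve(M_ref)`. With `M_ref = NULL` the
#' measurement is returned unchanged.
#'
#' @param M_meas measured 4x4 Mueller matrix.
#' @param M_ref reference (blank substrate) 4x4 Mueller matrix, or
#'   `NULL` to skip the correction.
#' @return the corrected 4x4 matrix.
#' @export
substrate_correct <- function(M_meas, M_ref = NULL) {
  .check_mueller(M_meas, "M_meas")
  if (is.null(M_ref)) return(M_meas)
  .check_mueller(M_ref, "M_ref")
  if (rcond(M_ref) < 1e-12)
    stop("substrate correction failed: singular reference matrix")
  M_meas %*% solve(M_ref)
}
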