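#' Minkowski-metric split of a Mueller-matrix logarithm
#'
#' Splits `L = log(M)` into the G-antisymmetric polarizing generator
#' `mm = (L - G t(L) G) / 2` and the G-symmetric depolarizing generator
#' `mu = (L + G t(L) G) / 2`, where `G = diag(1, -1, -1, -1)` is the
#' Minkowski metric. `mm + mu == L` exactly; `mm` carries the mean
#' dichroism/birefringence of the medium and `mu` the depolarization
#' and property uncertainties.
#'
#' @param L a 4x4 real matrix (a Mueller-matrix logarithm).
#' @return a list with 4x4 matrices `mm` and `mu`.
#' @export
gl_split <- function(L) {
  if (!is.matrix(L) || !all(dim(L) == c(4L, 4L)) || !all(is.finite(L)))
    stop("'L' must be a finite 4x4 matrix")
  G <- diag(c(1, -1, -1, -1))
  GLG <- G %*% t(L) %*% G
  list(mm = (L - GLG) / 2, mu = (L + GLG) / 2)
}

#' Elementary polarization properties from the differential generators
#'
#' Reads the six elementary properties from the polarizing generator
#' `mm` (p1: linear dichroism x-y, p2: linear dichroism +-45deg,
#' p3: circular dichroism, p4: linear birefringence x-y, p5: linear
#' birefringence +-45deg, p6: circular birefringence), the depolarizing
#' diagonal `alpha0..alpha3` and property uncertainties `d1..d6` from
#' `mu`, and forms the rotation-invariant summaries: net scalar
#' retardance `Rt = sqrt(p4^2 + p5^2 + p6^2)` (degrees), total
#' depolarization `alpha_t = |alpha1 + alpha2 + alpha3| / 3`, and the
#' optical-axis azimuth `theta = atan2(p5, p4) / 2` mapped to
#' `[0, 180)` degrees. The azimuth is reported as `NaN` when the linear
#' birefringence magnitude is negligible (axis undefined).
#'
#' @param mm,mu generators from [gl_split()].
#' @return a list of class `diff_props` with fields `p1..p6`,
#'   `alpha0..alpha3`, `d1..d6`, `rt_deg`, `alpha_t`, `theta_deg`,
#'   `valid`.
#' @export
extract_properties <- function(mm, mu) {
  if (any(!is.finite(mm)) || any(!is.finite(mu)))
    return(.diff_props_invalid())
  p <- c(mm[1, 2], mm[1, 3], mm[1, 4], mm[3, 4], mm[2, 4], mm[2, 3])
  alpha <- diag(mu)
  d <- c(mu[1, 2], mu[1, 3], mu[1, 4], mu[3, 4], mu[2, 4], mu[2, 3])
  rt_rad <- sqrt(p[4]^2 + p[5]^2 + p[6]^2)
  lin <- sqrt(p[4]^2 + p[5]^2)
  theta <- if (lin < 1e-12) NaN else ((atan2(p[5], p[4]) / 2) * 180 / pi) %% 180
  structure(list(
    p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4], p5 = p[5], p6 = p[6],
    alpha0 = alpha[1], alpha1 = alpha[2], alpha2 = alpha[3], alpha3 = alpha[4],
    d1 = d[1], d2 = d[2], d3 = d[3], d4 = d[4], d5 = d[5], d6 = d[6],
    rt_deg = rt_rad * 180 / pi,
    alpha_t = abs(alpha[2] + alpha[3] + alpha[4]) / 3,
    theta_deg = theta,
    valid = TRUE
  ), class = "diff_props")
}

.diff_props_invalid <- function() {
  nm <- c(paste0("p", 1:6), paste0("alpha", 0:3), paste0("d", 1:6),
          "rt_deg", "alpha_t", "theta_deg")
  out <- as.list(rep(NA_real_, length(nm)))
  names(out) <- nm
  out$valid <- FALSE
  structure(out, class = "diff_props")
}

#' Differential (logarithmic) decomposition of a Mueller matrix
#'
#' Full chain [matrix_log()] -> [gl_split()] -> [extract_properties()]
#' for one pixel. The input must be physically realizable (run
#' [cloude_filter()] first on measured data) and m11-normalized. When
#' the principal logarithm does not exist the pixel is returned with
#' `valid = FALSE` instead of aborting, so image-level loops can mask
#' and continue.
#'
#' @param M a 4x4 real, filtered, m11-normalized Mueller matrix.
#' @return a `diff_props` list; see [extract_properties()].
#' @export
differential_decompose <- function(M) {
  L <- tryCatch(matrix_log(M), error = function(e) NULL)
  if (is.null(L)) return(.diff_props_invalid())
  sp <- gl_split(L)
  extract_properties(sp$mm, sp$mu)
}
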