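#' Diattenuation and polarizance of a Mueller matrix
#'
#' The diattenuation vector is the normalized first row,
#' `Dvec = (m12, m13, m14) / m11`, and the polarizance vector the
#' normalized first column, `Pvec = (m21, m31, m41) / m11`; the scalar
#' diattenuation `D` and polarizance `P` are their Euclidean norms.
#'
#' @param M a 4x4 Mueller matrix with `M[1,1] > 0`.
#' @return a list with `D`, `Dvec`, `P`, `Pvec`.
#' @export
diattenuation_polarizance <- function(M) {
  .check_mueller(M)
  if (M[1, 1] <= 0) stop("m11 must be positive")
  Dvec <- M[1, 2:4] / M[1, 1]
  Pvec <- M[2:4, 1] / M[1, 1]
  D <- sqrt(sum(Dvec^2))
  if (D > 1 + 1e-6)
    warning("non-physical pixel: diattenuation exceeds 1 (should have been filtered)")
  list(D = D, Dvec = Dvec, P = sqrt(sum(Pvec^2)), Pvec = Pvec)
}

#' Diattenuator factor from a diattenuation vector
#'
#' Assembles the symmetric diattenuator Mueller matrix with 3x3 block
#' `mD = sqrt(1 - D^2) I + (1 - sqrt(1 - D^2)) Dhat Dhat^T` and first
#' row/column `(1, Dvec)`. `D = 0` gives the identity.
#'
#' @param D scalar diattenuation in `[0, 1)`.
#' @param Dvec diattenuation 3-vector (with `|Dvec| = D`).
#' @return the 4x4 diattenuator matrix `MD`.
#' @export
diattenuator_matrix <- function(D, Dvec) {
  if (D >= 1)
    stop("singular-diattenuator: D >= 1, retarder and depolarizer undefined")
  if (D < 1e-14) return(diag(4))
  Dhat <- Dvec / D
  r <- sqrt(1 - D^2)
  mD <- r * diag(3) + (1 - r) * (Dhat %o% Dhat)
  MD <- diag(4)
  MD[1, 2:4] <- Dvec
  MD[2:4, 1] <- Dvec
  MD[2:4, 2:4] <- mD
  MD
}

#' Factor the diattenuator out of a Mueller matrix
#'
#' `Mprime = M %*% solve(MD)`; for consistent inputs the first row of
#' the result is `(1, 0, 0, 0)` and `Mprime = MDelta %*% MR`.
#'
#' @param M a 4x4 Mueller matrix.
#' @param MD its diattenuator factor from [diattenuator_matrix()].
#' @return the 4x4 matrix `Mprime`.
#' @export
strip_diattenuator <- function(M, MD) {
  .check_mueller(M)
  if (rcond(MD) < 1e-14) stop("singular-diattenuator: MD not invertible")
  M %*% solve(MD)
}

#' Split a depolarizer-retarder product
#'
#' Given `Mprime = MDelta %*% MR` (first row `(1,0,0,0)`), recovers the
#' symmetric depolarizer block as the signed symmetric square root
#' `mDelta = sign(det m') sqrtm(m' m'^T)` via eigendecomposition of
#' `m' m'^T`, rebuilds `MDelta` with the polarizance column of
#' `Mprime`, and obtains the retarder as `MR = solve(MDelta) %*% Mprime`.
#' When `m'` is singular (complete depolarization along some axis) the
#' retarder is undefined: the depolarizer is still returned and
#' `valid_retarder` is `FALSE`.
#'
#' @param Mprime a 4x4 matrix with first row `(1, 0, 0, 0)`.
#' @return a list with `MDelta`, `MR` (or `NULL`), `abc` (eigenvalues of
#'   `mDelta` in its principal frame, decreasing by magnitude), and
#'   `valid_retarder`.
#' @export
depolarizer_retarder_split <- function(Mprime) {
  mp <- Mprime[2:4, 2:4]
  S <- mp %*% t(mp)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  sgn <- if (det(mp) < 0) -1 else 1
  mdelta <- sgn * es$vectors %*% diag(sqrt(lam)) %*% t(es$vectors)
  abc <- sgn * sqrt(lam)
  MDelta <- diag(4)
  MDelta[2:4, 1] <- Mprime[2:4, 1]
  MDelta[2:4, 2:4] <- mdelta
  if (min(sqrt(lam)) < 1e-12) {
    return(list(MDelta = MDelta, MR = NULL, abc = abc,
                valid_retarder = FALSE))
  }
  MR <- solve(MDelta) %*% Mprime
  list(MDelta = MDelta, MR = MR, abc = abc, valid_retarder = TRUE)
}

#' Scalar summaries of the Lu-Chipman factors
#'
#' Net scalar retardance `Rt = acos(tr(MR)/2 - 1)` in degrees on
#' `[0, 180]`, evaluated in the equivalent axis-angle form
#' `atan2(|w|, (tr(mR) - 1) / 2)` with `w` the antisymmetric part of
#' the rotation block - identical for exact rotations but accurate to
#' machine precision near zero retardance, where the arccosine of a
#' rounded trace loses half the significant digits; net depolarization `alpha_t = 1 - (|a|+|b|+|c|)/3` from
#' the principal-frame diagonal of the depolarizer block; optical-axis
#' azimuth from the linear components of the retardance vector, read
#' off the antisymmetric part of the retarder rotation block:
#' `theta = atan2(MR[2,4] - MR[4,2], MR[3,4] - MR[4,3]) / 2` mapped to
#' `[0, 180)` degrees. For a pure linear retarder this reduces exactly
#' to the textbook ratio `MR(2,4)/MR(4,3)` (the two-argument form fixes
#' the quadrant); for elliptical retarders arising from crossed-layer
#' composition it extracts the generator-space azimuth, which keeps the
#' Lu-Chipman azimuth consistent with the differential one. `theta` is
#' `NaN` when the retardance (or its linear part) is negligible.
#'
#' @param MDelta depolarizer factor.
#' @param MR retarder factor.
#' @return a list with `rt_deg`, `alpha_t`, `theta_deg`.
#' @export
lu_chipman_summaries <- function(MDelta, MR) {
  abc <- eigen((MDelta[2:4, 2:4] + t(MDelta[2:4, 2:4])) / 2,
               symmetric = TRUE, only.values = TRUE)$values
  alpha_t <- 1 - mean(abs(abc))
  x <- sum(diag(MR)) / 2 - 1
  if (abs(x) > 1 + 1e-9)
    stop("invalid retarder trace: |tr(MR)/2 - 1| > 1")
  x <- min(1, max(-1, x))
  p4c <- (MR[3, 4] - MR[4, 3]) / 2
  p5c <- (MR[2, 4] - MR[4, 2]) / 2
  p6c <- (MR[2, 3] - MR[3, 2]) / 2
  rt_deg <- atan2(sqrt(p4c^2 + p5c^2 + p6c^2), x) * 180 / pi
  lin <- sqrt(p4c^2 + p5c^2)
  theta <- if (rt_deg < 1e-6 || lin < 1e-12) NaN else
    ((atan2(p5c, p4c) / 2) * 180 / pi) %% 180
  list(rt_deg = rt_deg, alpha_t = alpha_t, theta_deg = theta)
}

#' Forward Lu-Chipman polar decomposition
#'
#' Factors a physically realizable, m11-normalized Mueller matrix into
#' the ordered product `M = MDelta %*% MR %*% MD` (diattenuator first
#' along the beam, then retarder, then depolarizer) and reports the
#' scalar summaries of [lu_chipman_summaries()]. Failure modes (total
#' diattenuation, singular depolarizer) are flagged per pixel via
#' `valid` / `valid_retarder` rather than raised, so image loops can
#' mask and continue.
#'
#' @param M a 4x4 real, filtered, m11-normalized Mueller matrix.
#' @return a list of class `lc_props` with the factors `MD`, `MR`,
#'   `MDelta`, scalars `D`, `P`, vectors `Dvec`, `Pvec`, principal-frame
#'   depolarizer diagonal `abc`, summaries `rt_deg`, `alpha_t`,
#'   `theta_deg`, and flags `valid`, `valid_retarder`.
#' @export
lu_chipman_decompose <- function(M) {
  out <- tryCatch({
    dp <- diattenuation_polarizance(M)
    if (dp$D >= 1) stop("singular diattenuator")
    MD <- diattenuator_matrix(dp$D, dp$Dvec)
    Mp <- strip_diattenuator(M, MD)
    sp <- depolarizer_retarder_split(Mp)
    if (!sp$valid_retarder) {
      abc <- sp$abc
      structure(list(MD = MD, MR = NULL, MDelta = sp$MDelta,
                     D = dp$D, Dvec = dp$Dvec, P = dp$P, Pvec = dp$Pvec,
                     abc = abc, rt_deg = NA_real_,
                     alpha_t = 1 - mean(abs(abc)), theta_deg = NA_real_,
                     valid = TRUE, valid_retarder = FALSE),
                class = "lc_props")
    } else {
      sm <- lu_chipman_summaries(sp$MDelta, sp$MR)
      structure(list(MD = MD, MR = sp$MR, MDelta = sp$MDelta,
                     D = dp$D, Dvec = dp$Dvec, P = dp$P, Pvec = dp$Pvec,
                     abc = sp$abc, rt_deg = sm$rt_deg,
                     alpha_t = sm$alpha_t, theta_deg = sm$theta_deg,
                     valid = TRUE, valid_retarder = TRUE),
                class = "lc_props")
    }
  }, error = function(e) NULL)
  if (is.null(out)) {
    out <- structure(list(MD = NULL, MR = NULL, MDelta = NULL,
                          D = NA_real_, Dvec = rep(NA_real_, 3),
                          P = NA_real_, Pvec = rep(NA_real_, 3),
                          abc = rep(NA_real_, 3), rt_deg = NA_real_,
                          alpha_t = NA_real_, theta_deg = NA_real_,
                          valid = FALSE, valid_retarder = FALSE),
                     class = "lc_props")
  }
  out
}
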