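#' Principal matrix logarithm of a Mueller matrix
#'
#' Computes `L = log(M)` by solving the eigenvalue-eigenvector problem
#' for `M` and forming `V diag(log d_i) V^-1` on the principal branch.
#' Complex-conjugate eigenvalue pairs of the real input combine so that
#' `L` is real; the imaginary residue is checked against `1e-9` and
#' discarded. When the eigenvector matrix is ill-conditioned (repeated
#' eigenvalues with a defective or nearly defective eigenspace) the
#' routine falls back to an inverse-scaling-and-squaring iteration
#' (repeated Denman-Beavers square roots followed by a Mercator series).
#'
#' The principal logarithm does not exist when an eigenvalue lies on the
#' closed negative real axis (the classical failure mode of the
#' differential decomposition for strongly scattering media); this
#' raises an error so the pixel can be flagged rather than silently
#' mis-decomposed.
#'
#' @param M a 4x4 real, m11-normalized Mueller matrix.
#' @return a 4x4 real matrix `L` with `expm(L) = M`.
#' @export
matrix_log <- function(M) {
  .check_mueller(M)
  ev <- eigen(M)
  vals <- ev$values
  if (any(Mod(vals) < 1e-12))
    stop("decomposition-failed: singular Mueller matrix (zero eigenvalue)")
  if (any(Re(vals) < 0 & abs(Im(vals)) <= 1e-12 * Mod(vals)))
    stop("decomposition-failed: eigenvalue on the negative real axis, principal logarithm undefined")
  L <- NULL
  V <- ev$vectors
  ok <- FALSE
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (!is.null(Vinv)) {
    Lc <- V %*% diag(log(vals)) %*% Vinv
    # accept the eigenpath only if it reproduces M and is real
    recon <- V %*% diag(vals) %*% Vinv
    if (max(abs(recon - M)) < 1e-10 * max(1, max(abs(M))) &&
        max(abs(Im(Lc))) < 1e-9) {
      L <- Re(Lc)
      ok <- TRUE
    }
  }
  if (!ok)
    L <- .logm_iss(M)
  L
}

# Inverse scaling and squaring: take Denman-Beavers square roots until
# the iterate is close to the identity, expand the Mercator series for
# log(I + A), then undo the scaling. Valid for matrices with no
# eigenvalue on the closed negative real axis (checked by the caller).
.logm_iss <- function(M, tol = 1e-14) {
  k <- 0L
  X <- M
  I4 <- diag(4)
  while (norm(X - I4, "F") > 0.25 && k < 60L) {
    X <- .sqrtm_db(X)
    k <- k + 1L
  }
  A <- X - I4
  L <- matrix(0, 4, 4)
  term <- I4
  for (j in 1:80) {
    term <- term %*% A
    L <- L + ((-1)^(j + 1) / j) * term
    if (max(abs(term)) / j < tol) break
  }
  L * 2^k
}

# Denman-Beavers iteration for the principal matrix square root.
.sqrtm_db <- function(A, maxit = 60L, tol = 1e-14) {
  Y <- A
  Z <- diag(4)
  for (i in seq_len(maxit)) {
    Y1 <- 0.5 * (Y + solve(Z))
    Z1 <- 0.5 * (Z + solve(Y))
    delta <- max(abs(Y1 - Y))
    Y <- Y1; Z <- Z1
    if (delta < tol * max(1, max(abs(Y)))) break
  }
  Y
}
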