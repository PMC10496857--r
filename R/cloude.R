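# Pauli basis in (I, Q, U, V) order: identity, sigma_z, sigma_x, sigma_y.
.pauli <- list(
  matrix(c(1, 0, 0, 1), 2, 2),
  matrix(c(1, 0, 0, -1), 2, 2),
  matrix(c(0, 1, 1, 0), 2, 2),
  matrix(c(0, 1i, -1i, 0), 2, 2)
)

# Precomputed tensor basis B[[i]][[j]] = sigma_i x conj(sigma_j): the 16
# Hermitian basis matrices of the Mueller <-> coherency map.
.pauli_basis <- local({
  lapply(1:4, function(i) lapply(1:4, function(j)
    kronecker(.pauli[[i]], Conj(.pauli[[j]]))))
})

#' Coherency matrix of a Mueller matrix
#'
#' Maps a real 4x4 Mueller matrix to its Hermitian coherency matrix
#' `H = (1/4) sum_ij m_ij (sigma_i x conj(sigma_j))`, with `sigma_0` the
#' identity and `sigma_1..3` the Pauli matrices ordered to match the
#' (I, Q, U, V) Stokes convention. The map is linear and invertible;
#' `trace(H) = m11`. A Mueller matrix is physically realizable exactly
#' when `H` is positive semi-definite (Cloude's criterion).
#'
#' @param M a 4x4 real Mueller matrix.
#' @return a 4x4 complex Hermitian matrix.
#' @seealso [mueller_from_coherency()], [cloude_filter()]
#' @export
coherency_from_mueller <- function(M) {
  .check_mueller(M)
  H <- matrix(0 + 0i, 4, 4)
  for (i in 1:4) for (j in 1:4)
    H <- H + M[i, j] * .pauli_basis[[i]][[j]]
  H <- H / 4
  (H + Conj(t(H))) / 2  # enforce exact Hermiticity
}

#' Mueller matrix of a coherency matrix
#'
#' Exact inverse of [coherency_from_mueller()]:
#' `m_ij = Re tr(H (sigma_i x conj(sigma_j)))`. The imaginary residue of
#' the trace is checked against `1e-8 * trace(H)` and discarded.
#'
#' @param H a 4x4 complex Hermitian matrix.
#' @return a 4x4 real Mueller matrix.
#' @export
mueller_from_coherency <- function(H) {
  if (!all(dim(H) == c(4L, 4L)))
    stop("'H' must be a 4x4 matrix")
  if (max(abs(H - Conj(t(H)))) > 1e-10 * max(1, max(abs(H))))
    stop("'H' is not Hermitian")
  M <- matrix(0, 4, 4)
  scale <- max(1e-12, abs(Re(sum(diag(H)))))
  for (i in 1:4) for (j in 1:4) {
    z <- sum(.pauli_basis[[i]][[j]] * t(H))  # tr(B %*% H)
    if (abs(Im(z)) > 1e-8 * scale)
      stop("numerical-consistency error: imaginary residue in Mueller elements")
    M[i, j] <- Re(z)
  }
  M
}

#' Cloude physical-realizability filter
#'
#' Projects a measured Mueller matrix onto the physically realizable
#' set: the Hermitian coherency matrix is eigendecomposed, negative
#' eigenvalues are clamped to zero, and the matrix is rebuilt from the
#' clamped spectrum. Matrices whose smallest coherency eigenvalue is
#' already `>= -tol * trace(H)` are returned unchanged, which makes the
#' filter idempotent. By default the trace (total intensity) is not
#' renormalized after clamping; `renormalize = TRUE` rescales the
#' clamped spectrum to preserve the trace.
#'
#' @param M a 4x4 real Mueller matrix with `M[1,1] > 0`.
#' @param tol realizability tolerance relative to `trace(H)`
#'   (default `1e-6`, well below a typical 1% instrument accuracy).
#' @param renormalize logical; rescale the clamped spectrum so the trace
#'   is preserved.
#' @return a list with elements `M` (the filtered matrix) and
#'   `min_eigenvalue` (smallest pre-clamp coherency eigenvalue, a
#'   diagnostic of how non-physical the input was).
#' @export
cloude_filter <- function(M, tol = 1e-6, renormalize = FALSE) {
  .check_mueller(M)
  if (M[1, 1] <= 0) stop("cloude_filter requires m11 > 0")
  H <- coherency_from_mueller(M)
  e <- eigen(H, symmetric = TRUE)
  vals <- e$values
  if (any(!is.finite(vals)))
    stop("filter error: non-finite coherency eigenvalues")
  min_ev <- min(vals)
  tr <- sum(vals)
  if (min_ev >= -tol * tr)
    return(list(M = M, min_eigenvalue = min_ev))
  clamped <- pmax(vals, 0)
  if (renormalize && sum(clamped) > 0)
    clamped <- clamped * tr / sum(clamped)
  Hf <- e$vectors %*% diag(clamped) %*% Conj(t(e$vectors))
  list(M = mueller_from_coherency(Hf), min_eigenvalue = min_ev)
}

#' Test physical realizability of a Mueller matrix
#'
#' `TRUE` when the smallest eigenvalue of the coherency matrix is
#' `>= -tol * trace(H)`.
#'
#' @inheritParams cloude_filter
#' @return logical.
#' @export
is_physical <- function(M, tol = 1e-6) {
  H <- coherency_from_mueller(M)
  vals <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  min(vals) >= -tol * sum(vals)
}
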