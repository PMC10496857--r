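# Independent numerical oracles, deliberately separate from the package
# implementation paths.

# Matrix logarithm by inverse scaling and squaring with a Gregory
# series: repeated principal square roots (Denman-Beavers iteration)
# until the iterate is near the identity, then
# log(A) = 2 atanh(X) = 2 sum_k X^(2k+1) / (2k+1),
# X = (A - I)(A + I)^-1, undone by the power of two.
oracle_logm <- function(A) {
  I4 <- diag(4)
  k <- 0L
  while (norm(A - I4, "F") > 0.2 && k < 40L) {
    Y <- A; Z <- I4
    for (it in 1:60) {
      Y1 <- 0.5 * (Y + solve(Z)); Z1 <- 0.5 * (Z + solve(Y))
      conv <- max(abs(Y1 - Y)) < 1e-15 * max(1, max(abs(Y1)))
      Y <- Y1; Z <- Z1
      if (conv) break
    }
    A <- Y
    k <- k + 1L
  }
  X <- (A - I4) %*% solve(A + I4)
  S <- X
  term <- X
  X2 <- X %*% X
  for (j in 1:60) {
    term <- term %*% X2
    S <- S + term / (2 * j + 1)
    if (max(abs(term)) < 1e-17) break
  }
  (2 * S) * 2^k
}

# Reference matrix exponential (independent of everything in R/).
expm_ref <- function(A) as.matrix(Matrix::expm(A))

rand_unit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Anisotropic diagonal depolarizer factors satisfying Cloude's
# realizability constraints (a_i + a_j <= 1 + a_k for all permutations;
# a fully anisotropic diagonal like diag(1, 1, 1, 0.4) is NOT a
# physical Mueller matrix), drawn by rejection.
rand_depol_triple <- function(a_min = 0.4) {
  repeat {
    a <- stats::runif(3, a_min, 1)
    if (a[1] + a[2] <= 1 + a[3] && a[1] + a[3] <= 1 + a[2] &&
        a[2] + a[3] <= 1 + a[1])
      return(a)
  }
}

# Random physical Mueller matrix: anisotropic depolarizer x retarder x
# mild diattenuator, m11-normalized. Parameter ranges keep all
# eigenvalues off the negative real axis so the principal logarithm
# exists.
random_physical_mueller <- function(delta_max = 150, d_max = 0.15,
                                    a_min = 0.4) {
  a <- rand_depol_triple(a_min)
  M <- depolarizer_mueller(a[1], a[2], a[3]) %*%
    retarder_mueller(stats::runif(1, 1, delta_max),
                     stats::runif(1, 0, 180))
  if (d_max > 0) {
    D <- stats::runif(1, 0, d_max)
    M <- M %*% diattenuator_matrix(D, D * rand_unit3())
  }
  M / M[1, 1]
}

# Folded absolute distance on the 180-degree azimuth circle.
ang_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Axis-angle rotation magnitude of the retarder 3x3 block, as an
# independent check of the retardance trace formula.
oracle_rotation_angle_deg <- function(MR) {
  acos(min(1, max(-1, (sum(diag(MR[2:4, 2:4])) - 1) / 2))) * 180 / pi
}

# Build a Mueller matrix whose coherency spectrum is prescribed, using
# the eigenvectors of an unrelated physical matrix.
mueller_with_spectrum <- function(lambda, seed_elem = NULL) {
  base <- if (is.null(seed_elem))
    depolarizer_mueller(0.6, 0.5, 0.4) %*% retarder_mueller(40, 30)
  else seed_elem
  Q <- eigen(coherency_from_mueller(base), symmetric = TRUE)$vectors
  mueller_from_coherency(Q %*% diag(lambda) %*% Conj(t(Q)))
}
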