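# internal helpers shared across modules

# voxel center coordinates (mm) along one axis: index 0 sits at -FOV/2
# (exactly for even N, to within half a voxel for odd N)
coordVec <- function(n, fov) {
  ((seq_len(n) - 1L) - floor(n / 2)) * (fov / n)
}

# Cartesian k-space integer offsets matching coordVec's convention
kIndexVec <- function(n) {
  (seq_len(n) - 1L) - floor(n / 2)
}

# run code with a temporary RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# correlated complex Gaussian noise: n x nCoils matrix, real and imaginary
# parts each with SD sd and inter-channel correlation rho
complexNoise <- function(n, nCoils, sd, rho) {
  R <- matrix(rho, nCoils, nCoils)
  diag(R) <- 1
  L <- chol(R)  # R = t(L) %*% L
  re <- matrix(stats::rnorm(n * nCoils, sd = sd), n, nCoils) %*% L
  im <- matrix(stats::rnorm(n * nCoils, sd = sd), n, nCoils) %*% L
  re + 1i * im
}

# fftshift-style reordering index for length n (maps stored order 0..n-1 to
# ascending frequency -floor(n/2)..)
shiftOrder <- function(n) {
  c(seq.int(ceiling(n / 2) + 1L, n), seq_len(ceiling(n / 2)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
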