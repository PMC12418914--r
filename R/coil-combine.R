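#' Estimate the coil noise covariance
#'
#' Sample covariance of the complex channel noise from a noise-only block,
#' Hermitian-symmetrized. Requires at least 10 noise draws per coil. The
#' result is flagged ill-conditioned (condition number above 1e6) when
#' channels are (nearly) duplicated.
#'
#' @param noiseBlock complex matrix, coils x draws (a
#'   \linkS4class{KSpaceData} noise slot), or a \linkS4class{KSpaceData}.
#' @return A \linkS4class{NoiseCovariance}.
#' @export
estimateNoiseCov <- function(noiseBlock) {
  if (is(noiseBlock, "KSpaceData")) noiseBlock <- noiseBlock@noise
  nCoils <- nrow(noiseBlock)
  n <- ncol(noiseBlock)
  if (n < 10L * nCoils) {
    stopf("need at least %d noise samples for %d coils, got %d",
          10L * nCoils, nCoils, n)
  }
  C <- noiseBlock %*% Conj(t(noiseBlock)) / n
  C <- (C + Conj(t(C))) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  kappa <- max(ev) / max(min(ev), .Machine$double.xmin)
  new("NoiseCovariance", cov = C, nSamples = as.integer(n),
      illConditioned = kappa > 1e6)
}

# whitening matrix W with W C W^H = I, via eigen decomposition; a ridge of
# 1e-6 tr(C)/n is added when the covariance is near-singular
whiteningMatrix <- function(cov) {
  C <- cov@cov
  n <- nrow(C)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values)) {
    C <- C + diag(1e-6 * Re(sum(diag(C))) / n, n)
    e <- eigen(C, symmetric = TRUE)
  }
  diag(1 / sqrt(e$values), n) %*% Conj(t(e$vectors))
}

#' Whitened-SVD combination of one voxel's multi-coil FID
#'
#' Whitens the coil x time matrix with the inverse Cholesky-like factor of
#' the noise covariance, takes its rank-1 (dominant) singular decomposition
#' (combined FID proportional to the dominant right-singular vector scaled
#' by its singular value), and returns the matched-filter combination
#' w^H X / ||w|| in raw signal units, with the global phase fixed so the
#' first FID point is real and non-negative. For a single coil this
#' reduces to the input up to that phase convention. Consistently
#' rescaling one channel and its covariance leaves the combination
#' direction, phase convention and SNR unchanged (the raw-unit amplitude
#' follows the rescaled geometry).
#'
#' @param voxelMatrix complex coils x time matrix.
#' @param cov \linkS4class{NoiseCovariance}.
#' @return list with \code{fid} (combined complex FID) and \code{weights}
#'   (raw-domain coil weight vector).
#' @export
wsvdCombine <- function(voxelMatrix, cov) {
  if (is.null(dim(voxelMatrix))) voxelMatrix <- matrix(voxelMatrix, nrow = 1)
  if (all(voxelMatrix == 0)) {
    warning("all-zero voxel data; returning zero FID")
    return(list(fid = complex(ncol(voxelMatrix)), weights = complex(nrow(voxelMatrix))))
  }
  W <- whiteningMatrix(cov)
  Xw <- W %*% voxelMatrix
  M <- Xw %*% Conj(t(Xw))
  u1 <- eigen(M, symmetric = TRUE)$vectors[, 1]
  w <- Conj(t(W)) %*% u1
  comb <- as.vector(Conj(t(u1)) %*% Xw) / sqrt(Re(sum(Conj(w) * w)))
  ph <- comb[1]
  if (Mod(ph) > 0) comb <- comb * Conj(ph) / Mod(ph)
  list(fid = comb, weights = as.vector(w))
}

#' Combine all voxels of a per-coil image by WSVD
#'
#' Applies \code{\link{wsvdCombine}} voxel-wise; the two-channel case is
#' solved in closed form (vectorized 2x2 Hermitian eigenproblem) for speed.
#'
#' @param img per-coil FID-domain \linkS4class{SpectralImage}.
#' @param cov \linkS4class{NoiseCovariance}.
#' @return A combined (coil-free) \linkS4class{SpectralImage}.
#' @export
combineCoils <- function(img, cov) {
  if (!img@perCoil) stopf("image is already coil-combined")
  d <- dim(img@data)
  nVox <- prod(d[1:3]); nT <- d[4]; nCoils <- d[5]
  X <- matrix(img@data, nVox * nT, nCoils)
  W <- whiteningMatrix(cov)
  Xw <- X %*% t(W)                      # whitened, (nVox*nT) x nCoils
  out <- matrix(0 + 0i, nVox, nT)

  if (nCoils == 2L) {
    X1 <- matrix(Xw[, 1], nVox, nT); X2 <- matrix(Xw[, 2], nVox, nT)
    a <- rowSums(Mod(X1)^2); b <- rowSums(Mod(X2)^2)
    cc <- rowSums(X1 * Conj(X2))
    lam1 <- (a + b + sqrt((a - b)^2 + 4 * Mod(cc)^2)) / 2
    # dominant eigenvector of [[a, cc], [Conj(cc), b]]
    u1 <- cc; u2 <- lam1 - a
    degen <- Mod(u1) + Mod(u2) < 1e-300
    u1[degen] <- 1; u2[degen] <- 0
    nrm <- sqrt(Mod(u1)^2 + Mod(u2)^2)
    u1 <- u1 / nrm; u2 <- u2 / nrm
    # raw-domain weight norm per voxel for matched-filter units
    Wh <- Conj(t(W))
    w1 <- Wh[1, 1] * u1 + Wh[1, 2] * u2
    w2 <- Wh[2, 1] * u1 + Wh[2, 2] * u2
    wNorm <- sqrt(Mod(w1)^2 + Mod(w2)^2)
    out <- (Conj(u1) * X1 + Conj(u2) * X2) / wNorm
  } else {
    for (v in seq_len(nVox)) {
      xv <- t(matrix(Xw[seq.int(v, by = nVox, length.out = nT), , drop = FALSE],
                     nT, nCoils))
      M <- xv %*% Conj(t(xv))
      u <- eigen(M, symmetric = TRUE)$vectors[, 1]
      w <- Conj(t(W)) %*% u
      out[v, ] <- as.vector(Conj(t(u)) %*% xv) / sqrt(Re(sum(Conj(w) * w)))
    }
  }
  ph <- out[, 1]
  scale <- Conj(ph) / pmax(Mod(ph), .Machine$double.xmin)
  out <- out * scale
  new("SpectralImage",
    data = array(out, dim = d[1:4]), domain = img@domain,
    dwell = img@dwell, acqDelay = img@acqDelay, freqAxis = img@freqAxis,
    referencePpm = img@referencePpm, hzPerPpm = img@hzPerPpm,
    voxelSize = img@voxelSize, nTimeMeasured = img@nTimeMeasured,
    perCoil = FALSE
  )
}
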