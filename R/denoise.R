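#' Marchenko-Pastur signal rank and noise estimate
#'
#' Given the singular values of an M x N matrix (sorted descending), finds
#' the smallest signal rank p such that the trailing eigenvalues
#' lambda_i = s_i^2 / max(M, N) are consistent with a Marchenko-Pastur
#' noise bulk: their spread lambda_(p+1) - lambda_min must not exceed the
#' bulk width 4 sqrt((M-p)/N) sigma^2, with sigma^2 the mean trailing
#' eigenvalue, evaluated iteratively over p. The returned sigma is the
#' per-entry noise SD (for complex entries, sqrt of the complex variance).
#'
#' @param singularValues singular values, descending.
#' @param nRows,nCols dimensions of the unfolded matrix.
#' @return list with \code{rank} (signal rank, 0 for pure noise) and
#'   \code{sigma} (per-entry noise SD estimate).
#' @export
mpRankEstimate <- function(singularValues, nRows, nCols) {
  if (length(singularValues) == 0L) stopf("empty singular value vector")
  if (is.unsorted(rev(singularValues))) stopf("singular values must be sorted descending")
  M <- min(nRows, nCols)
  N <- max(nRows, nCols)
  lam <- singularValues^2 / N
  for (p in 0:(M - 1L)) {
    tail <- lam[(p + 1L):M]
    sigma2 <- mean(tail)
    gamma <- (M - p) / N
    # 5% allowance on the asymptotic bulk width for finite-size
    # (Tracy-Widom) edge fluctuations of the empirical spectrum
    if (lam[p + 1L] - lam[M] <= 1.05 * 4 * sqrt(gamma) * sigma2) {
      return(list(rank = p, sigma = sqrt(sigma2)))
    }
  }
  list(rank = M - 1L, sigma = sqrt(lam[M]))
}

# mode-m unfolding of a 3-way tensor and its inverse
unfoldTensor <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(x, perm), d[mode], prod(d[-mode]))
}

foldTensor <- function(m, mode, dims) {
  perm <- c(mode, setdiff(seq_along(dims), mode))
  x <- array(m, dim = dims[perm])
  aperm(x, order(perm))
}

# hard-truncate a matrix at the MP-estimated rank; returns the denoised
# matrix and the (rank, sigma) report
mpTruncate <- function(X) {
  sv <- svd(X)
  est <- mpRankEstimate(sv$d, nrow(X), ncol(X))
  r <- est$rank
  Xd <- if (r == 0L) {
    matrix(0 + 0i, nrow(X), ncol(X))
  } else {
    sv$u[, seq_len(r), drop = FALSE] %*%
      (sv$d[seq_len(r)] * Conj(t(sv$v[, seq_len(r), drop = FALSE])))
  }
  list(X = Xd, rank = r, sigma = est$sigma)
}

#' Tensor Marchenko-Pastur PCA denoising
#'
#' Denoises a complex FID-domain image stack (x, y, z, time[, dynamic]) by
#' local-patch tensor MP-PCA: for every sliding spatial patch the tensor
#' (patch voxels x FID time x dynamics) is denoised by sequentially
#' unfolding along each mode and hard-truncating singular values at the
#' Marchenko-Pastur rank of \code{\link{mpRankEstimate}}, with
#' \code{sweeps} passes over the modes. Overlapping patches are averaged
#' uniformly. Phase is preserved (the operation is on complex data).
#'
#' @param x complex array (x, y, z, t) or (x, y, z, t, dynamics); a
#'   combined \linkS4class{SpectralImage}; or a list of combined
#'   SpectralImages (the dynamic frames).
#' @param patch spatial patch size, length 3.
#' @param stride sliding stride.
#' @param sweeps passes over the tensor modes.
#' @return list with \code{denoised} (same type as the input) and
#'   \code{report}: per-patch retained ranks per mode (first sweep), the
#'   median per-component noise SD estimate, input/output variance and the
#'   pass count.
#' @export
tmppcaDenoise <- function(x, patch = c(5, 5, 5), stride = 2L, sweeps = 2L) {
  asImage <- is(x, "SpectralImage")
  asList <- is.list(x) && all(vapply(x, is, logical(1), "SpectralImage"))
  arr <- if (asImage) {
    x@data
  } else if (asList) {
    d <- dim(x[[1]]@data)
    a <- array(0 + 0i, dim = c(d, length(x)))
    for (i in seq_along(x)) a[, , , , i] <- x[[i]]@data
    a
  } else {
    x
  }
  d <- dim(arr)
  if (length(d) < 4L) stopf("need at least a 4-D (x, y, z, time) array")
  spatial <- d[1:3]
  nT <- d[4]
  nDyn <- if (length(d) >= 5L) d[5] else 1L
  if (any(patch > spatial)) stopf("patch (%s) larger than image (%s)",
                                  paste(patch, collapse = "x"),
                                  paste(spatial, collapse = "x"))
  nonSingleton <- sum(c(prod(patch), nT, nDyn) > 1L)
  if (nonSingleton < 2L) stopf("need at least 2 non-singleton tensor modes")

  starts <- lapply(1:3, function(a) {
    unique(c(seq.int(1L, spatial[a] - patch[a] + 1L, by = stride),
             spatial[a] - patch[a] + 1L))
  })
  dim(arr) <- c(spatial, nT, nDyn)
  accum <- array(0 + 0i, dim = dim(arr))
  count <- array(0, dim = spatial)
  modes <- which(c(prod(patch), nT, nDyn) > 1L)
  ranks <- list()
  sigmas <- numeric(0)

  for (ix in starts[[1]]) for (iy in starts[[2]]) for (iz in starts[[3]]) {
    xs <- ix:(ix + patch[1] - 1L)
    ys <- iy:(iy + patch[2] - 1L)
    zs <- iz:(iz + patch[3] - 1L)
    sub <- arr[xs, ys, zs, , , drop = FALSE]
    ten <- array(sub, dim = c(prod(patch), nT, nDyn))
    patchRanks <- rep(NA_integer_, 3)
    first <- TRUE
    for (sw in seq_len(sweeps)) {
      for (m in modes) {
        X <- unfoldTensor(ten, m)
        tr <- mpTruncate(X)
        ten <- foldTensor(tr$X, m, dim(ten))
        if (sw == 1L) {
          patchRanks[m] <- tr$rank
          if (first) { sigmas <- c(sigmas, tr$sigma); first <- FALSE }
        }
      }
    }
    ranks[[length(ranks) + 1L]] <- patchRanks
    dim(ten) <- c(patch, nT, nDyn)
    accum[xs, ys, zs, , ] <- accum[xs, ys, zs, , , drop = FALSE] + ten
    count[xs, ys, zs] <- count[xs, ys, zs] + 1
  }

  res <- accum / array(count, dim = dim(accum))
  cplx <- is.complex(arr)
  report <- list(
    ranks = do.call(rbind, ranks),
    sigmaEstimate = stats::median(sigmas) / (if (cplx) sqrt(2) else 1),
    inputVariance = mean(Mod(arr)^2),
    outputVariance = mean(Mod(res)^2),
    sweeps = sweeps,
    patch = patch, stride = stride
  )
  if (length(d) == 4L) dim(res) <- d

  out <- if (asImage) {
    y <- x; y@data <- res; y
  } else if (asList) {
    lapply(seq_along(x), function(i) {
      y <- x[[i]]; y@data <- res[, , , , i]; y
    })
  } else {
    res
  }
  list(denoised = out, report = report)
}
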