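#' Build a density-weighted concentric-ring k-space trajectory
#'
#' Ring radii follow the half-offset scheme r_i = kmax (i + 1/2) / nRings
#' (no ring at k = 0, where the angular Nyquist count would be undefined).
#' Each ring carries at least its angular Nyquist count of samples,
#' ceiling(2 pi k_ring / delta_k) with delta_k = 1/FOV. The kz direction is
#' encoded as matrix_z equally spaced Cartesian partitions. Per-sample
#' density-compensation weights come from \code{\link{densityWeights}}.
#'
#' With \code{degenerateCartesian = TRUE} the returned object holds exactly
#' the Cartesian grid points of the target matrix with uniform weights; on
#' that trajectory the adjoint NUDFT reduces to the inverse discrete
#' Fourier transform, which is used as an oracle in the test suite.
#'
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param nRings number of rings (default from \code{acq}).
#' @param window radial density window, "uniform" or "hamming".
#' @param degenerateCartesian return the Cartesian grid instead of rings.
#' @return A \linkS4class{Trajectory}.
#' @examples
#' traj <- makeCrtTrajectory(acqParams())
#' max(traj@radii) < traj@kmax        # half-offset scheme stays inside kmax
#' sum(traj@weights)                  # 1
#' @export
makeCrtTrajectory <- function(acq, nRings = acq@nRings,
                              window = c("uniform", "hamming"),
                              degenerateCartesian = FALSE) {
  window <- match.arg(window)
  nx <- acq@matrixSize[1]; ny <- acq@matrixSize[2]; nz <- acq@matrixSize[3]
  kmaxX <- nx / (2 * acq@fov[1])
  kmaxY <- ny / (2 * acq@fov[2])
  kmax <- min(kmaxX, kmaxY)
  kzOffsets <- kIndexVec(nz) / acq@fov[3]

  if (degenerateCartesian) {
    mx <- kIndexVec(nx) / acq@fov[1]
    my <- kIndexVec(ny) / acq@fov[2]
    g <- expand.grid(kx = mx, ky = my)
    n <- nrow(g)
    return(new("Trajectory",
      radii = numeric(0), angularCounts = integer(0),
      kx = g$kx, ky = g$ky, ringIndex = rep(NA_integer_, n),
      kzOffsets = kzOffsets, weights = rep(1 / n, n),
      degenerateCartesian = TRUE, kmax = kmax,
      fov = acq@fov, matrixSize = acq@matrixSize
    ))
  }

  needed <- ceiling(max(nx, ny) / 2)
  if (nRings < needed) {
    stopf("nRings = %d cannot support a %dx%d matrix: radial spacing would exceed 1/FOV (need >= %d rings)",
          nRings, nx, ny, needed)
  }

  i <- seq_len(nRings) - 1L
  radii <- kmax * (i + 0.5) / nRings
  dk <- 1 / max(acq@fov[1], acq@fov[2])
  angularCounts <- pmax(4L, as.integer(ceiling(2 * pi * radii / dk)))

  kx <- ky <- numeric(sum(angularCounts))
  ringIndex <- integer(sum(angularCounts))
  pos <- 1L
  for (r in seq_len(nRings)) {
    m <- angularCounts[r]
    th <- 2 * pi * (seq_len(m) - 1L) / m
    idx <- pos:(pos + m - 1L)
    kx[idx] <- radii[r] * cos(th)
    ky[idx] <- radii[r] * sin(th)
    ringIndex[idx] <- r
    pos <- pos + m
  }

  traj <- new("Trajectory",
    radii = radii, angularCounts = angularCounts,
    kx = kx, ky = ky, ringIndex = ringIndex,
    kzOffsets = kzOffsets, weights = rep(1 / length(kx), length(kx)),
    degenerateCartesian = FALSE, kmax = kmax,
    fov = acq@fov, matrixSize = acq@matrixSize
  )
  traj@weights <- densityWeights(traj, window)
  traj
}

#' Density-compensation weights for a ring trajectory
#'
#' The weight of a sample on ring i is proportional to the annulus area of
#' that ring (proportional to its radius for equal-width annuli) divided by
#' the ring's angular sample count, multiplied by an optional radial window
#' (uniform, or Hamming tapering towards the Nyquist edge). Weights are
#' normalized to sum to 1.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param window "uniform" or "hamming".
#' @return numeric vector of positive per-sample weights summing to 1.
#' @export
densityWeights <- function(traj, window = c("uniform", "hamming")) {
  window <- match.arg(window)
  if (traj@degenerateCartesian) {
    n <- sampleCount(traj)
    return(rep(1 / n, n))
  }
  win <- switch(window,
    uniform = rep(1, length(traj@radii)),
    hamming = 0.54 + 0.46 * cos(pi * traj@radii / traj@kmax)
  )
  wRing <- traj@radii * win / traj@angularCounts
  w <- wRing[traj@ringIndex]
  w / sum(w)
}
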