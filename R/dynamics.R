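#' Aggregate a map over a mask
#'
#' Mean, SD or sum over the unexcluded mask voxels. The sum mode is the
#' aggregate used to compare kidney signal across different spatial
#' resolutions: per-voxel reconstructed amplitudes are proportional to
#' voxel volume, so their sum approximates the volume integral and is
#' resolution-independent for a smooth object.
#'
#' @param map numeric 3-D array or \linkS4class{ConcentrationMap} (a single
#'   time point).
#' @param mask logical array (taken from the map when NULL).
#' @param mode "mean", "sd" or "sum".
#' @param excluded optional logical array of voxels to drop; for a
#'   \linkS4class{ConcentrationMap} the stored exclusion flags are used.
#' @return scalar aggregate.
#' @export
maskAggregate <- function(map, mask = NULL, mode = c("mean", "sd", "sum"),
                          excluded = NULL) {
  mode <- match.arg(mode)
  if (is(map, "ConcentrationMap")) {
    if (is.null(mask)) mask <- map@mask
    if (is.null(excluded)) {
      excluded <- map@crlbExcluded | map@concExcluded | map@unfit
    }
    map <- map@values
  }
  if (is.null(excluded)) excluded <- array(FALSE, dim = dim(map))
  sel <- mask & !excluded
  vals <- map[sel]
  if (mode %in% c("mean", "sd") && length(vals) == 0L) {
    stopf("empty mask for mode '%s'", mode)
  }
  switch(mode,
    mean = mean(vals),
    sd = stats::sd(vals),
    sum = sum(vals)
  )
}

#' Fold change of a time course relative to baseline
#'
#' @param values aggregate values over time.
#' @param baselineIndex index of the baseline point (default 1).
#' @return values / values[baselineIndex].
#' @export
foldChange <- function(values, baselineIndex = 1L) {
  b <- values[baselineIndex]
  if (!is.finite(b) || b <= 0) stopf("baseline value must be positive")
  values / b
}

#' Coefficient of variation in percent
#'
#' 100 x sample SD / mean over a time-course segment.
#'
#' @param values segment values (at least 2, positive mean).
#' @return percent.
#' @examples
#' covPercent(c(9, 10, 11))  # 10
#' @export
covPercent <- function(values) {
  if (length(values) < 2L) stopf("need at least 2 points")
  m <- mean(values)
  if (m <= 0) stopf("mean must be positive")
  100 * stats::sd(values) / m
}

#' Friedman test across repeated-measure conditions
#'
#' Nonparametric comparison of paired measurements (e.g. voxel-wise SNR
#' under three reference voltages): the standard Friedman chi-square on
#' within-block ranks with average-rank ties.
#'
#' @param groups numeric matrix, blocks x conditions.
#' @return list with \code{statistic}, \code{df} and \code{p.value}.
#' @export
friedmanCompare <- function(groups) {
  groups <- as.matrix(groups)
  if (ncol(groups) < 2L) stopf("need at least 2 conditions")
  if (anyNA(groups)) stopf("blocks must be complete (no missing values)")
  ft <- stats::friedman.test(groups)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) {
    # fully tied blocks: no evidence against equality (the tie-corrected
    # statistic is 0/0)
    stat <- 0
    p <- 1
  }
  list(statistic = stat, df = unname(ft$parameter), p.value = p)
}

#' Paired t-test between two matched samples
#'
#' @param x,y numeric vectors of equal length (matched pairs, e.g. left
#'   and right kidney quality metrics).
#' @return list with \code{statistic}, \code{df} and \code{p.value}.
#' @export
pairedCompare <- function(x, y) {
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Kidney time course from a list of concentration (or amplitude) maps
#'
#' @param maps list of 3-D arrays or \linkS4class{ConcentrationMap}s, one
#'   per time point.
#' @param times acquisition times, minutes, strictly increasing.
#' @param mask logical mask (needed when maps are plain arrays).
#' @param mode aggregation mode.
#' @return data.frame with time, value and fold change columns.
#' @export
timeCourse <- function(maps, times, mask = NULL, mode = "mean") {
  if (length(maps) != length(times)) stopf("one map per time point required")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  vals <- vapply(maps, maskAggregate, numeric(1), mask = mask, mode = mode)
  fc <- if (is.finite(vals[1]) && vals[1] > 0) foldChange(vals) else rep(NA_real_, length(vals))
  data.frame(timeMin = times, value = vals, foldChange = fc)
}
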