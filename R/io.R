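#' Write a voxel map as NIfTI
#'
#' @param arr numeric 3-D or 4-D array (one volume per time point /
#'   parameter).
#' @param voxelSize voxel edge lengths, mm.
#' @param path output file (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeMapNifti <- function(arr, voxelSize, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- if (length(dim(arr)) == 4L) c(voxelSize, 1) else voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a label map as NIfTI
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param path output file.
#' @export
writeLabelMapNifti <- function(labels, path) {
  writeMapNifti(labels@labels, labels@voxelSize, path)
}

#' Read phantom and acquisition configuration from YAML
#'
#' The file may contain an \code{acquisition} block (arguments of
#' \code{\link{acqParams}}), a \code{relaxation} block (arguments of
#' \code{\link{relaxationAssumptions}}) and a \code{phantom} block with
#' \code{compartments} plus the noise/coil arguments of
#' \code{\link{phantomSpec}}.
#'
#' @param path YAML file.
#' @return list with \code{acq}, \code{relax} and \code{spec} objects
#'   (NULL where the block is absent).
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  acq <- if (!is.null(cfg$acquisition)) do.call(acqParams, cfg$acquisition)
  relax <- if (!is.null(cfg$relaxation)) {
    do.call(relaxationAssumptions, cfg$relaxation)
  }
  spec <- if (!is.null(cfg$phantom)) {
    args <- cfg$phantom
    args$compartments <- lapply(args$compartments, function(comp) {
      comp$center <- as.numeric(comp$center)
      comp$semiAxes <- as.numeric(comp$semiAxes)
      comp
    })
    if (!is.null(args$coilCenters)) {
      args$coilCenters <- do.call(rbind, lapply(args$coilCenters, as.numeric))
    }
    do.call(phantomSpec, args)
  }
  list(acq = acq, relax = relax, spec = spec)
}

#' Write a JSON run manifest
#'
#' Serializes run parameters and summary values (e.g. a denoise report or
#' exclusion counts) next to exported maps.
#'
#' @param manifest named list.
#' @param path output JSON file.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
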