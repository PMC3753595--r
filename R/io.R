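# NIfTI-1 volume and displacement-field I/O, plus the run configuration.
#
# Volumes are interpreted on the unit cube regardless of header pixdim
# (the grid spacing is 1/shape per axis); anisotropic headers are
# rejected by default since the method assumes isotropically resampled
# inputs.

INT_DATATYPES <- c(2L, 4L, 8L, 256L, 512L, 768L, 1024L, 1280L)

labelSidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".labels.tsv")
}

#' Read a NIfTI-1 volume as a scalar or label image
#'
#' Integer-typed volumes load as [LabelImage-class] (reading ROI names
#' from a `<base>.labels.tsv` sidecar when present), floating-point ones
#' as [ScalarImage-class]. The grid is built from the header dimensions
#' and normalized to the unit cube. Anisotropic voxel headers raise an
#' error instructing the caller to resample isotropically first, unless
#' `allowAnisotropic = TRUE`.
#'
#' @param path NIfTI file path.
#' @param allowAnisotropic accept anisotropic pixdim headers (the
#'   domain is still the unit cube).
#' @return a [ScalarImage-class] or [LabelImage-class]
#' @export
readVolume <- function(path, allowAnisotropic = FALSE) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (!(length(dm) %in% c(2L, 3L)))
    stop("unsupported header field dim: need 2 or 3 axes, got ",
         length(dm), call. = FALSE)
  pd <- RNifti::pixdim(img)[seq_along(dm)]
  if (!allowAnisotropic &&
      (max(pd) - min(pd)) > 1e-6 * max(pd))
    stop("anisotropic voxels in header field pixdim (",
         paste(signif(pd, 4), collapse = " x "),
         "); resample to isotropic voxels first or pass ",
         "allowAnisotropic = TRUE", call. = FALSE)
  grid <- ImageGrid(dm)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$datatype %in% INT_DATATYPES) {
    names <- NULL
    sc <- labelSidecarPath(path)
    if (file.exists(sc)) {
      tab <- utils::read.table(sc, header = TRUE, sep = "\t",
                               colClasses = c("integer", "character"))
      names <- stats::setNames(tab$name, as.character(tab$id))
    }
    LabelImage(array(as.integer(img), dm), grid, labelNames = names)
  } else {
    ScalarImage(array(as.double(img), dm), grid)
  }
}

#' Write a scalar or label image as NIfTI-1
#'
#' Scalar images are written as float64 (bit-exact round trip); label
#' images as int32 with their ROI names in a `<base>.labels.tsv`
#' sidecar.
#'
#' @param x a [ScalarImage-class] or [LabelImage-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly
#' @export
writeVolume <- function(x, path) {
  if (is(x, "ScalarImage")) {
    RNifti::writeNifti(RNifti::asNifti(x@values), path,
                       datatype = "double")
  } else if (is(x, "LabelImage")) {
    RNifti::writeNifti(RNifti::asNifti(x@labels), path,
                       datatype = "int32")
    if (length(x@labelNames)) {
      tab <- data.frame(id = as.integer(names(x@labelNames)),
                        name = unname(x@labelNames))
      utils::write.table(tab, labelSidecarPath(path), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  } else stop("x must be a ScalarImage or LabelImage", call. = FALSE)
  invisible(path)
}

#' Write a deformation map as a NIfTI displacement volume
#'
#' Stored as a (d+1)-dimensional float64 volume whose last axis indexes
#' the displacement component, in voxel units, with a plain-text sidecar
#' recording the domain convention. Round-trips displacements exactly.
#'
#' @param map a [DeformationMap-class].
#' @param path output path.
#' @return `path`, invisibly
#' @export
writeDeformation <- function(map, path) {
  grid <- map@grid
  d <- gridDim(grid)
  arr <- array(0, c(dim_of(grid), d))
  for (c in seq_len(d)) {
    arr_c <- map@displacement[[c]] / grid@spacing[c]
    arr[seq_len(length(arr_c)) + (c - 1L) * length(arr_c)] <- arr_c
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "double")
  writeLines(c(
    "lddmmseg displacement field",
    paste0("axes: ", d),
    paste0("shape: ", paste(dim_of(grid), collapse = " ")),
    "units: voxels (multiply by 1/shape per axis for domain units)",
    "convention: cell-centered unit-cube domain; pullback sampling",
    "  (voxel x of the warped image samples the source at x + u(x))"),
    sub("\\.nii(\\.gz)?$", "", path) |> paste0(".convention.txt"))
  invisible(path)
}

#' Read a deformation map written by [writeDeformation()]
#'
#' @param path NIfTI displacement volume path.
#' @return a [DeformationMap-class]
#' @export
readDeformation <- function(path) {
  arr <- RNifti::readNifti(path)
  dm <- dim(arr)
  d <- dm[length(dm)]
  shape <- dm[-length(dm)]
  stopifnot(length(shape) == d)
  grid <- ImageGrid(shape)
  nvox <- prod(shape)
  disp <- lapply(seq_len(d), function(c) {
    array(as.double(arr)[seq_len(nvox) + (c - 1L) * nvox], shape) *
      grid@spacing[c]
  })
  DeformationMap(disp, grid)
}

#' Default run configuration
#'
#' Every pipeline stage reads its settings from this plain list, which
#' round-trips losslessly through YAML. Defaults follow the method's
#' standard operating point: T = 10 timesteps, gamma = 1, cascade
#' schedule alpha = 0.01, 0.005, 0.002.
#'
#' @param ... named overrides of the defaults (unknown names are an
#'   error); nested lists (`registration`, `fusion`, `preprocessing`)
#'   are replaced wholesale if supplied.
#' @return a named list with components `registration`, `fusion`,
#'   `preprocessing`, `outputDir`, `seed`, `verbosity`
#' @export
runConfig <- function(...) {
  cfg <- list(
    registration = list(
      cascadeAlphas = c(0.01, 0.005, 0.002),
      gamma = 1, sigma = 0.1, nTimeSteps = 10L, epsilon0 = 1,
      maxIter = 100L, tol = 1e-6, tolWindow = 5L, lineSearch = TRUE),
    fusion = list(
      noiseVar = NA_real_, maxEmIter = 10L, emTol = 1e-6,
      neighborhoodRadius = 0L, tieBreak = "smallest"),
    preprocessing = list(histMatch = TRUE, prealign = FALSE),
    outputDir = ".",
    seed = 1L,
    verbosity = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (n in names(ov)) {
    if (is.list(cfg[[n]]) && is.list(ov[[n]])) {
      bad2 <- setdiff(names(ov[[n]]), names(cfg[[n]]))
      if (length(bad2)) stop("unknown config fields in ", n, ": ",
                             paste(bad2, collapse = ", "), call. = FALSE)
      cfg[[n]][names(ov[[n]])] <- ov[[n]]
    } else cfg[[n]] <- ov[[n]]
  }
  cfg
}

#' Write a run configuration as YAML
#' @param cfg list from [runConfig()].
#' @param path output path.
#' @return `path`, invisibly
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a run configuration written by [writeRunConfig()]
#'
#' Missing fields are filled with the [runConfig()] defaults.
#'
#' @param path YAML path.
#' @return config list
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  for (n in c("registration", "fusion", "preprocessing")) {
    if (!is.null(raw[[n]])) raw[[n]] <- as.list(raw[[n]])
  }
  if (!is.null(raw$registration$cascadeAlphas))
    raw$registration$cascadeAlphas <-
      as.numeric(unlist(raw$registration$cascadeAlphas))
  do.call(runConfig, raw)
}

# Config -> solver / fusion parameter objects
configToParams <- function(cfg) {
  r <- cfg$registration
  LDDMMParams(alpha = r$cascadeAlphas[length(r$cascadeAlphas)],
              gamma = r$gamma, sigma = r$sigma,
              nTimeSteps = r$nTimeSteps, epsilon0 = r$epsilon0,
              maxIter = r$maxIter, tol = r$tol,
              tolWindow = r$tolWindow, lineSearch = r$lineSearch,
              seed = cfg$seed)
}

configToFusion <- function(cfg) {
  f <- cfg$fusion
  FusionParams(noiseVar = f$noiseVar, maxEmIter = f$maxEmIter,
               emTol = f$emTol,
               neighborhoodRadius = f$neighborhoodRadius,
               tieBreak = f$tieBreak)
}
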