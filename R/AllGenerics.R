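# Accessor generics. Slots are never reached into from user code.

#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))
#' @export
setGeneric("fieldComponents", function(x) standardGeneric("fieldComponents"))
#' @export
setGeneric("displacement", function(x) standardGeneric("displacement"))
#' @export
setGeneric("mapCoords", function(x) standardGeneric("mapCoords"))
#' @export
setGeneric("energyTrace", function(x) standardGeneric("energyTrace"))
#' @export
setGeneric("forwardMap", function(x) standardGeneric("forwardMap"))
#' @export
setGeneric("inverseMap", function(x) standardGeneric("inverseMap"))
#' @export
setGeneric("fusedLabels", function(x) standardGeneric("fusedLabels"))
#' @export
setGeneric("fusionWeights", function(x) standardGeneric("fusionWeights"))
#' @export
setGeneric("mixingProportions",
           function(x) standardGeneric("mixingProportions"))
#' @export
setGeneric("emTrace", function(x) standardGeneric("emTrace"))

#' Grid accessor
#' @param x an object carrying an [ImageGrid-class]
#' @return the grid
#' @describeIn imageGrid grid of a scalar image
#' @export
setMethod("imageGrid", "ScalarImage", function(x) x@grid)
#' @describeIn imageGrid grid of a label image
#' @export
setMethod("imageGrid", "LabelImage", function(x) x@grid)
#' @describeIn imageGrid grid of a vector field
#' @export
setMethod("imageGrid", "VectorField", function(x) x@grid)
#' @describeIn imageGrid grid of a deformation map
#' @export
setMethod("imageGrid", "DeformationMap", function(x) x@grid)
#' @describeIn imageGrid grid of kernel multipliers
#' @export
setMethod("imageGrid", "KernelMultipliers", function(x) x@grid)

#' Intensity array of a scalar image
#' @param x a [ScalarImage-class]
#' @return double array
#' @export
setMethod("intensities", "ScalarImage", function(x) x@values)

#' Label array of a label image
#' @param x a [LabelImage-class]
#' @return integer array
#' @export
setMethod("labelArray", "LabelImage", function(x) x@labels)

#' @export
setGeneric("subjectImage", function(x) standardGeneric("subjectImage"))
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))

#' Intensity image of a phantom subject
#' @param x a [GroundTruth-class]
#' @return a [ScalarImage-class]
#' @export
setMethod("subjectImage", "GroundTruth", function(x) x@image)

#' Ground-truth label image of a phantom subject
#' @param x a [GroundTruth-class]
#' @return a [LabelImage-class]
#' @export
setMethod("subjectLabels", "GroundTruth", function(x) x@labels)

#' @export
setGeneric("atlasImage", function(x) standardGeneric("atlasImage"))
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))

#' Intensity image of an atlas
#' @param x an [AtlasEntry-class]
#' @return a [ScalarImage-class]
#' @export
setMethod("atlasImage", "AtlasEntry", function(x) x@image)

#' ROI charts of an atlas
#' @param x an [AtlasEntry-class]
#' @return a [LabelImage-class]
#' @export
setMethod("atlasLabels", "AtlasEntry", function(x) x@labels)

#' Label id to ROI name map
#' @param x a [LabelImage-class]
#' @return named character vector (names are label ids)
#' @export
setMethod("labelNames", "LabelImage", function(x) x@labelNames)

#' Component arrays of a vector field
#' @param x a [VectorField-class]
#' @return list of double arrays, one per axis
#' @export
setMethod("fieldComponents", "VectorField", function(x) x@components)

#' Displacement arrays of a deformation map
#' @param x a [DeformationMap-class]
#' @return list of double arrays (domain units), one per axis
#' @export
setMethod("displacement", "DeformationMap", function(x) x@displacement)

#' Mapped coordinates of a deformation map
#' @param x a [DeformationMap-class]
#' @return list of arrays, identity coordinates plus displacement
#' @export
setMethod("mapCoords", "DeformationMap", function(x) {
  ident <- identityCoords(x@grid)
  lapply(seq_along(ident), function(c) ident[[c]] + x@displacement[[c]])
})

#' Energy trace of a registration
#' @param x a [RegistrationResult-class]
#' @return data.frame with total, regularization and mismatch per accepted
#'   iteration
#' @export
setMethod("energyTrace", "RegistrationResult", function(x) x@energyTrace)

#' Forward map phi of a registration
#' @param x a [RegistrationResult-class]
#' @return a [DeformationMap-class]
#' @export
setMethod("forwardMap", "RegistrationResult", function(x) x@phi)

#' Backward map phi^-1 of a registration (pulls the atlas to the target)
#' @param x a [RegistrationResult-class]
#' @return a [DeformationMap-class]
#' @export
setMethod("inverseMap", "RegistrationResult", function(x) x@phiInv)
#' @describeIn inverseMap the known ground-truth map of a phantom subject
#' @export
setMethod("inverseMap", "GroundTruth", function(x) x@deformation)

#' Fused labels of a multi-atlas segmentation
#' @param x a [FusionResult-class]
#' @return a [LabelImage-class]
#' @export
setMethod("fusedLabels", "FusionResult", function(x) x@labels)

#' Per-atlas, per-voxel fusion weights
#' @param x a [FusionResult-class]
#' @return list of arrays, convex across atlases at every voxel
#' @export
setMethod("fusionWeights", "FusionResult", function(x) x@weights)

#' Global per-atlas mixing priors pi_j
#' @param x a [FusionResult-class]
#' @return numeric vector summing to 1
#' @export
setMethod("mixingProportions", "FusionResult", function(x) x@mixing)

#' Per-iteration EM observed-data log-likelihood
#' @param x a [FusionResult-class]
#' @return numeric vector, non-decreasing
#' @export
setMethod("emTrace", "FusionResult", function(x) x@emTrace)
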