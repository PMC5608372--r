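#' Number of voxels in a grid or field
#'
#' @param x a [VoxelGrid-class] or [OxygenField-class]
#' @return integer count
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "VoxelGrid", function(x) nrow(x@centers))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "OxygenField", function(x) length(x@conc))

#' Per-voxel concentrations of a solved field
#'
#' @param x an [OxygenField-class]
#' @param kConv optional mol/m3-per-percent conversion; when supplied the
#'   concentrations are returned in \% O2 instead of mol/m3
#' @return numeric vector
#' @export
setGeneric("concentrations",
           function(x, kConv = NULL) standardGeneric("concentrations"))

#' @rdname concentrations
#' @export
setMethod("concentrations", "OxygenField", function(x, kConv = NULL) {
  if (is.null(kConv)) x@conc else x@conc / kConv
})

#' Active-consumption mask of a solved field
#'
#' @param x an [OxygenField-class]
#' @return logical vector; FALSE marks dead-core voxels
#' @export
setGeneric("activeMask", function(x) standardGeneric("activeMask"))

#' @rdname activeMask
#' @export
setMethod("activeMask", "OxygenField", function(x) x@active)

#' Estimated permeability in m/s
#' @param x a [PermeabilityEstimate-class]
#' @return numeric scalar (m/s)
#' @export
setGeneric("permeability", function(x) standardGeneric("permeability"))

#' @rdname permeability
#' @export
setMethod("permeability", "PermeabilityEstimate", function(x) x@EHat)

#' Curve coefficients of a dose-response fit
#' @param object a [DoseResponseFit-class]
#' @param ... unused
#' @return named numeric vector (a, b, c, d)
#' @export
setMethod("coef", "DoseResponseFit", function(object, ...) {
  c(a = object@a, b = object@b, c = object@c, d = object@d)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat("Stern-Volmer calibration: I0 =", format(object@I0),
      " Ksv =", format(object@Ksv), "per % O2\n")
})

setMethod("show", "DeviceProfile", function(object) {
  cat("Device oxygen profile:", object@cLo, "-", object@cHi,
      "% O2 plateaus; peak gradients", object@peakSlope0, "(0 um) /",
      object@peakSlope180, "(180 um) %/um; wall at x =", object@wallX,
      "um\n")
})

setMethod("show", "Placement", function(object) {
  cat("Embryo placement:", object@orientation)
  if (object@orientation == "perpendicular")
    cat(" (mid-", object@polarity, ")", sep = "")
  cat(", offset", object@offset, "um from wall\n")
})

setMethod("show", "EmbryoGeometry", function(object) {
  cat("Embryo geometry (", object@shape, "): ", object@length, " x ",
      object@diameter, " x ", object@diameter, " um, voxel edge ",
      object@voxelEdge, " um\n", sep = "")
})

setMethod("show", "TransportParams", function(object) {
  cat("Transport parameters:\n",
      "  D     =", format(object@D), "m2/s\n",
      "  R     =", format(object@R), "mol/(m3 s)\n",
      "  E     =", format(object@E), "m/s (",
      format(object@E * 100), "cm/s )\n",
      "  kConv =", format(object@kConv), "mol/m3 per % O2\n")
})

setMethod("show", "VoxelGrid", function(object) {
  cat("Voxel grid:", nrow(object@centers), "elements,",
      nrow(object@interiorFaces), "interior faces,",
      nrow(object@boundaryFaces), "boundary faces (voxel edge",
      object@voxelEdge, "um)\n")
})

setMethod("show", "OxygenField", function(object) {
  nd <- sum(!object@active)
  cat("Oxygen field over", length(object@conc), "voxels: mean",
      format(mean(object@conc), digits = 4), "mol/m3,", nd,
      "dead-core voxel(s)\n")
})

setMethod("show", "DoseResponseFit", function(object) {
  cat("Dose-response curve: [O2] =", format(object@a, digits = 4), "+",
      format(object@b, digits = 4), "* exp[-", format(object@c, digits = 3),
      "(t +", format(object@d, digits = 4), ")]  (% O2, t in min)\n")
  if (is.finite(object@rss))
    cat("  residual sum of squares:", format(object@rss, digits = 4), "\n")
})

setMethod("show", "PermeabilityEstimate", function(object) {
  cat("Permeability estimate: E =", format(object@EHat, digits = 4),
      "m/s (", format(object@EHat * 100, digits = 4), "cm/s )\n",
      " objective:", format(object@objective, digits = 4),
      "; residuals (% O2):", paste(format(object@residuals, digits = 3),
                                   collapse = ", "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "frames over",
      format(diff(range(object@times))), "min; EL",
      format(object@positions[1], digits = 3), "->",
      format(object@positions[length(object@positions)], digits = 3), "\n")
})
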