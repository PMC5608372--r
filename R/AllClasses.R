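#' @import methods
#' @importFrom stats approx lm median optimize rnorm runif runmed uniroot
#'   coef resid setNames
NULL

#' Stern-Volmer calibration curve
#'
#' Relates fluorescence intensity of an optical oxygen sensor to oxygen
#' concentration through the Stern-Volmer quenching relation
#' \eqn{I_0/I = 1 + K_{sv} C}.
#'
#' @slot I0 reference intensity at zero oxygen (arbitrary units), > 0
#' @slot Ksv Stern-Volmer quenching constant (per \% O2), > 0
#' @seealso [fitSternVolmer()], [intensityToOxygen()]
#' @export
setClass("CalibrationCurve",
  representation(I0 = "numeric", Ksv = "numeric"),
  validity = function(object) {
    if (length(object@I0) != 1L || !is.finite(object@I0) || object@I0 <= 0)
      return("I0 must be a single positive number")
    if (length(object@Ksv) != 1L || !is.finite(object@Ksv) || object@Ksv <= 0)
      return("Ksv must be a single positive number")
    TRUE
  })

#' @param I0 reference intensity at zero oxygen
#' @param Ksv quenching constant (per \% O2)
#' @rdname CalibrationCurve-class
#' @export
calibrationCurve <- function(I0, Ksv) {
  new("CalibrationCurve", I0 = as.numeric(I0), Ksv = as.numeric(Ksv))
}

#' Oxygen concentration profile of the microfluidic device
#'
#' Parametric model of the oxygen field over the device surface: a logistic
#' transition between a hypoxic and a normoxic plateau, centred on the wall
#' separating the two gas microchannels.  The steepness at each height is
#' calibrated so that the slope at the wall centre equals the measured peak
#' gradient, interpolated linearly between the profile measured at the
#' membrane (0 um) and at embryo thickness (180 um) and clamped above.
#'
#' @slot cLo low plateau (\% O2)
#' @slot cHi high plateau (\% O2)
#' @slot peakSlope0 peak gradient at height 0 um (\%/um)
#' @slot peakSlope180 peak gradient at height 180 um (\%/um)
#' @slot wallX gradient centre position (um)
#' @seealso [deviceOxygenAt()]
#' @export
setClass("DeviceProfile",
  representation(cLo = "numeric", cHi = "numeric", peakSlope0 = "numeric",
                 peakSlope180 = "numeric", wallX = "numeric"),
  validity = function(object) {
    if (object@cLo >= object@cHi) return("cLo must be < cHi")
    if (object@peakSlope0 <= 0 || object@peakSlope180 <= 0)
      return("peak slopes must be > 0")
    TRUE
  })

#' @param cLo,cHi plateau concentrations (\% O2)
#' @param peakSlope0,peakSlope180 peak gradients (\%/um) at 0 and 180 um height
#' @param wallX gradient centre (um)
#' @rdname DeviceProfile-class
#' @export
deviceProfile <- function(cLo = 3, cHi = 20, peakSlope0 = 0.028,
                          peakSlope180 = 0.023, wallX = 0) {
  new("DeviceProfile", cLo = as.numeric(cLo), cHi = as.numeric(cHi),
      peakSlope0 = as.numeric(peakSlope0),
      peakSlope180 = as.numeric(peakSlope180), wallX = as.numeric(wallX))
}

#' Placement of an embryo in the device
#'
#' Describes how an embryo is positioned relative to the gas microchannels:
#' parallel to them (whole body at one oxygen level, up to the small gradient
#' across its width) or perpendicular, spanning the wall.  For perpendicular
#' placements the polarity states which pole faces the high-oxygen channel:
#' \code{"AP"} (mid-AP) puts the posterior pole on the high-oxygen side,
#' \code{"PA"} (mid-PA) the anterior pole.
#'
#' @slot orientation \code{"parallel"} or \code{"perpendicular"}
#' @slot polarity \code{"AP"} or \code{"PA"} (perpendicular only)
#' @slot offset signed distance (um) of the embryo AP-axis midpoint from the
#'   wall centre, positive toward the oxygen channel
#' @export
setClass("Placement",
  representation(orientation = "character", polarity = "character",
                 offset = "numeric"),
  validity = function(object) {
    if (!object@orientation %in% c("parallel", "perpendicular"))
      return("orientation must be 'parallel' or 'perpendicular'")
    if (object@orientation == "perpendicular" &&
        !object@polarity %in% c("AP", "PA"))
      return("perpendicular placements must specify polarity 'AP' or 'PA'")
    TRUE
  })

#' @param orientation \code{"parallel"} or \code{"perpendicular"}
#' @param polarity \code{"AP"} or \code{"PA"}; required for perpendicular
#'   placements, ignored for parallel ones
#' @param offset signed distance (um) from the wall centre
#' @rdname Placement-class
#' @export
placement <- function(orientation = c("parallel", "perpendicular"),
                      polarity = NA_character_, offset = 0) {
  orientation <- match.arg(orientation)
  new("Placement", orientation = orientation,
      polarity = as.character(polarity), offset = as.numeric(offset))
}

#' Embryo geometry
#'
#' The notional embryo is a prolate ellipsoid (anterior-posterior semi-axis
#' \code{length/2}, transverse semi-axes \code{diameter/2}) discretized into
#' cubic voxels of edge \code{voxelEdge}.  \code{shape = "box"} gives a
#' rectangular block instead, used for slab and block verification cases.
#'
#' @slot length AP extent (um)
#' @slot diameter VD/LR extent (um)
#' @slot voxelEdge cube edge length l (um)
#' @slot shape \code{"ellipsoid"} or \code{"box"}
#' @export
setClass("EmbryoGeometry",
  representation(length = "numeric", diameter = "numeric",
                 voxelEdge = "numeric", shape = "character"),
  validity = function(object) {
    if (object@voxelEdge <= 0) return("voxelEdge must be > 0")
    if (object@length <= 2 * object@voxelEdge ||
        object@diameter <= 2 * object@voxelEdge)
      return("length and diameter must exceed twice the voxel edge")
    if (!object@shape %in% c("ellipsoid", "box"))
      return("shape must be 'ellipsoid' or 'box'")
    TRUE
  })

#' @param length AP extent (um)
#' @param diameter transverse extent (um)
#' @param voxelEdge voxel edge (um)
#' @param shape \code{"ellipsoid"} (default) or \code{"box"}
#' @rdname EmbryoGeometry-class
#' @export
embryoGeometry <- function(length = 500, diameter = 180, voxelEdge = 10,
                           shape = c("ellipsoid", "box")) {
  shape <- match.arg(shape)
  new("EmbryoGeometry", length = as.numeric(length),
      diameter = as.numeric(diameter), voxelEdge = as.numeric(voxelEdge),
      shape = shape)
}

#' Oxygen transport parameters
#'
#' Physical constants of the oxygen balance: diffusivity D inside the tissue,
#' zero-order volumetric consumption rate R, membrane permeability E, and the
#' conversion factor from \% O2 in the gas phase to dissolved concentration
#' (mol/m3 per \%, default 0.26/21 for air-saturated aqueous medium at room
#' temperature).  The face exchange coefficient is D/l across interior faces
#' and E across boundary faces.
#'
#' @slot D oxygen diffusivity (m2/s)
#' @slot R volumetric consumption rate (mol/(m3 s))
#' @slot E membrane permeability (m/s)
#' @slot kConv dissolved-concentration conversion (mol/m3 per \% O2)
#' @export
setClass("TransportParams",
  representation(D = "numeric", R = "numeric", E = "numeric",
                 kConv = "numeric"),
  validity = function(object) {
    v <- c(D = object@D, E = object@E, kConv = object@kConv)
    if (any(!is.finite(v)) || any(v <= 0))
      return("D, E and kConv must be positive and finite")
    if (!is.finite(object@R) || object@R < 0)
      return("R must be >= 0 (zero-consumption limit allowed)")
    TRUE
  })

#' @param D diffusivity (m2/s)
#' @param R consumption rate (mol/(m3 s))
#' @param E membrane permeability (m/s)
#' @param kConv mol/m3 per \% O2
#' @rdname TransportParams-class
#' @export
transportParams <- function(D = 1.0e-9, R = 0.02, E = 1e-5,
                            kConv = 0.26 / 21) {
  new("TransportParams", D = as.numeric(D), R = as.numeric(R),
      E = as.numeric(E), kConv = as.numeric(kConv))
}

#' Voxelized embryo grid
#'
#' Finite-volume discretization of the embryo: voxel centre coordinates (um,
#' embryo frame: x along AP with the posterior pole at x = 0, z the height
#' above the device membrane), the interior face adjacency list and the
#' boundary face table.  Every voxel accounts for exactly 6 faces split
#' between the two lists.
#'
#' @slot centers n x 3 matrix of voxel centre coordinates (um)
#' @slot interiorFaces m x 2 integer matrix, one row per interior face
#' @slot boundaryFaces data.frame with columns \code{elem} (voxel index) and
#'   \code{cx}, \code{cy}, \code{cz} (face centroid, um)
#' @slot voxelEdge edge length l (um)
#' @slot geometry the [EmbryoGeometry-class] that was voxelized
#' @seealso [voxelize()]
#' @export
setClass("VoxelGrid",
  representation(centers = "matrix", interiorFaces = "matrix",
                 boundaryFaces = "data.frame", voxelEdge = "numeric",
                 geometry = "EmbryoGeometry"),
  validity = function(object) {
    n <- nrow(object@centers)
    if (n < 1L) return("grid contains no voxels")
    faces <- 2L * nrow(object@interiorFaces) + nrow(object@boundaryFaces)
    if (faces != 6L * n)
      return("face accounting inconsistent: every voxel must own 6 faces")
    TRUE
  })

#' Solved oxygen field over a voxel grid
#'
#' Per-voxel dissolved oxygen concentration (mol/m3) together with the
#' active-consumption mask.  Voxels where zero-order consumption would drive
#' the concentration negative form the dead core: consumption is switched off
#' there and the concentration is exactly zero.
#'
#' @slot conc per-voxel concentration (mol/m3), >= 0
#' @slot active logical mask; FALSE marks dead-core voxels
#' @seealso [solveSteadyState()]
#' @export
setClass("OxygenField",
  representation(conc = "numeric", active = "logical"),
  validity = function(object) {
    if (length(object@conc) != length(object@active))
      return("conc and active must have equal length")
    if (any(object@conc < 0)) return("concentrations must be non-negative")
    if (any(object@conc[!object@active] != 0))
      return("dead-core voxels must have zero concentration")
    TRUE
  })

#' One-term exponential oxygen / migration-time dose-response
#'
#' The fitted relation \eqn{[O_2](t) = a + b\,e^{-c(t+d)}} between the
#' environmental oxygen concentration (\%) and the engrailed stripe migration
#' time t (min).  The horizontal asymptote a is the critical oxygen level
#' below which stripe migration arrests.
#'
#' @slot a horizontal asymptote (\% O2)
#' @slot b amplitude (\% O2), > 0
#' @slot c rate (1/min), > 0
#' @slot d time offset (min)
#' @slot rss residual sum of squares of the fit (NA for curves built from
#'   published coefficients)
#' @seealso [fitDoseResponse()], [evalDoseResponse()], [invertDoseResponse()]
#' @export
setClass("DoseResponseFit",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
                 rss = "numeric"),
  validity = function(object) {
    if (object@b <= 0) return("amplitude b must be > 0")
    if (object@c <= 0) return("rate c must be > 0")
    TRUE
  })

#' @param a,b,c,d curve coefficients
#' @param rss residual sum of squares (optional)
#' @rdname DoseResponseFit-class
#' @export
doseResponseFit <- function(a, b, c, d, rss = NA_real_) {
  new("DoseResponseFit", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), d = as.numeric(d), rss = as.numeric(rss))
}

#' Published stripe-migration dose-response curve
#'
#' The one-term exponential reported for engrailed stripe migration under
#' graded oxygen: \eqn{[O_2] = 4.93 + 2480\,e^{-0.03 (t + 167.3)}}.
#'
#' @return a [DoseResponseFit-class]
#' @export
referenceDoseResponse <- function() {
  doseResponseFit(a = 4.93, b = 2480, c = 0.03, d = 167.3)
}

#' Estimate of the trans-embryonic oxygen permeability
#'
#' @slot EHat estimated permeability (m/s)
#' @slot objective value of the least-squares objective at the optimum
#' @slot residuals per-constraint residuals (\% O2)
#' @slot params the [TransportParams-class] used (with E = EHat)
#' @slot perConstraint data.frame of per-constraint diagnostics
#' @seealso [estimatePermeability()]
#' @export
setClass("PermeabilityEstimate",
  representation(EHat = "numeric", objective = "numeric",
                 residuals = "numeric", params = "TransportParams",
                 perConstraint = "data.frame"),
  validity = function(object) {
    if (object@EHat <= 0) return("EHat must be > 0")
    if (any(!is.finite(object@residuals))) return("residuals must be finite")
    TRUE
  })

#' Pole-cell migration trajectory
#'
#' Position time series of the pole-cell cluster centre along the AP axis in
#' effective length units (EL: distance from the posterior end divided by the
#' embryo length, so 0 = posterior pole, 1 = anterior pole).
#'
#' @slot times frame times (min), strictly increasing
#' @slot positions EL per frame, in [0, 1]
#' @seealso [migrationTime1090()], [meanVelocity()]
#' @export
setClass("Trajectory",
  representation(times = "numeric", positions = "numeric"),
  validity = function(object) {
    if (length(object@times) < 3L) return("a trajectory needs >= 3 frames")
    if (length(object@times) != length(object@positions))
      return("times and positions must have equal length")
    if (any(diff(object@times) <= 0))
      return("times must be strictly increasing")
    if (any(object@positions < 0 | object@positions > 1))
      return("positions must lie in [0, 1] (effective length)")
    TRUE
  })

#' @param times frame times (min)
#' @param positions effective-length positions
#' @rdname Trajectory-class
#' @export
trajectory <- function(times, positions) {
  new("Trajectory", times = as.numeric(times),
      positions = as.numeric(positions))
}
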