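#' Oxygen concentration in the device at a position and height
#'
#' Evaluates the parametric device oxygen field: a logistic transition from
#' the hypoxic plateau \code{cLo} to the normoxic plateau \code{cHi} as a
#' function of the signed distance x from the wall centre (positive toward
#' the oxygen-infused channel).  The logistic steepness is set so that the
#' slope at the wall centre equals the measured peak gradient at the given
#' height; the peak gradient is interpolated linearly between the profiles
#' measured at 0 um and 180 um and held constant above 180 um.  The value at
#' the wall centre is the plateau midpoint at every height.
#'
#' @param x position (um), signed distance from the wall centre; vectorized
#' @param h height above the membrane (um), >= 0
#' @param profile a [DeviceProfile-class]
#' @return oxygen concentration (\% O2)
#' @examples
#' deviceOxygenAt(0, 0, deviceProfile())     # midpoint 11.5 %
#' deviceOxygenAt(500, 0, deviceProfile())   # ~ high plateau
#' @export
deviceOxygenAt <- function(x, h, profile) {
  stopifnot(is(profile, "DeviceProfile"))
  if (any(h < 0)) stop("height must be >= 0")
  slope <- peakSlopeAtHeight(h, profile)
  span <- profile@cHi - profile@cLo
  # logistic slope at the centre is span * k / 4
  k <- 4 * slope / span
  profile@cLo + span / (1 + exp(-k * (x - profile@wallX)))
}

# linear interpolation of the peak gradient between the two measured heights,
# clamped above 180 um
peakSlopeAtHeight <- function(h, profile) {
  hc <- pmin(pmax(h, 0), 180)
  profile@peakSlope0 +
    (profile@peakSlope180 - profile@peakSlope0) * hc / 180
}

#' External oxygen field seen by each boundary face of a placed embryo
#'
#' Maps every boundary face of a voxelized embryo to device coordinates for
#' the given placement and evaluates the device oxygen profile at the face
#' centroid.  Parallel placements have the AP axis along the wall, so the
#' field is constant along AP (the small transverse gradient across the
#' embryo width remains); perpendicular placements span the wall, with the
#' posterior pole toward the oxygen channel for polarity \code{"AP"}
#' (mid-AP) and away from it for \code{"PA"} (mid-PA), so mid-AP and mid-PA
#' fields are mirror images along AP.
#'
#' @param placement a [Placement-class]
#' @param profile a [DeviceProfile-class]
#' @param grid a [VoxelGrid-class] from [voxelize()]
#' @return numeric vector of \% O2, one entry per row of the grid's boundary
#'   face table
#' @export
externalFieldForPlacement <- function(placement, profile, grid) {
  stopifnot(is(placement, "Placement"), is(profile, "DeviceProfile"),
            is(grid, "VoxelGrid"))
  bf <- grid@boundaryFaces
  geom <- grid@geometry
  if (placement@orientation == "parallel") {
    # AP axis along the wall; the VD axis (y) crosses the gradient
    dx <- placement@offset + (bf$cy - geom@diameter / 2)
  } else {
    # embryo spans the wall; embryo frame has the posterior pole at x = 0
    half <- geom@length / 2
    dx <- if (placement@polarity == "AP") {
      placement@offset + (half - bf$cx)   # posterior on the high-O2 side
    } else {
      placement@offset - (half - bf$cx)   # anterior on the high-O2 side
    }
  }
  deviceOxygenAt(dx, bf$cz, profile)
}
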