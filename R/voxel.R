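#' Voxelize an embryo geometry
#'
#' Discretizes the embryo into cubic finite-volume elements on a regular
#' lattice.  A lattice cube belongs to the embryo when its centre lies inside
#' the prolate ellipsoid with semi-axes \code{length/2}, \code{diameter/2},
#' \code{diameter/2} (or anywhere in the bounding box for
#' \code{shape = "box"}).  The embryo frame has x along the AP axis with the
#' posterior pole at x = 0, and z the height above the device membrane.
#'
#' Faces shared by two occupied cubes are interior faces; the remaining faces
#' are boundary faces through which membrane exchange occurs.
#'
#' @param geometry an [EmbryoGeometry-class]
#' @return a [VoxelGrid-class]
#' @examples
#' grid <- voxelize(embryoGeometry(length = 200, diameter = 100))
#' nVoxels(grid)
#' @export
voxelize <- function(geometry) {
  stopifnot(is(geometry, "EmbryoGeometry"))
  l <- geometry@voxelEdge
  nx <- ceiling(geometry@length / l)
  ny <- ceiling(geometry@diameter / l)
  nz <- ceiling(geometry@diameter / l)

  cx <- (seq_len(nx) - 0.5) * l
  cy <- (seq_len(ny) - 0.5) * l
  cz <- (seq_len(nz) - 0.5) * l
  centers <- cbind(x = rep(cx, times = ny * nz),
                   y = rep(rep(cy, each = nx), times = nz),
                   z = rep(cz, each = nx * ny))

  if (geometry@shape == "ellipsoid") {
    a <- geometry@length / 2
    b <- geometry@diameter / 2
    occ <- ((centers[, 1] - a) / a)^2 +
      ((centers[, 2] - b) / b)^2 +
      ((centers[, 3] - b) / b)^2 <= 1
  } else {
    occ <- rep(TRUE, nrow(centers))
  }
  if (!any(occ)) stop("geometry too small to contain any voxel")

  idx <- array(0L, dim = c(nx, ny, nz))
  idx[occ] <- seq_len(sum(occ))
  centers <- centers[occ, , drop = FALSE]

  # six lattice directions; each +-pair visited once via the positive shifts
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  pos <- which(idx > 0L, arr.ind = TRUE)
  ord <- order(idx[idx > 0L])
  pos <- pos[ord, , drop = FALSE]

  int_i <- int_j <- integer(0)
  b_elem <- integer(0)
  b_cx <- b_cy <- b_cz <- numeric(0)
  dims <- c(nx, ny, nz)
  for (s in seq_len(6L)) {
    sh <- shifts[s, ]
    nb <- sweep(pos, 2L, sh, "+")
    inside <- nb[, 1] >= 1L & nb[, 1] <= nx &
      nb[, 2] >= 1L & nb[, 2] <= ny &
      nb[, 3] >= 1L & nb[, 3] <= nz
    nb_idx <- rep(0L, nrow(pos))
    if (any(inside))
      nb_idx[inside] <- idx[nb[inside, , drop = FALSE]]
    here <- seq_len(nrow(pos))
    is_int <- nb_idx > 0L
    if (s %% 2L == 1L) {  # positive shifts: record each interior face once
      int_i <- c(int_i, here[is_int])
      int_j <- c(int_j, nb_idx[is_int])
    }
    bd <- !is_int
    if (any(bd)) {
      b_elem <- c(b_elem, here[bd])
      b_cx <- c(b_cx, centers[bd, 1] + sh[1] * l / 2)
      b_cy <- c(b_cy, centers[bd, 2] + sh[2] * l / 2)
      b_cz <- c(b_cz, centers[bd, 3] + sh[3] * l / 2)
    }
  }

  new("VoxelGrid",
      centers = centers,
      interiorFaces = cbind(i = int_i, j = int_j),
      boundaryFaces = data.frame(elem = b_elem, cx = b_cx, cy = b_cy,
                                 cz = b_cz),
      voxelEdge = l,
      geometry = geometry)
}

#' Write a solved field as a flat table
#'
#' @param field an [OxygenField-class]
#' @param grid the matching [VoxelGrid-class]
#' @param params a [TransportParams-class] (for the \%-O2 conversion)
#' @param file path of the CSV to write; when NULL the data.frame is returned
#'   without writing
#' @return invisibly, a data.frame with element index, centre coordinates
#'   (um), concentration in mol/m3 and \% O2, and the active flag
#' @export
fieldToTable <- function(field, grid, params, file = NULL) {
  stopifnot(is(field, "OxygenField"), is(grid, "VoxelGrid"),
            is(params, "TransportParams"))
  df <- data.frame(element = seq_len(nVoxels(grid)),
                   x = grid@centers[, 1], y = grid@centers[, 2],
                   z = grid@centers[, 3],
                   C_mol_m3 = field@conc,
                   C_percent = field@conc / params@kConv,
                   active = field@active)
  if (!is.null(file))
    utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
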