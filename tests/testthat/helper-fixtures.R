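# Shared fixtures: small geometries and a cached default grid so the heavier
# solver tests do not re-voxelize repeatedly.

defaultGrid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- voxelize(embryoGeometry())
    g
  }
})

smallGrid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- voxelize(embryoGeometry(200, 80, 10))
    g
  }
})

# 20 x 3 x 3 box of 5 um voxels; side faces insulated so each column is a
# one-dimensional slab exchanging only through its two end faces
slabCase <- function(R = 0.02, E = 1e-4, ext = 20) {
  g <- voxelize(embryoGeometry(100, 15, 5, shape = "box"))
  bf <- g@boundaryFaces
  external <- ifelse(bf$cx %in% c(0, 100), ext, NA)
  list(grid = g, params = transportParams(D = 1e-9, R = R, E = E),
       external = external, ext = ext)
}

# independent dense direct solve of the same discrete balance, assembled by
# plain loops and solved with base R linear algebra
denseOracle <- function(grid, params, external) {
  n <- nVoxels(grid)
  l <- grid@voxelEdge * 1e-6
  S <- l^2; V <- l^3
  external <- rep_len(external, nrow(grid@boundaryFaces))
  A <- matrix(0, n, n)
  b <- rep(params@R * V, n)
  eta <- params@D / l
  for (r in seq_len(nrow(grid@interiorFaces))) {
    i <- grid@interiorFaces[r, 1]; j <- grid@interiorFaces[r, 2]
    A[i, i] <- A[i, i] - eta * S; A[i, j] <- A[i, j] + eta * S
    A[j, j] <- A[j, j] - eta * S; A[j, i] <- A[j, i] + eta * S
  }
  for (r in seq_len(nrow(grid@boundaryFaces))) {
    i <- grid@boundaryFaces$elem[r]
    A[i, i] <- A[i, i] - params@E * S
    b[i] <- b[i] - params@E * S * external[r] * params@kConv
  }
  solve(A, b)
}

# permutation mapping each voxel to its mirror image across the AP midplane
mirrorPermutation <- function(grid) {
  L <- grid@geometry@length
  key <- function(M) paste(round(M[, 1], 6), round(M[, 2], 6),
                           round(M[, 3], 6))
  match(key(cbind(L - grid@centers[, 1], grid@centers[, 2],
                  grid@centers[, 3])),
        key(grid@centers))
}
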