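## Internal helpers for addressing nodes of an EnergyGrid. Nodes are
## identified by their flat (column-major) index, so the first axis varies
## fastest -- the same convention the grid file dialects use.

gridDim <- function(grid) as.integer(grid@axes$n)

nNodes <- function(grid) prod(gridDim(grid))

## flat index -> matrix of per-axis sub-indices (1-based)
nodeSub <- function(grid, flat) arrayInd(flat, gridDim(grid))

## matrix of sub-indices -> flat index
nodeFlat <- function(grid, sub) {
  dims <- gridDim(grid)
  stride <- cumprod(c(1L, dims[-length(dims)]))
  as.integer(1 + (sub - 1L) %*% stride)
}

#' Coordinates of grid nodes
#'
#' @param grid an [EnergyGrid-class].
#' @param flat flat node indices (default all nodes).
#' @return numeric matrix, one row per node, one column per axis, in the
#'   grid's axis unit.
#' @export
nodeCoordinates <- function(grid, flat = seq_len(nNodes(grid))) {
  sub <- nodeSub(grid, flat)
  sp <- gridSpacing(grid)
  co <- sweep(sweep(sub - 1, 2, sp, "*"), 2, grid@axes$min, "+")
  colnames(co) <- grid@axes$name
  co
}

#' Nearest grid node to a point
#'
#' Snaps a point in CV space to the nearest grid node, by default skipping
#' masked nodes.
#'
#' @param grid an [EnergyGrid-class].
#' @param point numeric vector with one coordinate per axis.
#' @param unmaskedOnly if TRUE (default) only unmasked nodes are candidates.
#' @return flat node index.
#' @export
nearestNode <- function(grid, point, unmaskedOnly = TRUE) {
  if (length(point) != nrow(grid@axes))
    stop("point must have one coordinate per grid axis")
  co <- nodeCoordinates(grid)
  d2 <- rowSums(sweep(co, 2, point)^2)
  if (unmaskedOnly) d2[as.vector(grid@mask)] <- Inf
  if (all(!is.finite(d2))) stop("all grid nodes are masked")
  which.min(d2)
}

## Neighbourhood offsets: "moore" = all 3^d - 1 adjacent nodes (diagonals
## included), "axis" = the 2d axis-aligned neighbours.
connectivityOffsets <- function(d, connectivity = c("moore", "axis")) {
  connectivity <- match.arg(connectivity)
  if (connectivity == "moore") {
    off <- as.matrix(expand.grid(rep(list(-1L:1L), d)))
    off <- off[rowSums(off != 0L) > 0L, , drop = FALSE]
  } else {
    off <- matrix(0L, 2L * d, d)
    for (k in seq_len(d)) {
      off[2L * k - 1L, k] <- -1L
      off[2L * k, k] <- 1L
    }
  }
  dimnames(off) <- NULL
  off
}

## Precomputed neighbour table: for each offset, the flat index of every
## node's neighbour (NA outside the grid), plus the Euclidean edge length.
## Masked nodes keep entries here; callers exclude them.
neighborTable <- function(grid, connectivity = "moore") {
  dims <- gridDim(grid)
  d <- length(dims)
  off <- connectivityOffsets(d, connectivity)
  sp <- gridSpacing(grid)
  per <- grid@axes$periodic
  V <- prod(dims)
  sub <- arrayInd(seq_len(V), dims)
  stride <- cumprod(c(1L, dims[-d]))
  nbr <- vector("list", nrow(off))
  len <- sqrt(rowSums(sweep(off, 2, sp, "*")^2))
  for (k in seq_len(nrow(off))) {
    ns <- sub
    ok <- rep(TRUE, V)
    for (j in seq_len(d)) {
      v <- ns[, j] + off[k, j]
      if (per[j]) {
        v <- ((v - 1L) %% dims[j]) + 1L
      } else {
        ok <- ok & v >= 1L & v <= dims[j]
      }
      ns[, j] <- v
    }
    fl <- as.integer(1 + (ns - 1L) %*% stride)
    fl[!ok] <- NA_integer_
    nbr[[k]] <- fl
  }
  list(offsets = off, nbr = nbr, len = len)
}
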