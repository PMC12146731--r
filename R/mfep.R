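## Minimum free energy path (minimum resistance path) search on gridded
## free-energy surfaces.
##
## The resistance of a path is the discretised integral of exp(E/RT) along
## it: each grid edge (u, v) contributes the trapezoidal average
## 0.5*(exp(E_u/RT) + exp(E_v/RT)) times the Euclidean edge length. All
## internal bookkeeping is done with log-resistances accumulated by
## log-sum-exp, so that low temperatures (where exp(E/RT) overflows double
## precision) are handled exactly; in that limit the minimum-resistance
## path converges to the minimax (lowest-barrier) path.
##
## The search follows a basin coarse-graining scheme: (1) each node points
## to its lowest-energy neighbour (successor), (2) nodes that are their own
## successor are fixed points (local minima) whose successor chains define
## attraction basins, (3) basins sharing adjacent nodes define a
## coarse-grained (CG) state network, (4) a full-grid Dijkstra search gives
## the minimum-resistance path between the fixed points of every pair of
## adjacent basins, and (5) a Dijkstra search on the CG network with those
## segment resistances as edge weights selects the chain of basins, whose
## segments are spliced into the final grid path.

## ---------------------------------------------------------------------------
## binary heap keyed by (cost, node index) for deterministic tie-breaking
## ---------------------------------------------------------------------------

newHeap <- function(capacity = 1024L) {
  env <- new.env(parent = emptyenv())
  env$keys <- numeric(capacity)
  env$vals <- integer(capacity)
  env$n <- 0L
  env
}

heapLess <- function(h, i, j) {
  ki <- h$keys[i]; kj <- h$keys[j]
  ki < kj || (ki == kj && h$vals[i] < h$vals[j])
}

heapPush <- function(h, key, val) {
  n <- h$n + 1L
  if (n > length(h$keys)) {
    h$keys <- c(h$keys, numeric(length(h$keys)))
    h$vals <- c(h$vals, integer(length(h$vals)))
  }
  h$keys[n] <- key; h$vals[n] <- val; h$n <- n
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (heapLess(h, i, p)) {
      tk <- h$keys[i]; h$keys[i] <- h$keys[p]; h$keys[p] <- tk
      tv <- h$vals[i]; h$vals[i] <- h$vals[p]; h$vals[p] <- tv
      i <- p
    } else break
  }
}

heapPop <- function(h) {
  if (h$n == 0L) return(NULL)
  out <- c(h$keys[1L], h$vals[1L])
  h$keys[1L] <- h$keys[h$n]; h$vals[1L] <- h$vals[h$n]
  h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L; m <- i
    if (l <= h$n && heapLess(h, l, m)) m <- l
    if (r <= h$n && heapLess(h, r, m)) m <- r
    if (m == i) break
    tk <- h$keys[i]; h$keys[i] <- h$keys[m]; h$keys[m] <- tk
    tv <- h$vals[i]; h$vals[i] <- h$vals[m]; h$vals[m] <- tv
    i <- m
  }
  out
}

## ---------------------------------------------------------------------------
## successor map and basin decomposition (algorithm steps 1-3)
## ---------------------------------------------------------------------------

#' Successor map of a free-energy grid
#'
#' For every unmasked node, the flat index of the lowest-energy node among
#' the node itself and its unmasked neighbours; ties are broken by the
#' smallest flat index. Nodes that are their own successor are fixed points
#' (local minima, including flat-plateau nodes without a strictly lower
#' neighbour).
#'
#' @param grid an [EnergyGrid-class].
#' @param connectivity `"moore"` (all `3^d - 1` adjacent nodes, default) or
#'   `"axis"` (axis-aligned neighbours only).
#' @return integer vector of successor flat indices, NA at masked nodes.
#' @export
buildSuccessorMap <- function(grid, connectivity = "moore") {
  maskVec <- as.vector(grid@mask)
  if (all(maskVec)) stop("empty domain: all grid nodes are masked")
  vals <- as.vector(grid@values)
  V <- length(vals)
  nt <- neighborTable(grid, connectivity)
  bestE <- vals
  bestI <- seq_len(V)
  for (k in seq_along(nt$nbr)) {
    cand <- nt$nbr[[k]]
    ok <- !is.na(cand)
    ok[ok] <- !maskVec[cand[ok]]
    if (!any(ok)) next
    cE <- rep(Inf, V)
    cE[ok] <- vals[cand[ok]]
    better <- cE < bestE | (cE == bestE & ok & cand < bestI)
    better[is.na(better)] <- FALSE
    bestE[better] <- cE[better]
    bestI[better] <- cand[better]
  }
  bestI[maskVec] <- NA_integer_
  bestI
}

#' Basin decomposition from a successor map
#'
#' Identifies fixed points (nodes that are their own successor), assigns
#' every unmasked node to the basin of the fixed point its successor chain
#' terminates at, and records which basins touch (share adjacent nodes),
#' forming the coarse-grained state network.
#'
#' @param grid an [EnergyGrid-class].
#' @param connectivity neighbourhood used for the successor map and basin
#'   adjacency.
#' @param smap optional precomputed successor map from
#'   [buildSuccessorMap()].
#' @return list with `fixedPoints` (flat indices), `basinLabel` (per-node
#'   fixed-point flat index, NA at masked nodes) and `cgAdjacency`
#'   (two-column matrix of adjacent basin label pairs).
#' @export
findFixedPoints <- function(grid, connectivity = "moore", smap = NULL) {
  if (is.null(smap)) smap <- buildSuccessorMap(grid, connectivity)
  V <- length(smap)
  lab <- smap
  repeat {
    nxt <- lab
    ok <- !is.na(lab)
    nxt[ok] <- lab[lab[ok]]
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  fixed <- which(!is.na(smap) & smap == seq_len(V))
  nt <- neighborTable(grid, connectivity)
  pairs <- NULL
  maskVec <- as.vector(grid@mask)
  for (k in seq_along(nt$nbr)) {
    v <- nt$nbr[[k]]
    ok <- !is.na(v) & !maskVec
    ok[ok] <- !maskVec[v[ok]]
    u <- which(ok)
    lu <- lab[u]; lv <- lab[v[u]]
    dif <- lu != lv
    if (any(dif))
      pairs <- rbind(pairs, cbind(pmin(lu[dif], lv[dif]),
                                  pmax(lu[dif], lv[dif])))
  }
  adj <- if (is.null(pairs)) matrix(integer(), 0, 2) else unique(pairs)
  colnames(adj) <- c("a", "b")
  list(fixedPoints = fixed, basinLabel = lab, cgAdjacency = adj)
}

## ---------------------------------------------------------------------------
## resistance costs
## ---------------------------------------------------------------------------

#' Resistance of a single grid edge
#'
#' Trapezoidal discretisation of the resistance integral over one edge:
#' `0.5 * (exp(E_u/RT) + exp(E_v/RT)) * |x_u - x_v|`.
#'
#' @param grid an [EnergyGrid-class].
#' @param u,v flat indices of two adjacent unmasked nodes.
#' @param temperature temperature in kelvin.
#' @param connectivity neighbourhood defining adjacency.
#' @return the (strictly positive) edge resistance; may overflow to `Inf`
#'   at very low temperatures -- the path search itself works in log space
#'   and is not affected.
#' @export
edgeResistance <- function(grid, u, v, temperature, connectivity = "moore") {
  maskVec <- as.vector(grid@mask)
  if (maskVec[u] || maskVec[v]) stop("edge endpoint is masked")
  su <- nodeSub(grid, u); sv <- nodeSub(grid, v)
  dims <- gridDim(grid)
  dsub <- sv - su
  per <- grid@axes$periodic
  for (j in seq_along(dims)) if (per[j]) {
    if (dsub[j] > dims[j] / 2) dsub[j] <- dsub[j] - dims[j]
    if (dsub[j] < -dims[j] / 2) dsub[j] <- dsub[j] + dims[j]
  }
  if (all(dsub == 0) || any(abs(dsub) > 1) ||
      (connectivity == "axis" && sum(dsub != 0) > 1))
    stop("nodes ", u, " and ", v, " are not adjacent under ", connectivity,
         " connectivity")
  rt <- thermalEnergy(temperature)
  len <- sqrt(sum((dsub * gridSpacing(grid))^2))
  vals <- as.vector(grid@values)
  0.5 * (exp(vals[u] / rt) + exp(vals[v] / rt)) * len
}

## log of the edge resistance, overflow-safe
edgeLogResistance <- function(eu, ev, len, rt) {
  logAddExp(eu / rt, ev / rt) + log(0.5 * len)
}

## Cumulative log-resistance along a node sequence (consecutive nodes must
## be grid neighbours). Returns the vector of cumulative log-costs
## (first entry -Inf = zero cost) and cumulative arc length.
pathAccumulate <- function(grid, nodes, temperature) {
  rt <- thermalEnergy(temperature)
  vals <- as.vector(grid@values)
  co <- nodeCoordinates(grid, nodes)
  n <- length(nodes)
  logc <- rep(-Inf, n)
  arc <- numeric(n)
  if (n > 1) {
    dco <- diff(co)
    ax <- grid@axes
    rng <- ax$max - ax$min + gridSpacing(grid) * ax$periodic
    for (j in seq_len(ncol(dco))) if (ax$periodic[j]) {
      w <- dco[, j]
      w[w > rng[j] / 2] <- w[w > rng[j] / 2] - rng[j]
      w[w < -rng[j] / 2] <- w[w < -rng[j] / 2] + rng[j]
      dco[, j] <- w
    }
    len <- sqrt(rowSums(dco^2))
    le <- edgeLogResistance(vals[nodes[-n]], vals[nodes[-1]], len, rt)
    for (i in seq_len(n - 1L)) logc[i + 1L] <- logAddExp(logc[i], le[i])
    arc <- c(0, cumsum(len))
  }
  list(logCost = logc, arclength = arc)
}

## ---------------------------------------------------------------------------
## full-grid Dijkstra (log-space)
## ---------------------------------------------------------------------------

## Dijkstra over unmasked nodes with log-resistance accumulation.
## Stops once all `targets` are settled (or explores everything if NULL).
dijkstraGrid <- function(grid, sources, temperature, targets = NULL,
                         connectivity = "moore", nt = NULL) {
  if (is.null(nt)) nt <- neighborTable(grid, connectivity)
  rt <- thermalEnergy(temperature)
  maskVec <- as.vector(grid@mask)
  vals <- as.vector(grid@values)
  logE <- vals / rt
  V <- length(vals)
  dist <- rep(Inf, V)
  prev <- rep(NA_integer_, V)
  settled <- logical(V)
  h <- newHeap()
  for (s in sources) {
    dist[s] <- -Inf
    heapPush(h, -Inf, s)
  }
  remaining <- if (is.null(targets)) -1L else length(unique(targets))
  targetSet <- logical(V)
  if (!is.null(targets)) targetSet[targets] <- TRUE
  logHalfLen <- log(0.5 * nt$len)
  while (h$n > 0L) {
    top <- heapPop(h)
    u <- as.integer(top[2])
    if (settled[u]) next
    settled[u] <- TRUE
    if (targetSet[u]) {
      remaining <- remaining - 1L
      if (remaining == 0L) break
    }
    du <- dist[u]
    for (k in seq_along(nt$nbr)) {
      v <- nt$nbr[[k]][u]
      if (is.na(v) || maskVec[v] || settled[v]) next
      nd <- logAddExp(du, logAddExp(logE[u], logE[v]) + logHalfLen[k])
      if (nd < dist[v] || (nd == dist[v] && !is.na(prev[v]) && u < prev[v])) {
        dist[v] <- nd
        prev[v] <- u
        heapPush(h, nd, v)
      }
    }
  }
  list(dist = dist, prev = prev, settled = settled)
}

tracePath <- function(prev, from, to) {
  path <- to
  while (path[1L] != from) {
    p <- prev[path[1L]]
    if (is.na(p)) return(NULL)
    path <- c(p, path)
  }
  path
}

gridPathFrame <- function(grid, nodes, temperature) {
  acc <- pathAccumulate(grid, nodes, temperature)
  co <- nodeCoordinates(grid, nodes)
  df <- data.frame(node = nodes, co,
                   energy = as.vector(grid@values)[nodes],
                   arclength = acc$arclength, logCost = acc$logCost)
  rownames(df) <- NULL
  df
}

#' Minimum-resistance path between two grid nodes
#'
#' Full-grid Dijkstra search minimising the total resistance
#' `sum 0.5*(exp(E_u/RT)+exp(E_v/RT))*len` over all grid paths between two
#' unmasked nodes. This is the exhaustive (non-coarse-grained) search that
#' the basin algorithm in [mfep()] is checked against.
#'
#' @param grid an [EnergyGrid-class].
#' @param a,b flat node indices (unmasked).
#' @param temperature temperature in kelvin.
#' @param connectivity neighbourhood spec, see [buildSuccessorMap()].
#' @return list with `path` (data.frame: node, coordinates, energy,
#'   cumulative arc length, cumulative log-resistance), `logCost` and
#'   `cost` (= `exp(logCost)`, may overflow to Inf at low temperature).
#' @export
shortestResistancePath <- function(grid, a, b, temperature,
                                   connectivity = "moore") {
  maskVec <- as.vector(grid@mask)
  if (maskVec[a] || maskVec[b]) stop("endpoint node is masked")
  if (a == b) {
    df <- gridPathFrame(grid, a, temperature)
    return(list(path = df, logCost = -Inf, cost = 0))
  }
  res <- dijkstraGrid(grid, a, temperature, targets = b,
                      connectivity = connectivity)
  if (!is.finite(res$dist[b]) && res$dist[b] > 0)
    stop("no path: nodes ", a, " and ", b,
         " lie in different unmasked connected components")
  nodes <- tracePath(res$prev, a, b)
  df <- gridPathFrame(grid, nodes, temperature)
  lc <- df$logCost[nrow(df)]
  list(path = df, logCost = lc, cost = exp(lc))
}

## ---------------------------------------------------------------------------
## the five-step coarse-grained MFEP (steps 1-5)
## ---------------------------------------------------------------------------

#' Minimum free energy path between two points
#'
#' Basin coarse-grained minimum-resistance path search: endpoints are
#' snapped to the nearest unmasked nodes and replaced by the fixed points
#' (local minima) of their attraction basins; minimum-resistance segments
#' between fixed points of adjacent basins are computed by full-grid
#' Dijkstra searches; a shortest-path search on the coarse-grained basin
#' network (with segment resistances as edge weights) selects the chain of
#' basins; and the segments are spliced into a single grid path from the
#' start basin's fixed point to the end basin's fixed point.
#'
#' @param grid an [EnergyGrid-class].
#' @param start,end CV-space points (numeric vectors, one coordinate per
#'   axis) or single flat node indices.
#' @param temperature temperature in kelvin.
#' @param connectivity neighbourhood spec, see [buildSuccessorMap()].
#' @param includeEndpoints if TRUE, prepend/append the steepest-descent
#'   segments from the snapped query nodes to their basin fixed points; by
#'   default the reported path runs fixed-point to fixed-point.
#' @param verify if TRUE, additionally run the exhaustive full-grid search
#'   between the terminal fixed points and record the log-cost difference
#'   (`cgDiscrepancy` attribute of the result's path). On smooth surfaces
#'   the coarse-grained result is exact and the discrepancy is 0; on rough
#'   surfaces, where the optimal path may clip a basin without visiting
#'   its minimum, the coarse-grained cost can exceed the exhaustive one,
#'   and this option reports it instead of hiding it.
#' @return an [MfepResult-class].
#' @examples
#' toy <- toyLandscape("double_well_2d")
#' res <- mfep(toy$grid, c(-1, 0), c(1, 0), temperature = 300)
#' mfepBarrier(res)
#' @export
mfep <- function(grid, start, end, temperature, connectivity = "moore",
                 includeEndpoints = FALSE, verify = FALSE) {
  d <- nrow(grid@axes)
  asNode <- function(p) {
    if (length(p) == 1L && d != 1L) as.integer(p)
    else nearestNode(grid, p)
  }
  sNode <- asNode(start)
  eNode <- asNode(end)
  maskVec <- as.vector(grid@mask)
  if (maskVec[sNode] || maskVec[eNode])
    stop("start/end map to masked nodes")
  smap <- buildSuccessorMap(grid, connectivity)
  basins <- findFixedPoints(grid, connectivity, smap = smap)
  lab <- basins$basinLabel
  fpS <- lab[sNode]
  fpE <- lab[eNode]

  descentChain <- function(from) {
    chain <- from
    while (smap[chain[length(chain)]] != chain[length(chain)])
      chain <- c(chain, smap[chain[length(chain)]])
    chain
  }

  if (fpS == fpE) {
    nodes <- fpS
  } else {
    adj <- basins$cgAdjacency
    if (nrow(adj) == 0L)
      stop("no path: start and end basins are not connected")
    fps <- sort(unique(c(adj[, 1], adj[, 2], fpS, fpE)))
    nt <- neighborTable(grid, connectivity)
    ## step 4: full-grid minimum-resistance segments between the fixed
    ## points of every pair of adjacent basins (one multi-target Dijkstra
    ## per fixed point)
    segCost <- new.env(parent = emptyenv())
    segPath <- new.env(parent = emptyenv())
    adjList <- split(c(adj[, 2], adj[, 1]), c(adj[, 1], adj[, 2]))
    for (fp in fps) {
      tg <- adjList[[as.character(fp)]]
      if (is.null(tg)) next
      res <- dijkstraGrid(grid, fp, temperature, targets = tg,
                          connectivity = connectivity, nt = nt)
      for (t in tg) {
        key <- paste(fp, t)
        if (!is.finite(res$dist[t]) && res$dist[t] > 0) next
        assign(key, res$dist[t], envir = segCost)
        assign(key, tracePath(res$prev, fp, t), envir = segPath)
      }
    }
    ## step 5: Dijkstra on the CG-state network, accumulating segment
    ## resistances with log-sum-exp
    ids <- fps
    idx <- stats::setNames(seq_along(ids), ids)
    nB <- length(ids)
    distB <- rep(Inf, nB)
    prevB <- rep(NA_integer_, nB)
    setB <- logical(nB)
    h <- newHeap()
    distB[idx[as.character(fpS)]] <- -Inf
    heapPush(h, -Inf, idx[as.character(fpS)])
    while (h$n > 0L) {
      top <- heapPop(h)
      u <- as.integer(top[2])
      if (setB[u]) next
      setB[u] <- TRUE
      if (ids[u] == fpE) break
      tg <- adjList[[as.character(ids[u])]]
      if (is.null(tg)) next
      for (t in tg) {
        key <- paste(ids[u], t)
        if (!exists(key, envir = segCost)) next
        j <- idx[as.character(t)]
        if (setB[j]) next
        nd <- logAddExp(distB[u], get(key, envir = segCost))
        if (nd < distB[j]) {
          distB[j] <- nd
          prevB[j] <- u
          heapPush(h, nd, j)
        }
      }
    }
    jE <- idx[as.character(fpE)]
    if (!setB[jE] && !is.finite(distB[jE]) && distB[jE] > 0)
      stop("no path: start and end regions are mutually unreachable ",
           "(fixed points ", fpS, " and ", fpE, ")")
    chain <- jE
    while (chain[1L] != idx[as.character(fpS)])
      chain <- c(prevB[chain[1L]], chain)
    ## splice the per-segment grid paths
    nodes <- ids[chain[1L]]
    for (i in seq_len(length(chain) - 1L)) {
      seg <- get(paste(ids[chain[i]], ids[chain[i + 1L]]), envir = segPath)
      nodes <- c(nodes, seg[-1L])
    }
  }

  if (includeEndpoints) {
    pre <- descentChain(sNode)
    post <- rev(descentChain(eNode))
    nodes <- c(pre[-length(pre)], nodes, post[-1L])
  }

  df <- gridPathFrame(grid, nodes, temperature)
  if (verify) {
    full <- shortestResistancePath(grid, fpS, fpE, temperature, connectivity)
    cg <- pathAccumulate(grid, if (includeEndpoints)
      nodes[seq(match(fpS, nodes), length(nodes) + 1L -
                  match(fpE, rev(nodes)))] else nodes, temperature)
    attr(df, "cgDiscrepancy") <-
      cg$logCost[length(cg$logCost)] - full$logCost
  }
  prof <- pathProfile(grid, nodes)
  new("MfepResult", path = df, profile = prof,
      barrier = barrierHeight(prof, "start_min"),
      logCost = df$logCost[nrow(df)], basins = basins,
      temperature = temperature)
}

## ---------------------------------------------------------------------------
## profiles and barriers
## ---------------------------------------------------------------------------

#' Free-energy profile along a grid path
#'
#' @param grid an [EnergyGrid-class].
#' @param nodes flat node indices of the path (consecutive nodes must be
#'   grid neighbours), or the `path` data.frame of an [MfepResult-class].
#' @return data.frame with `s` (cumulative arc length normalised to [0, 1];
#'   0 for a single-node path) and `energy` (kJ/mol).
#' @export
pathProfile <- function(grid, nodes) {
  if (is.data.frame(nodes)) nodes <- nodes$node
  if (!length(nodes)) stop("empty path")
  acc <- pathAccumulate(grid, nodes, temperature = 300)
  arc <- acc$arclength
  s <- if (max(arc) > 0) arc / max(arc) else rep(0, length(arc))
  data.frame(s = s, energy = as.vector(grid@values)[nodes])
}

#' Pointwise mean and SD of aligned profiles
#'
#' Resamples each profile onto a common reaction-coordinate grid by linear
#' interpolation and returns the pointwise mean and population SD
#' (divide-by-n, matching an SD over snapshots of a fluctuating PMF).
#'
#' @param profiles list of >= 2 data.frames with columns `s` and `energy`.
#' @param n number of points of the common grid (default 101).
#' @return data.frame with `s`, `mean` and `sd`.
#' @export
profileStatistics <- function(profiles, n = 101L) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop("SD undefined: need at least 2 profiles")
  s <- seq(0, 1, length.out = n)
  m <- vapply(profiles, function(p)
    stats::approx(p$s, p$energy, xout = s, rule = 2)$y, numeric(n))
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))
  data.frame(s = s, mean = mu, sd = sdv)
}

#' Barrier height of a 1D free-energy profile
#'
#' @param profile data.frame with columns `s` and `energy` (as returned by
#'   [pathProfile()]), or an [MfepResult-class].
#' @param reference `"start_min"` (energy of the profile's first point, the
#'   start basin's fixed point) or `"global_min"` (profile minimum).
#' @return `max(energy) - energy[reference]`, always >= 0.
#' @export
barrierHeight <- function(profile, reference = c("start_min", "global_min")) {
  reference <- match.arg(reference)
  if (is(profile, "MfepResult")) profile <- profile@profile
  if (!nrow(profile)) stop("empty profile")
  ref <- switch(reference,
                start_min = profile$energy[1L],
                global_min = min(profile$energy))
  max(profile$energy) - ref
}
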