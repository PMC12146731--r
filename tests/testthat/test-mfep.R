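test_that("successor map points at the lowest-energy neighbour with index tie-break", {
  g <- energyGrid(gridAxes("x", 0, 2, 3), c(3, 1, 2))
  expect_equal(buildSuccessorMap(g), c(2L, 2L, 2L))
  ## strictly monotone ramp: every successor one step downhill, last fixed
  ramp <- energyGrid(gridAxes("x", 0, 4, 5), c(5, 4, 3, 2, 1))
  expect_equal(buildSuccessorMap(ramp), c(2L, 3L, 4L, 5L, 5L))
  ## flat plateau: tie-break by smallest flat index; first node is fixed
  flat <- energyGrid(gridAxes("x", 0, 2, 3), c(1, 1, 1))
  expect_equal(buildSuccessorMap(flat), c(1L, 1L, 2L))
  ## random grid: successor energy never above own energy, masked excluded
  set.seed(7)
  gr <- energyGrid(gridAxes(c("x", "y"), 0, 1, 20), rnorm(400))
  gr <- maskHighEnergy(gr, 1)
  sm <- buildSuccessorMap(gr)
  v <- as.vector(gridValues(gr)); m <- as.vector(gridMask(gr))
  expect_true(all(is.na(sm[m])))
  expect_true(all(v[sm[!m]] <= v[!m]))
  expect_true(all(!m[sm[!m]]))
  expect_error(buildSuccessorMap(maskHighEnergy(gr, -Inf)), "masked")
})

test_that("basin decomposition partitions the grid and terminates at fixed points", {
  ## single-well quadratic bowl: one fixed point at the minimum node
  toy <- toyLandscape("bowl_2d")
  b <- findFixedPoints(toy$grid)
  expect_length(b$fixedPoints, 1L)
  expect_equal(unname(nodeCoordinates(toy$grid, b$fixedPoints)[1, ]),
               c(0, 0))
  ## clean 1D double well: two fixed points, boundary in the middle
  g2 <- energyGrid(gridAxes("x", 0, 4, 5), c(0, 1, 2, 1, 0))
  b2 <- findFixedPoints(g2)
  expect_equal(b2$fixedPoints, c(1L, 5L))
  expect_equal(b2$cgAdjacency[, "a"], 1L, ignore_attr = TRUE)
  ## a mid-profile local minimum is its own fixed point
  g3 <- energyGrid(gridAxes("x", 0, 4, 5), c(0, 1, 0.5, 1, 0))
  expect_equal(findFixedPoints(g3)$fixedPoints, c(1L, 3L, 5L))
  ## random grids: basins partition all unmasked nodes and successor chains
  ## terminate at the labelled fixed point
  for (s in 1:3) {
    gr <- randomSmoothLandscape(n = 15, seed = s)
    sm <- buildSuccessorMap(gr)
    bb <- findFixedPoints(gr, smap = sm)
    expect_true(all(!is.na(bb$basinLabel)))
    expect_true(all(bb$basinLabel %in% bb$fixedPoints))
    expect_equal(sm[bb$fixedPoints], bb$fixedPoints)
    for (n0 in sample(length(sm), 10)) {
      u <- n0
      while (sm[u] != u) u <- sm[u]
      expect_identical(u, bb$basinLabel[n0])
    }
  }
})

test_that("edge resistance follows the trapezoidal exp(E/RT) discretisation", {
  rt <- thermalEnergy(300)
  g <- energyGrid(gridAxes(c("x", "y"), 0, 3, 4), rep(0, 16))
  expect_equal(edgeResistance(g, 1, 2, 300), 1.0)
  expect_equal(edgeResistance(g, 1, 6, 300), sqrt(2))   # diagonal
  g2 <- energyGrid(gridAxes("x", 0, 1, 2), rep(rt * log(2), 2))
  expect_equal(edgeResistance(g2, 1, 2, 300), 2.0)
  expect_error(edgeResistance(g, 1, 3, 300), "not adjacent")
  gm <- maskHighEnergy(energyGrid(gridAxes("x", 0, 1, 2), c(0, 9)), 5)
  expect_error(edgeResistance(gm, 1, 2, 300), "masked")
})

test_that("shortest resistance path matches exhaustive enumeration on tiny grids", {
  ## flat 1D grid: straight path, cost = 4 * spacing
  flat <- energyGrid(gridAxes("x", 0, 8, 5), rep(0, 5))
  r <- shortestResistancePath(flat, 1, 5, 300)
  expect_equal(r$path$node, 1:5)
  expect_equal(r$cost, 4 * 2)
  ## 4x4 grid with a ridge and a low corridor: equals brute-force
  ## enumeration over all simple paths, and the path avoids the ridge
  set.seed(3)
  vals <- matrix(c(0, 8, 8, 0,
                   0, 8, 8, 0,
                   0, 0, 0, 0,
                   2, 2, 2, 2), 4, 4, byrow = TRUE) + runif(16)
  g <- energyGrid(gridAxes(c("x", "y"), 0, 3, 4), vals)
  r2 <- shortestResistancePath(g, 1, 4, 300)
  expect_equal(r2$cost, enumMinResistance(g, 1, 4, 300), tolerance = 1e-12)
  ## symmetry of the cost
  r3 <- shortestResistancePath(g, 4, 1, 300)
  expect_equal(r3$logCost, r2$logCost, tolerance = 1e-12)
  ## random tiny grids vs the enumeration oracle
  for (s in 1:4) {
    set.seed(s)
    gg <- energyGrid(gridAxes(c("x", "y"), 0, 3, 4), rnorm(16, sd = 4))
    rr <- shortestResistancePath(gg, 1, 16, 310)
    expect_equal(rr$cost, enumMinResistance(gg, 1, 16, 310),
                 tolerance = 1e-10)
  }
  ## disconnected components raise a no-path error
  gd <- energyGrid(gridAxes("x", 0, 4, 5), c(0, 0, 50, 0, 0))
  gd <- maskHighEnergy(gd, 10)
  expect_error(shortestResistancePath(gd, 1, 5, 300), "no path")
})

test_that("mfep finds the analytic saddle of the double well", {
  toy <- toyLandscape("double_well_2d")
  res <- mfep(toy$grid, c(-1, 0), c(1, 0), temperature = 300, verify = TRUE)
  sp <- max(gridSpacing(toy$grid))
  expect_equal(mfepBarrier(res), toy$facts$saddle_energy, tolerance = sp)
  ## the path crosses near the (0,0) saddle
  top <- mfepPath(res)[which.max(mfepPath(res)$energy), ]
  expect_lt(abs(top$x), 2 * sp)
  expect_lt(abs(top$y), 2 * sp)
  ## coarse-grained cost equals the full-grid search
  expect_equal(attr(mfepPath(res), "cgDiscrepancy"), 0, tolerance = 1e-9)
  ## profile endpoints sit at the basin fixed points' energies
  prof <- mfepProfile(res)
  expect_equal(prof$energy[1], 0, tolerance = sp)
  expect_equal(prof$energy[nrow(prof)], 0, tolerance = sp)
  expect_equal(prof$s[c(1, nrow(prof))], c(0, 1))
})

test_that("single-basin queries pass through the minimum node", {
  toy <- toyLandscape("bowl_2d")
  res <- mfep(toy$grid, c(-1, 0), c(1, 0), temperature = 300,
              includeEndpoints = TRUE)
  minNode <- nearestNode(toy$grid, c(0, 0))
  expect_true(minNode %in% mfepPath(res)$node)
  ## fixed-point-to-fixed-point default collapses to the single minimum
  res0 <- mfep(toy$grid, c(-1, 0), c(1, 0), temperature = 300)
  expect_equal(mfepPath(res0)$node, minNode)
})

test_that("mfep is invariant to shifting all energies by a constant", {
  g <- randomSmoothLandscape(n = 20, seed = 13)
  b <- findFixedPoints(g)
  fps <- b$fixedPoints
  expect_gte(length(fps), 2)
  v <- as.vector(gridValues(g))
  a <- fps[which.min(v[fps])]; z <- fps[order(v[fps])[2]]
  r1 <- mfep(g, a, z, 310)
  gShift <- energyGrid(gridAxesOf(g), gridValues(g) + 7)
  r2 <- mfep(gShift, a, z, 310)
  expect_equal(mfepPath(r2)$node, mfepPath(r1)$node)
  ## cost rescales by exp(c/RT)
  expect_equal(mfepLogCost(r2) - mfepLogCost(r1), 7 / thermalEnergy(310),
               tolerance = 1e-9)
})

test_that("masked nodes never appear on a path and corridor routing works", {
  toy <- toyLandscape("corridor_2d")
  g <- maskHighEnergy(toy$grid, 30)
  res <- mfep(g, c(-1.8, 0), c(1.8, 0), temperature = 310,
              includeEndpoints = TRUE)
  expect_false(any(as.vector(gridMask(g))[mfepPath(res)$node]))
  ## the path uses the low corridor around y = corridor_y
  top <- mfepPath(res)[which.max(mfepPath(res)$energy), ]
  expect_lt(abs(top$y - toy$facts$corridor_y), 0.5)
})

test_that("at very low temperature the path max matches the minimax oracle", {
  g <- randomSmoothLandscape(n = 12, seed = 31)
  b <- findFixedPoints(g)
  fps <- b$fixedPoints
  expect_gte(length(fps), 2)
  v <- as.vector(gridValues(g))
  a <- fps[which.min(v[fps])]; z <- fps[order(v[fps])[2]]
  res <- mfep(g, a, z, temperature = 1)
  expect_equal(max(mfepPath(res)$energy), minimaxOracle(g, a, z),
               tolerance = 1e-9)
})

test_that("path profiles normalise arc length and copy grid energies", {
  g <- energyGrid(gridAxes("x", 0, 4, 5), c(0, 5, 2, 4, 1))
  p <- pathProfile(g, 1:5)
  expect_equal(p$s, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(p$energy, c(0, 5, 2, 4, 1))
  expect_equal(max(p$energy), max(as.vector(gridValues(g))[1:5]))
  expect_equal(pathProfile(g, 3L), data.frame(s = 0, energy = 2))
  expect_error(pathProfile(g, integer(0)), "empty")
})

test_that("profile statistics give the pointwise mean and population SD", {
  p1 <- data.frame(s = seq(0, 1, 0.25), energy = rep(0, 5))
  p2 <- data.frame(s = seq(0, 1, 0.25), energy = rep(2, 5))
  st <- profileStatistics(list(p1, p2), n = 11)
  expect_equal(st$mean, rep(1, 11))
  expect_equal(st$sd, rep(1, 11))      # population SD, divide by n
  st2 <- profileStatistics(list(p1, p1), n = 5)
  expect_equal(st2$sd, rep(0, 5))
  expect_error(profileStatistics(list(p1)), "2 profiles")
  ## random profiles against the brute-force formulas
  set.seed(9)
  ps <- lapply(1:4, function(i)
    data.frame(s = seq(0, 1, length.out = 21), energy = rnorm(21)))
  st3 <- profileStatistics(ps, n = 21)
  m <- sapply(ps, function(p) p$energy)
  expect_equal(st3$mean, rowMeans(m))
  expect_equal(st3$sd, apply(m, 1, function(r) sqrt(mean((r - mean(r))^2))))
})

test_that("barrier heights are max minus reference and never negative", {
  prof <- data.frame(s = c(0, 0.5, 1), energy = c(0, 5, 2))
  expect_equal(barrierHeight(prof, "start_min"), 5)
  expect_equal(barrierHeight(prof, "global_min"), 5)
  dec <- data.frame(s = c(0, 0.5, 1), energy = c(3, 2, 1))
  expect_equal(barrierHeight(dec, "start_min"), 0)
  expect_equal(barrierHeight(dec, "global_min"), 2)
  expect_error(barrierHeight(data.frame(s = numeric(), energy = numeric())),
               "empty")
})
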