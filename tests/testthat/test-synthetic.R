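test_that("toy landscapes match their embedded analytic facts", {
  bowl <- toyLandscape("bowl_2d")
  v <- as.vector(gridValues(bowl$grid))
  expect_equal(unname(nodeCoordinates(bowl$grid, which.min(v))[1, ]),
               bowl$facts$minimum)
  dw <- toyLandscape("double_well_2d")
  vd <- as.vector(gridValues(dw$grid))
  expect_equal(min(vd), 0)
  saddleNode <- nearestNode(dw$grid, dw$facts$saddle)
  expect_equal(vd[saddleNode], dw$facts$saddle_energy,
               tolerance = max(gridSpacing(dw$grid)))
  ## the 3-CV knock-on surrogate has three basins visited in z-order
  ko <- toyLandscape("knockon_3d_surrogate")
  b <- findFixedPoints(ko$grid)
  expect_gte(length(b$fixedPoints), 3L)
  res <- mfep(ko$grid, ko$facts$basins[1, ], ko$facts$basins[3, ],
              temperature = 310, verify = TRUE)
  expect_equal(attr(mfepPath(res), "cgDiscrepancy"), 0, tolerance = 1e-9)
  z1 <- mfepPath(res)$z1
  expect_true(all(diff(range(z1)) > 0) && z1[1] < z1[length(z1)])
  expect_error(toyLandscape("double_well_2d", spacing = 2), "spacing")
})

test_that("generators are bit-reproducible under a fixed seed", {
  g1 <- randomSmoothLandscape(seed = 5)
  g2 <- randomSmoothLandscape(seed = 5)
  expect_identical(gridValues(g1), gridValues(g2))
  s1 <- simulateKnockonKmc(knockOnModel(10, 20, 5), 5, seed = 9)
  s2 <- simulateKnockonKmc(knockOnModel(10, 20, 5), 5, seed = 9)
  expect_identical(stateLabels(s1$states), stateLabels(s2$states))
  expect_identical(s1$events, s2$events)
  cfg <- langevinConfig(nIons = 2, nSteps = 500, seed = 4)
  expect_identical(trajZ(simulateMultiIonLangevin(cfg)),
                   trajZ(simulateMultiIonLangevin(cfg)))
})

test_that("kMC cycle statistics match analytic cycle kinetics", {
  ## symmetric two-state reduction: equal occupancies within 3 SE
  simSym <- simulateKnockonKmc(knockOnModel(8, 1e6, 8), duration = 50,
                               dt = 1, seed = 2)
  occ <- occupancyProbabilities(simSym$states)
  n <- length(simSym$events)
  expect_lt(abs(occ[["1"]] - 0.5), 3 * sqrt(0.25 / n))
  ## irreversible (10, 20, 5) cycle: stationary occupancies ~ 1/k and the
  ## event rate is the harmonic cycle rate
  sim <- simulateKnockonKmc(knockOnModel(10, 20, 5), duration = 200,
                            dt = 2, seed = 3)
  pi0 <- c(1 / 10, 1 / 20, 1 / 5) / 0.35
  occ2 <- occupancyProbabilities(sim$states)
  nev <- length(sim$events)
  for (i in 1:3)
    expect_lt(abs(occ2[[i]] - pi0[i]), 3 * sqrt(pi0[i] * (1 - pi0[i]) / nev))
  cycleRate <- 1 / 0.35
  expect_lt(abs(nev / 200 - cycleRate), 3 * sqrt(nev) / 200)
  ## zero duration gives empty outputs
  sim0 <- simulateKnockonKmc(knockOnModel(10, 20, 5), duration = 0, seed = 1)
  expect_length(sim0$events, 0L)
  expect_length(stateLabels(sim0$states), 0L)
  ## absorbing state flagged
  expect_warning(simulateKnockonKmc(list(entry = 5, translocation = 0,
                                         exit = 0, rEntry = 0,
                                         rTranslocation = 0, rExit = 0),
                                    duration = 10, seed = 1), "absorbing")
  expect_error(knockOnModel(10, 0, 5), "cycle direction")
})

test_that("Langevin integrator obeys free diffusion and equipartition", {
  ## 200 independent ions, flat potential, no field: ensemble variance of
  ## the displacement is 2 D t within 3 SE
  cfg <- langevinConfig(nIons = 200, U = function(z) 0 * z,
                        dU = function(z) 0 * z, repulsionA = 0, efield = 0,
                        friction = 20, dt = 0.05, boxZ = 2000, nSteps = 2000,
                        saveStride = 2000, seed = 17)
  traj <- simulateMultiIonLangevin(cfg, wrap = FALSE)
  z0 <- seq(-1000 + 2000 / 400, 1000 - 2000 / 400, length.out = 200)
  disp <- trajZ(traj)[1, ] - z0
  tTot <- 2000 * 0.05
  D <- thermalEnergy(310) / 20
  v <- var(disp)
  expect_lt(abs(mean(disp)), 3 * sqrt(v / 200))
  expect_lt(abs(v - 2 * D * tTot), 3 * sqrt(2 / 199) * 2 * D * tTot)
  ## harmonic well: stationary variance RT/k within 3 SE
  k <- 2
  cfgh <- langevinConfig(nIons = 1, U = function(z) 0.5 * k * z^2,
                         dU = function(z) k * z, repulsionA = 0, efield = 0,
                         friction = 10, dt = 0.05, boxZ = 100,
                         nSteps = 200000, saveStride = 10, seed = 18)
  zh <- trajZ(simulateMultiIonLangevin(cfgh, wrap = FALSE))[, 1]
  tau <- 10 / k                      # relaxation time, ps
  nEff <- length(zh) * 0.5 / tau     # frames are 0.5 ps apart
  vh <- var(zh)
  expect_lt(abs(vh - thermalEnergy(310) / k),
            3 * sqrt(2 / nEff) * thermalEnergy(310) / k)
  ## unstable time step is rejected up front
  expect_error(langevinConfig(dt = 10, friction = 1, seed = 1), "0.5 A")
})

test_that("single-file ions with strong repulsion keep their z-order", {
  cfg <- langevinConfig(nIons = 2, U = function(z) 0.02 * z^2,
                        dU = function(z) 0.04 * z, repulsionA = 2000,
                        screeningLambda = 4, efield = 0, friction = 20,
                        dt = 0.05, boxZ = 400, nSteps = 50000,
                        saveStride = 5, seed = 19)
  z <- trajZ(simulateMultiIonLangevin(cfg, wrap = FALSE))
  expect_true(all(z[, 2] > z[, 1]))
})

test_that("field-driven ions permeate and conductance grows with the field", {
  Uw <- function(z) 6 * cos(2 * pi * z / 10)
  dUw <- function(z) -1.2 * pi * sin(2 * pi * z / 10)
  run <- function(E) {
    cfg <- langevinConfig(nIons = 3, U = Uw, dU = dUw, efield = E,
                          friction = 20, dt = 0.05, boxZ = 40,
                          nSteps = 150000, saveStride = 20, seed = 23)
    traj <- simulateMultiIonLangevin(cfg)
    sum(countPermeationEvents(traj, 8, -8)$direction)
  }
  n1 <- run(0.05); n2 <- run(0.12)
  expect_gt(n1, 0)
  expect_gt(n2, n1)
})

test_that("well-tempered toy sampler reconstructs known 1D surfaces", {
  ## flat potential: reconstruction flat to within ~1 kJ/mol RMS
  flat <- wtMetadynamics1d(function(x) 0 * x,
                           metadConfig(totalTime = 6000,
                                       domain = c(-0.45, 0.45), seed = 5),
                           grad = function(x) 0 * x)
  expect_lt(sd(gridValues(flat$fes)), 1)
  ## double well, barrier 10 kJ/mol: recovered within 1.5 kJ/mol
  U <- function(x) 10 * ((x / 0.2)^2 - 1)^2
  dU <- function(x) 40 * ((x / 0.2)^2 - 1) * x / 0.04
  res <- wtMetadynamics1d(U, metadConfig(totalTime = 10000,
                                         domain = c(-0.45, 0.45), seed = 11),
                          grad = dU)
  expect_equal(metadBarrier(res$fes, 0.2), 10, tolerance = 0.15)
  expect_gt(nrow(res$hills), 9000)
  ## hill heights decay under well-tempering
  expect_lt(mean(tail(res$hills$height, 100)),
            mean(head(res$hills$height, 100)))
  ## reconstruction error decreases with simulation time (3 checkpoints)
  errs <- sapply(c(1500, 4000, 10000), function(tt) {
    r <- wtMetadynamics1d(U, metadConfig(totalTime = tt,
                                         domain = c(-0.45, 0.45), seed = 11),
                          grad = dU)
    abs(metadBarrier(r$fes, 0.2) - 10)
  })
  expect_true(all(diff(errs) < 0))
  ## zero total time: empty-bias FES is identically zero
  r0 <- wtMetadynamics1d(U, metadConfig(totalTime = 0, seed = 1))
  expect_equal(as.vector(gridValues(r0$fes)), rep(0, 201))
  expect_error(metadConfig(biasFactor = 1, seed = 1), "bias factor")
})

test_that("coordination fixtures agree with their emitted ground truth", {
  oct <- syntheticCoordinationFrames(octahedralLayout(2.4), nFrames = 25,
                                     noise = 0.35, seed = 6)
  cp <- coordinationProfile(oct$frames, cutoff = 3, binWidth = 100)
  truth <- oct$truth[oct$truth$kind == "ox_carboxylate", ]
  expect_equal(sum(cp$byClass$mean_count * cp$byClass$n_obs),
               sum(truth$count))
  ## zero noise: exactly six coordinating oxygens every frame
  oct0 <- syntheticCoordinationFrames(octahedralLayout(2.4), nFrames = 3,
                                      noise = 0, seed = 1)
  expect_true(all(oct0$truth$count == 6))
  ## an oxygen at exactly the cutoff distance is counted (closed cutoff)
  edge <- syntheticCoordinationFrames(octahedralLayout(3.0), nFrames = 1,
                                      noise = 0, seed = 1)
  expect_true(all(edge$truth$count == 6))
})
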