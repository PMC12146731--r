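test_that("z-density conserves the time-averaged ion count", {
  ## one ion fixed at z=0: a single occupied bin with value 1
  traj1 <- ionTrajectory(1:20, matrix(0, 20, 1), boxZ = 40)
  d1 <- zDensity(traj1, binWidth = 1, region = c(-5, 5))
  expect_equal(sum(d1$count), 1)
  expect_equal(d1$count[d1$zlo <= 0 & d1$zhi > 0], 1)
  ## two fixed ions: profile sums to 2
  traj2 <- ionTrajectory(1:20, cbind(rep(-2.8, 20), rep(1.7, 20)), boxZ = 40)
  d2 <- zDensity(traj2, binWidth = 0.2, region = c(-5, 5))
  expect_equal(sum(d2$count), 2)
  ## random-walk positions: mass equals the mean in-region count
  set.seed(8)
  z <- matrix(runif(300, -8, 8), 100, 3)
  d3 <- zDensity(z, binWidth = 0.5, region = c(-5, 5))
  expect_equal(sum(d3$count), mean(rowSums(z >= -5 & z <= 5)))
  expect_error(zDensity(traj1, binWidth = 0), "binWidth")
  expect_error(zDensity(traj1, region = c(5, -5)), "empty region")
})

test_that("Boltzmann sampling reproduces the generating potential's density", {
  ## Langevin ions in a harmonic well: z-histogram matches the Gaussian
  ## Boltzmann weight within sampling error
  k <- 1
  cfg <- langevinConfig(nIons = 1, U = function(z) 0.5 * k * z^2,
                        dU = function(z) k * z, repulsionA = 0, efield = 0,
                        friction = 10, dt = 0.05, boxZ = 60,
                        nSteps = 200000, saveStride = 5, seed = 21)
  traj <- simulateMultiIonLangevin(cfg, wrap = FALSE)
  d <- zDensity(traj, binWidth = 1, region = c(-6, 6))
  sigma2 <- thermalEnergy(310) / k
  expected <- pnorm(d$zhi / sqrt(sigma2)) - pnorm(d$zlo / sqrt(sigma2))
  expect_gt(cor(d$count, expected), 0.98)
  expect_equal(sum(d$count), sum(expected), tolerance = 0.05)
})

test_that("binding-site detection ranks density peaks with prominence/separation", {
  z <- seq(-6, 6, 0.2)
  ## two Gaussians at the printed two-ion binding sites -2.8 and 1.7 A
  y <- 1.0 * exp(-(z + 2.8)^2 / 0.3) + 0.7 * exp(-(z - 1.7)^2 / 0.3)
  prof <- data.frame(zmid = z, count = y)
  pk <- detectBindingSites(prof, minProminence = 0.1, minSeparation = 1)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$z, c(-2.8, 1.7), tolerance = 0.11)
  expect_gt(pk$height[1], pk$height[2])
  ## single Gaussian: one peak at its mode bin
  y1 <- exp(-(z - 0.5)^2 / 0.5)
  pk1 <- detectBindingSites(data.frame(zmid = z, count = y1))
  expect_lt(abs(pk1$z[1] - 0.5), 0.11)   # mode between two grid points
  ## flat profile: no peaks
  expect_equal(nrow(detectBindingSites(data.frame(zmid = z,
                                                  count = rep(1, length(z))))),
               0L)
})

test_that("coordination counting uses a closed 3 A cutoff and matches brute force", {
  mk <- function(dists) {
    data.frame(frame = 1, atom_id = c("I", paste0("O", seq_along(dists))),
               kind = c("ion", rep("ox_carboxylate", length(dists))),
               residue_label = c("CA", rep("GLU", length(dists))),
               x = c(0, dists), y = 0, z = 0)
  }
  cp29 <- coordinationProfile(mk(2.9), cutoff = 3)
  expect_equal(cp29$byClass$mean_count, 1)
  cp31 <- coordinationProfile(mk(3.1), cutoff = 3)
  expect_equal(sum(cp31$byClass$mean_count), 0)
  cp30 <- coordinationProfile(mk(3.0), cutoff = 3)   # boundary is included
  expect_equal(cp30$byClass$mean_count, 1)
  ## octahedral fixture: six oxygens at 2.4 A
  oct <- syntheticCoordinationFrames(octahedralLayout(2.4), nFrames = 1,
                                     noise = 0, seed = 1)
  cp6 <- coordinationProfile(oct$frames, cutoff = 3)
  expect_equal(cp6$byClass$mean_count, 6)
  ## randomised fixture vs O(n^2) brute-force oracle
  set.seed(33)
  m <- 40
  fr <- data.frame(frame = rep(1:3, each = m + 1),
                   atom_id = rep(c("I", paste0("O", 1:m)), 3),
                   kind = rep(c("ion", rep(c("ox_carboxylate", "ox_carbonyl",
                                             "ox_water"), length.out = m)), 3),
                   residue_label = rep(c("CA", rep(c("GLU", "ASP"),
                                                   length.out = m)), 3),
                   x = runif(3 * (m + 1), -4, 4),
                   y = runif(3 * (m + 1), -4, 4),
                   z = runif(3 * (m + 1), -4, 4))
  cp <- coordinationProfile(fr, cutoff = 3, binWidth = 100)
  brute <- sapply(1:3, function(f) {
    sub <- fr[fr$frame == f, ]
    ion <- sub[sub$kind == "ion", ]
    ox <- sub[sub$kind != "ion", ]
    sum(sqrt((ox$x - ion$x)^2 + (ox$y - ion$y)^2 + (ox$z - ion$z)^2) <= 3)
  })
  expect_equal(sum(cp$byClass$mean_count * cp$byClass$n_obs), sum(brute))
  expect_error(coordinationProfile(fr[, -3], cutoff = 3), "schema")
})

test_that("state assignment follows the 1 / 2U / 2L definitions", {
  sites <- siteDefinition()
  s2uC <- mean(sites$s2u); s1uC <- mean(sites$s1u)
  s2lC <- mean(sites$s2l); s1lC <- mean(sites$s1l)
  out <- 8  # vestibule, outside the SF extent
  expect_equal(assignStates(c(s2uC, out, out)), "1")
  expect_equal(assignStates(c(s1uC, s2uC, out)), "2U")
  expect_equal(assignStates(c(s1lC, s2lC, out)), "2L")
  expect_equal(assignStates(c(s1uC, s2lC, out)), "other")
  expect_equal(assignStates(c(out, out, out)), "other")
  expect_equal(assignStates(c(s1uC, s2uC, s2lC)), "other")  # 3 in the SF
  ## permutation invariance in ion order
  expect_equal(assignStates(c(s2uC, s1uC, out)),
               assignStates(c(s1uC, s2uC, out)))
  ## matrix input labels every frame
  zmat <- rbind(c(s2uC, out), c(s1uC, s2uC), c(s1lC, s2lC))
  expect_equal(assignStates(zmat), c("1", "2U", "2L"))
})

test_that("occupancy probabilities are frame fractions that sum to one", {
  p <- occupancyProbabilities(stateSequence(c("1", "1", "2U", "2L"), 10))
  expect_equal(p[["1"]], 0.5)
  expect_equal(p[["2U"]], 0.25)
  expect_equal(p[["2L"]], 0.25)
  expect_equal(sum(p), 1)
  expect_equal(unname(occupancyProbabilities(stateSequence(rep("1", 5), 1))), 1)
})

test_that("transition rates are per-time estimates with Poisson errors", {
  ## [A, A, B], dt = 1 ps: one transition over 2 ps in A -> 0.5 ps^-1
  seqAB <- stateSequence(c("A", "A", "B"), dt = 1)
  tr <- transitionRates(seqAB)
  expect_equal(tr$rates["A", "B"], 0.5 * 1000)     # ns^-1
  expect_equal(tr$se["A", "B"], 0.5 * 1000)
  ## constant sequence: all defined rates zero
  trc <- transitionRates(stateSequence(rep("1", 10), 10))
  expect_true(all(trc$rates[!is.na(trc$rates)] == 0))
  ## never-visited origin state: NA row
  expect_true(all(is.na(trc$rates["1", "1"])))
  expect_error(transitionRates(stateSequence("1", 1)), "2 frames")
})

test_that("kMC occupancies and rates are recovered within 3 SE", {
  model <- knockOnModel(10, 20, 5)
  sim <- simulateKnockonKmc(model, duration = 50, dt = 1, seed = 14)
  tr <- transitionRates(sim$states)
  prog <- c("1" = 10, "2U" = 20, "2L" = 5)
  nxt <- c("1" = "2U", "2U" = "2L", "2L" = "1")
  for (s in names(prog)) {
    expect_lt(abs(tr$rates[s, nxt[s]] - prog[s]), 3 * tr$se[s, nxt[s]])
  }
  pi0 <- (1 / prog) / sum(1 / prog)
  nCycles <- length(sim$events)
  for (s in names(pi0)) {
    se <- sqrt(pi0[s] * (1 - pi0[s]) / nCycles)
    expect_lt(abs(tr$occupancy[[s]] - pi0[[s]]), 3 * se)
  }
})
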