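## Synthetic generators: toy energy landscapes with known optima, a 1D
## well-tempered metadynamics toy sampler, a kinetic Monte Carlo knock-on
## state simulator, a multi-ion overdamped Langevin integrator, and
## coordination-geometry fixtures. These produce every input the analysis
## pipeline needs without running molecular dynamics. All generators take
## an explicit seed; there is no hidden global RNG state.

## force on a unit charge per V/nm of field, in kJ/mol/angstrom
FIELD_FORCE <- 9.6485

#' Toy free-energy landscapes with known analytic structure
#'
#' Closed-form surfaces sampled onto an [EnergyGrid-class], with the
#' analytic facts (well positions, saddle energies) returned alongside so
#' tests can compare grid results against ground truth.
#'
#' Families:
#' * `bowl_2d`: single quadratic well at the origin.
#' * `double_well_2d`: `h*(x^2-1)^2 + 5*y^2`; wells at (+-1, 0) with E = 0,
#'   saddle at the origin with E = `h` (default 1 kJ/mol).
#' * `corridor_2d`: a high ridge crossed by one low-energy corridor.
#' * `triple_well_1d`: three Gaussian wells along x.
#' * `knockon_3d_surrogate`: three basins in a 3-CV box whose centres
#'   advance in z-order, mimicking the concerted motion of three ions.
#'
#' @param family landscape family name.
#' @param spacing grid spacing (same for all axes).
#' @param barrier saddle height `h` for `double_well_2d` (kJ/mol).
#' @return list with `grid` (an [EnergyGrid-class]) and `facts` (named
#'   list of analytic features).
#' @export
toyLandscape <- function(family = c("double_well_2d", "bowl_2d",
                                    "corridor_2d", "triple_well_1d",
                                    "knockon_3d_surrogate"),
                         spacing = NULL, barrier = 1) {
  family <- match.arg(family)
  sampleGrid <- function(axes, f) {
    pts <- lapply(seq_len(nrow(axes)), function(i)
      axes$min[i] + (0:(axes$n[i] - 1L)) *
        ((axes$max[i] - axes$min[i]) / (axes$n[i] - 1L)))
    co <- as.matrix(expand.grid(pts))
    energyGrid(axes, f(co))
  }
  nFor <- function(lo, hi, sp) {
    n <- round((hi - lo) / sp) + 1L
    if (n < 4L) stop("spacing larger than the landscape feature scale")
    n
  }
  switch(family,
    bowl_2d = {
      sp <- spacing %||% 0.05
      n <- nFor(-1.5, 1.5, sp)
      ax <- gridAxes(c("x", "y"), -1.5, 1.5, n)
      g <- sampleGrid(ax, function(co) 2 * (co[, 1]^2 + co[, 2]^2))
      list(grid = g, facts = list(minimum = c(0, 0), min_energy = 0))
    },
    double_well_2d = {
      sp <- spacing %||% 0.05
      n <- nFor(-1.5, 1.5, sp)
      ax <- gridAxes(c("x", "y"), -1.5, 1.5, n)
      g <- sampleGrid(ax, function(co)
        barrier * (co[, 1]^2 - 1)^2 + 5 * co[, 2]^2)
      list(grid = g,
           facts = list(wells = rbind(c(-1, 0), c(1, 0)), well_energy = 0,
                        saddle = c(0, 0), saddle_energy = barrier))
    },
    corridor_2d = {
      sp <- spacing %||% 0.1
      n <- nFor(-2, 2, sp)
      ax <- gridAxes(c("x", "y"), -2, 2, n)
      ridge <- 40; yc <- 1; w <- 0.3
      g <- sampleGrid(ax, function(co)
        ridge * exp(-co[, 1]^2 / 0.5) * (1 - exp(-(co[, 2] - yc)^2 / w^2)) +
          0.5 * (co[, 1]^2 + co[, 2]^2))
      list(grid = g, facts = list(corridor_y = yc, ridge = ridge))
    },
    triple_well_1d = {
      sp <- spacing %||% 0.02
      n <- nFor(-1.6, 1.6, sp)
      ax <- gridAxes("x", -1.6, 1.6, n)
      depths <- c(8, 12, 6)
      centers <- c(-1, 0, 1)
      g <- sampleGrid(ax, function(co) {
        u <- 4 * co[, 1]^2
        for (k in 1:3)
          u <- u - depths[k] * exp(-(co[, 1] - centers[k])^2 / (2 * 0.15^2))
        u - min(u)
      })
      list(grid = g, facts = list(wells = centers, depths = depths))
    },
    knockon_3d_surrogate = {
      sp <- spacing %||% 1
      n <- nFor(-5, 6, sp)
      ax <- gridAxes(c("z1", "z2", "z3"), -5, 6, n)
      centers <- rbind(c(-4, -1, 2), c(-2, 1, 4), c(0, 3, 5))
      g <- sampleGrid(ax, function(co) {
        u <- 0.15 * rowSums(sweep(co, 2, c(-2, 1, 3.5))^2)
        for (k in 1:3)
          u <- u - 25 * exp(-rowSums(sweep(co, 2, centers[k, ])^2) / (2 * 1.2^2))
        u - min(u)
      })
      list(grid = g, facts = list(basins = centers))
    })
}

#' Random smooth landscape
#'
#' Sum of random Gaussian features (positive and negative) on a confining
#' quadratic background -- a generic stand-in for smooth multi-basin free
#' energy surfaces. The default feature widths (0.2-0.4 of the domain
#' edge) keep the surface genuinely smooth: every feature spans several
#' grid cells and minimum-resistance paths funnel through basin minima,
#' the regime the basin coarse-graining of [mfep()] is exact in (see the
#' methods vignette). Reproducible from the seed.
#'
#' @param d dimensionality.
#' @param n grid points per axis.
#' @param nBumps number of Gaussian features.
#' @param amplitude maximum |feature| amplitude in kJ/mol.
#' @param widthRange range the feature widths are drawn from (fraction of
#'   the unit domain).
#' @param seed RNG seed (mandatory).
#' @return an [EnergyGrid-class] with min energy shifted to 0.
#' @export
randomSmoothLandscape <- function(d = 2, n = 30, nBumps = 5, amplitude = 25,
                                  widthRange = c(0.2, 0.4), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  ax <- gridAxes(paste0("x", seq_len(d)), 0, 1, n)
  pts <- lapply(seq_len(d), function(i) seq(0, 1, length.out = n))
  co <- as.matrix(expand.grid(pts))
  u <- 2 * amplitude * rowSums((co - 0.5)^2) / d
  for (k in seq_len(nBumps)) {
    ctr <- stats::runif(d)
    amp <- stats::runif(1, -amplitude, amplitude)
    w <- stats::runif(1, widthRange[1], widthRange[2])
    u <- u + amp * exp(-rowSums(sweep(co, 2, ctr)^2) / (2 * w^2))
  }
  energyGrid(ax, u - min(u))
}

#' Well-tempered metadynamics configuration
#'
#' Defaults follow common practice for a 1D CV in nm: Gaussian hills of 5
#' kJ/mol height and 0.02 nm width deposited every 1 ps, bias factor 5.
#'
#' @param height initial hill height omega (kJ/mol), > 0.
#' @param width hill width sigma (nm), > 0.
#' @param biasFactor well-tempered bias factor gamma, > 1.
#' @param stride deposition stride (ps).
#' @param temperature temperature (K).
#' @param totalTime total simulated time (ps).
#' @param dt integrator time step (ps).
#' @param friction Langevin friction (kJ ps / mol / nm^2).
#' @param domain CV domain c(lo, hi) in nm (reflecting walls).
#' @param nbins FES grid points.
#' @param seed RNG seed (mandatory).
#' @return validated config list for [wtMetadynamics1d()].
#' @export
metadConfig <- function(height = 5, width = 0.02, biasFactor = 5,
                        stride = 1, temperature = 310, totalTime = 10000,
                        dt = 0.01, friction = 2000, domain = c(-0.5, 0.5),
                        nbins = 201, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (height <= 0) stop("hill height must be > 0")
  if (width <= 0) stop("hill width must be > 0")
  if (biasFactor <= 1) stop("bias factor must be > 1")
  list(height = height, width = width, biasFactor = biasFactor,
       stride = stride, temperature = temperature, totalTime = totalTime,
       dt = dt, friction = friction, domain = domain, nbins = as.integer(nbins),
       seed = seed)
}

#' 1D well-tempered metadynamics toy sampler
#'
#' Overdamped Langevin walker on `potential` with well-tempered hill
#' deposition: every `stride` ps a Gaussian of height
#' `omega * exp(-V_bias(x)/((gamma-1) RT))` is added to the bias. The free
#' energy estimate is the well-tempered identity
#' `F_hat = -gamma/(gamma-1) * V_bias`, shifted to min 0.
#'
#' The returned surface is the time average of the min-shifted estimate
#' over the final part of the run (`averageFrom` onward), the usual way a
#' converged metadynamics PMF is reported; the final-snapshot estimate is
#' returned alongside.
#'
#' @param potential function U(x) in kJ/mol of the CV x (nm).
#' @param cfg configuration from [metadConfig()].
#' @param grad optional analytic gradient dU/dx; numeric differentiation
#'   otherwise.
#' @param averageFrom fraction of the run after which snapshots enter the
#'   time-averaged estimate (default 0.5).
#' @return list with `fes` (1D [EnergyGrid-class], unit nm; time-averaged
#'   estimate), `fesFinal` (final-snapshot estimate), `hills` (data.frame
#'   time, center, height) and `bias` (final bias on the grid).
#' @export
wtMetadynamics1d <- function(potential, cfg, grad = NULL,
                             averageFrom = 0.5) {
  rt <- thermalEnergy(cfg$temperature)
  gam <- cfg$biasFactor
  lo <- cfg$domain[1]; hi <- cfg$domain[2]
  nb <- cfg$nbins
  xs <- seq(lo, hi, length.out = nb)
  dx <- xs[2] - xs[1]
  if (is.null(grad)) {
    h <- 1e-5
    grad <- function(x) (potential(x + h) - potential(x - h)) / (2 * h)
  }
  vbias <- numeric(nb)
  dvbias <- numeric(nb)       # dV/dx on the grid, refreshed per hill
  biasGrad <- function(x) {
    i <- pmin(nb - 1L, pmax(1L, floor((x - lo) / dx) + 1L))
    w <- (x - xs[i]) / dx
    dvbias[i] * (1 - w) + dvbias[i + 1L] * w
  }
  biasAt <- function(x) {
    i <- pmin(nb - 1L, pmax(1L, floor((x - lo) / dx) + 1L))
    w <- (x - xs[i]) / dx
    vbias[i] * (1 - w) + vbias[i + 1L] * w
  }
  set.seed(cfg$seed)
  nSteps <- max(0L, round(cfg$totalTime / cfg$dt))
  perHill <- max(1L, round(cfg$stride / cfg$dt))
  mob <- cfg$dt / cfg$friction
  noiseSd <- sqrt(2 * rt * cfg$dt / cfg$friction)
  x <- (lo + hi) / 2
  hills <- list(time = numeric(0), center = numeric(0), height = numeric(0))
  nHills <- 0L
  fAcc <- numeric(nb)
  nAcc <- 0L
  if (nSteps > 0L) {
    xi <- stats::rnorm(nSteps)
    for (s in seq_len(nSteps)) {
      f <- -grad(x) - biasGrad(x)
      x <- x + f * mob + noiseSd * xi[s]
      ## reflecting walls
      if (x < lo) x <- 2 * lo - x
      if (x > hi) x <- 2 * hi - x
      if (s %% perHill == 0L) {
        w <- cfg$height * exp(-biasAt(x) / ((gam - 1) * rt))
        ## image hills across the reflecting walls keep the bias
        ## consistent with the walker's reflected density at the edges
        vbias <- vbias + w *
          (exp(-(xs - x)^2 / (2 * cfg$width^2)) +
           exp(-(xs - (2 * lo - x))^2 / (2 * cfg$width^2)) +
           exp(-(xs - (2 * hi - x))^2 / (2 * cfg$width^2)))
        dvbias <- c(0, diff(vbias)) / dx
        dvbias[1] <- dvbias[2]
        nHills <- nHills + 1L
        hills$time[nHills] <- s * cfg$dt
        hills$center[nHills] <- x
        hills$height[nHills] <- w
        if (s >= averageFrom * nSteps) {
          fh <- -gam / (gam - 1) * vbias
          fAcc <- fAcc + (fh - min(fh))
          nAcc <- nAcc + 1L
        }
      }
    }
  }
  fhat <- -gam / (gam - 1) * vbias
  fhat <- fhat - min(fhat)
  ax <- gridAxes("x", lo, hi, nb)
  favg <- if (nAcc > 0L) fAcc / nAcc else fhat
  favg <- favg - min(favg)
  list(fes = energyGrid(ax, favg, unit = "nm"),
       fesFinal = energyGrid(ax, fhat, unit = "nm"),
       hills = as.data.frame(hills), bias = vbias)
}

#' Kinetic Monte Carlo knock-on cycle model
#'
#' @param entry,translocation,exit forward rates (ns^-1) for the cycle
#'   1 -> 2U -> 2L -> 1; a permeation event is emitted on each completed
#'   2L -> 1 transition.
#' @param rEntry,rTranslocation,rExit reverse rates (ns^-1), default 0.
#' @return validated model list for [simulateKnockonKmc()].
#' @export
knockOnModel <- function(entry, translocation, exit,
                         rEntry = 0, rTranslocation = 0, rExit = 0) {
  r <- c(entry, translocation, exit, rEntry, rTranslocation, rExit)
  if (any(r < 0)) stop("rates must be >= 0")
  if (!all(r[1:3] > 0) && !all(r[4:6] > 0))
    stop("at least one cycle direction needs all three rates > 0")
  list(entry = entry, translocation = translocation, exit = exit,
       rEntry = rEntry, rTranslocation = rTranslocation, rExit = rExit)
}

#' Simulate the knock-on occupancy cycle by exact kinetic Monte Carlo
#'
#' Gillespie simulation of the three-state cycle 1 -> 2U -> 2L -> 1 (plus
#' optional reverse rates). The jump process is resampled onto a uniform
#' frame grid, mimicking MD frame saving, and every completed 2L -> 1
#' transition is recorded as a permeation event.
#'
#' @param model from [knockOnModel()].
#' @param duration simulated time in ns.
#' @param dt frame spacing in ps (default 10).
#' @param seed RNG seed (mandatory).
#' @return list with `states` (a [StateSequence-class]), `events`
#'   (permeation completion times, ns) and `jumps` (data.frame time, state).
#' @export
simulateKnockonKmc <- function(model, duration, dt = 10, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  states <- c("1", "2U", "2L")
  ## rate matrix (ns^-1), rows = from
  K <- matrix(0, 3, 3, dimnames = list(states, states))
  K["1", "2U"] <- model$entry;          K["2U", "1"] <- model$rEntry
  K["2U", "2L"] <- model$translocation; K["2L", "2U"] <- model$rTranslocation
  K["2L", "1"] <- model$exit;           K["1", "2L"] <- model$rExit
  t <- 0; s <- 1L
  jumpT <- numeric(0); jumpS <- integer(0)
  events <- numeric(0)
  if (duration > 0) repeat {
    out <- K[s, ]
    tot <- sum(out)
    if (tot == 0) {
      warning("absorbing state '", states[s], "' reached; simulation ended early")
      break
    }
    t <- t + stats::rexp(1, tot)
    if (t > duration) break
    nxt <- sample.int(3L, 1L, prob = out)
    if (states[s] == "2L" && states[nxt] == "1")
      events <- c(events, t)
    s <- nxt
    jumpT <- c(jumpT, t); jumpS <- c(jumpS, s)
  }
  frameT <- seq(0, duration, by = dt / 1000)
  if (duration <= 0) frameT <- numeric(0)
  lab <- states[c(1L, jumpS)][findInterval(frameT, c(0, jumpT))]
  list(states = stateSequence(lab, dt),
       events = events,
       jumps = data.frame(time = jumpT, state = states[jumpS]))
}

#' Multi-ion Langevin configuration
#'
#' Defaults model a few divalent cations in a 1D channel-like potential
#' under an applied field, with a screened-Coulomb pair repulsion strong
#' enough that two ions rarely co-occupy one well (an explicit surrogate
#' for full electrostatics).
#'
#' @param nIons number of ions.
#' @param charge per-ion charge (elementary charges).
#' @param U potential U(z) in kJ/mol, z in angstrom (vectorised).
#' @param dU optional analytic gradient.
#' @param repulsionA pair-repulsion amplitude (kJ/mol * A).
#' @param screeningLambda screening length (angstrom).
#' @param efield applied field E (V/nm), positive drives cations to -z.
#' @param friction Langevin friction (kJ ps / mol / A^2).
#' @param temperature temperature (K).
#' @param dt time step (ps); the per-step displacement SD must stay below
#'   0.5 A.
#' @param boxZ periodic box length along z (angstrom).
#' @param nSteps integration steps.
#' @param saveStride save every so many steps.
#' @param fEcc ECC factor recorded in the trajectory metadata.
#' @param seed RNG seed (mandatory).
#' @return validated config list for [simulateMultiIonLangevin()].
#' @export
langevinConfig <- function(nIons = 3, charge = 2, U = function(z) 0 * z,
                           dU = NULL, repulsionA = 500, screeningLambda = 3,
                           efield = 0.02, friction = 20, temperature = 310,
                           dt = 0.05, boxZ = 40, nSteps = 20000L,
                           saveStride = 10L, fEcc = 0.87, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (friction <= 0) stop("friction must be > 0")
  stepSd <- sqrt(2 * thermalEnergy(temperature) * dt / friction)
  if (stepSd >= 0.5)
    stop(sprintf("time step too large: single-step displacement SD %.3g A >= 0.5 A",
                 stepSd))
  list(nIons = as.integer(nIons), charge = charge, U = U, dU = dU,
       repulsionA = repulsionA, screeningLambda = screeningLambda,
       efield = efield, friction = friction, temperature = temperature,
       dt = dt, boxZ = boxZ, nSteps = as.integer(nSteps),
       saveStride = as.integer(saveStride), fEcc = fEcc, seed = seed)
}

#' Simulate single-file multi-ion dynamics by overdamped Langevin
#'
#' Euler-Maruyama integration of
#' `dz_i = (-U'(z_i) + qE + sum_j f_rep(z_i - z_j)) / gamma * dt
#'  + sqrt(2 RT dt / gamma) dW`,
#' with screened-Coulomb pair repulsion
#' `f_rep(d) = A * sign(d) * exp(-|d|/lambda) / d^2` and periodic re-entry
#' across the box. A positive field drives cations toward -z (the
#' physiological inward direction), so inward permeation events correspond
#' to downward two-plane crossings.
#'
#' @param cfg configuration from [langevinConfig()].
#' @param wrap wrap coordinates into the box (default TRUE); unwrapped
#'   coordinates are useful for diffusion diagnostics.
#' @return an [IonTrajectory-class].
#' @export
simulateMultiIonLangevin <- function(cfg, wrap = TRUE) {
  set.seed(cfg$seed)
  rt <- thermalEnergy(cfg$temperature)
  n <- cfg$nIons
  dU <- cfg$dU
  if (is.null(dU)) {
    h <- 1e-5
    dU <- function(z) (cfg$U(z + h) - cfg$U(z - h)) / (2 * h)
  }
  half <- cfg$boxZ / 2
  ## start ions spread out in the box
  z <- seq(-half + cfg$boxZ / (2 * n), half - cfg$boxZ / (2 * n),
           length.out = n)
  mob <- cfg$dt / cfg$friction
  noiseSd <- sqrt(2 * rt * cfg$dt / cfg$friction)
  fieldF <- -cfg$charge * cfg$efield * FIELD_FORCE
  nSave <- cfg$nSteps %/% cfg$saveStride
  zsave <- matrix(NA_real_, nSave, n)
  tsave <- numeric(nSave)
  isave <- 0L
  minImage <- function(d) d - cfg$boxZ * round(d / cfg$boxZ)
  for (s in seq_len(cfg$nSteps)) {
    f <- -dU(z) + fieldF
    if (n > 1 && cfg$repulsionA > 0) {
      for (i in seq_len(n)) {
        d <- minImage(z[i] - z[-i])
        ad <- pmax(abs(d), 0.1)
        f[i] <- f[i] + sum(cfg$repulsionA * sign(d) *
                             exp(-ad / cfg$screeningLambda) / ad^2)
      }
    }
    step <- f * mob + noiseSd * stats::rnorm(n)
    if (any(abs(step) > cfg$boxZ / 4))
      stop(sprintf("unstable time step: displacement %.3g A > boxZ/4 at step %d",
                   max(abs(step)), s))
    z <- z + step
    if (wrap) z <- ((z + half) %% cfg$boxZ) - half
    if (s %% cfg$saveStride == 0L) {
      isave <- isave + 1L
      zsave[isave, ] <- z
      tsave[isave] <- s * cfg$dt
    }
  }
  ionTrajectory(tsave, zsave, species = "CA", charge = cfg$charge,
                boxZ = cfg$boxZ, efield = cfg$efield, lz = cfg$boxZ / 10,
                fEcc = cfg$fEcc)
}

#' Octahedral coordination layout
#'
#' One ion at the origin with six carboxylate oxygens at distance `dist`
#' along the +-x, +-y, +-z axes.
#'
#' @param dist ion-oxygen distance (angstrom).
#' @return layout data.frame for [syntheticCoordinationFrames()].
#' @export
octahedralLayout <- function(dist = 2.4) {
  ox <- rbind(c(dist, 0, 0), c(-dist, 0, 0), c(0, dist, 0),
              c(0, -dist, 0), c(0, 0, dist), c(0, 0, -dist))
  data.frame(atom_id = c("ION1", paste0("O", 1:6)),
             kind = c("ion", rep("ox_carboxylate", 6)),
             residue_label = c("CA", rep("GLU", 6)),
             x = c(0, ox[, 1]), y = c(0, ox[, 2]), z = c(0, ox[, 3]),
             stringsAsFactors = FALSE)
}

#' Synthetic coordination-geometry frames
#'
#' Replicates a static layout over `nFrames` frames with i.i.d. Gaussian
#' positional noise, and emits the ground-truth per-frame coordination
#' counts (closed `<=` cutoff) computed directly from the noisy
#' coordinates.
#'
#' @param layout data.frame with columns `atom_id`, `kind`,
#'   `residue_label`, `x`, `y`, `z` (see [octahedralLayout()]).
#' @param nFrames number of frames.
#' @param noise positional noise SD (angstrom).
#' @param seed RNG seed (mandatory).
#' @param cutoff ground-truth coordination cutoff (angstrom, default 3).
#' @return list with `frames` (coordinate data.frame with a `frame`
#'   column) and `truth` (data.frame frame, ion, kind, count).
#' @export
syntheticCoordinationFrames <- function(layout, nFrames = 10, noise = 0.1,
                                        seed, cutoff = 3) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  out <- vector("list", nFrames)
  truth <- list()
  for (f in seq_len(nFrames)) {
    fr <- layout
    m <- nrow(fr)
    fr$x <- fr$x + stats::rnorm(m, 0, noise)
    fr$y <- fr$y + stats::rnorm(m, 0, noise)
    fr$z <- fr$z + stats::rnorm(m, 0, noise)
    fr <- cbind(frame = f, fr)
    out[[f]] <- fr
    ions <- fr[fr$kind == "ion", , drop = FALSE]
    oxy <- fr[startsWith(fr$kind, "ox_"), , drop = FALSE]
    for (i in seq_len(nrow(ions))) {
      dd <- sqrt((oxy$x - ions$x[i])^2 + (oxy$y - ions$y[i])^2 +
                   (oxy$z - ions$z[i])^2)
      for (k in unique(oxy$kind))
        truth[[length(truth) + 1L]] <- data.frame(
          frame = f, ion = ions$atom_id[i], kind = k,
          count = sum(dd <= cutoff & oxy$kind == k))
    }
  }
  list(frames = do.call(rbind, out), truth = do.call(rbind, truth))
}
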