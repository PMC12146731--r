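## Permeation event counting and ECC-corrected conductance.
##
## The conductance follows from counting net permeation events N over a
## trajectory of duration t under a nominal transmembrane voltage V = E*Lz:
##
##     g = I / V = (N * q * e / t) / (E * Lz) * 1 / f_ECC
##
## where q is the nominal integer ion charge (ECC scales charges only to
## model electronic screening; the transported charge stays the real one)
## and the 1/f_ECC factor accounts for the effective field E*f_ECC seen by
## the scaled charges.

#' Count permeation events in an ion trajectory
#'
#' Two-plane state machine with hysteresis: an inward event (direction +1,
#' along the applied field, i.e. decreasing z) completes when an ion last
#' seen above `zUpper` is next seen below `zLower`; a reverse crossing
#' counts with direction -1. An ion dithering around a single plane never
#' double-counts because completing an event requires full traversal of
#' both planes. Periodic-boundary jumps (|dz| > boxZ/2 between consecutive
#' frames) reset the ion's bookkeeping instead of counting as a crossing.
#'
#' @param traj an [IonTrajectory-class].
#' @param zUpper,zLower crossing planes in angstrom, `zUpper > zLower`,
#'   both inside the box.
#' @return data.frame with columns `ion`, `time` (ps, completion frame
#'   time) and `direction` (+1 inward / -1 reverse), one row per event.
#' @export
countPermeationEvents <- function(traj, zUpper, zLower) {
  if (!(zUpper > zLower)) stop("zUpper must be > zLower")
  half <- traj@boxZ / 2
  if (zUpper >= half || zLower <= -half)
    stop("crossing planes must lie inside the box (+-boxZ/2)")
  z <- traj@z
  times <- traj@times
  events <- list()
  zoneOf <- function(zz) ifelse(zz > zUpper, 1L, ifelse(zz < zLower, -1L, 0L))
  for (ion in seq_len(ncol(z))) {
    zi <- z[, ion]
    zone <- zoneOf(zi)
    wrap <- c(FALSE, abs(diff(zi)) > traj@boxZ / 2)
    ## origin: the last extreme zone (above/below) reached without a wrap
    origin <- 0L
    for (f in seq_along(zi)) {
      if (wrap[f]) {
        origin <- zone[f]          # reappearance, not a crossing
        next
      }
      if (zone[f] == 0L) next
      if (origin == 1L && zone[f] == -1L) {
        events[[length(events) + 1L]] <-
          data.frame(ion = ion, time = times[f], direction = 1L)
      } else if (origin == -1L && zone[f] == 1L) {
        events[[length(events) + 1L]] <-
          data.frame(ion = ion, time = times[f], direction = -1L)
      }
      origin <- zone[f]
    }
  }
  if (!length(events))
    return(data.frame(ion = integer(), time = numeric(),
                      direction = integer()))
  ev <- do.call(rbind, events)
  ev[order(ev$time), , drop = FALSE]
}

#' ECC-corrected single-channel conductance from an event count
#'
#' @param n signed net permeation event count.
#' @param charge nominal integer ion charge in elementary charges (the
#'   unscaled, physical charge).
#' @param time trajectory duration in seconds.
#' @param efield applied field E in V/nm.
#' @param lz box length along z in nm (so the nominal voltage is
#'   `efield * lz`).
#' @param fEcc ECC scaling factor in (0, 1]; the effective field is
#'   `E * fEcc`, hence the 1/fEcc factor on the conductance.
#' @param sd optional replicate SD in pS.
#' @return a [ConductanceEstimate-class]; conductance in pS.
#' @examples
#' conductance(100, charge = 1, time = 1e-6, efield = 0.01, lz = 10)
#' @export
conductance <- function(n, charge, time, efield, lz, fEcc = 1, sd = NA_real_) {
  if (time <= 0) stop("trajectory duration must be positive")
  voltage <- efield * lz
  if (voltage <= 0) stop("nominal voltage E*Lz must be positive")
  if (fEcc <= 0) stop("fEcc must be positive")
  current <- n * charge * ELEMENTARY_CHARGE / time
  g <- current / (voltage * fEcc) * 1e12
  new("ConductanceEstimate", n = as.numeric(n), current = current,
      conductance = g, sd = as.numeric(sd), voltage = voltage, fEcc = fEcc)
}

#' Conductance of an IonTrajectory
#'
#' Convenience wrapper: counts events with [countPermeationEvents()], takes
#' the net signed count, and applies the conductance equation with the
#' trajectory's metadata.
#'
#' @param traj an [IonTrajectory-class] (all ions must share one charge).
#' @param zUpper,zLower crossing planes (angstrom).
#' @return a [ConductanceEstimate-class].
#' @export
trajectoryConductance <- function(traj, zUpper, zLower) {
  ev <- countPermeationEvents(traj, zUpper, zLower)
  q <- unique(traj@charge)
  if (length(q) != 1L)
    stop("trajectory mixes ion charges; count events per species instead")
  tSec <- diff(range(traj@times)) * 1e-12
  conductance(sum(ev$direction), q, tSec, traj@efield, traj@lz, traj@fEcc)
}

#' Replicate SD of conductance estimates
#'
#' @param replicates numeric vector (>= 2) of per-replicate conductances
#'   in pS.
#' @return the sample SD across replicates, in pS.
#' @export
conductanceError <- function(replicates) {
  if (length(replicates) < 2L)
    stop("SD undefined: need at least 2 replicates")
  stats::sd(replicates)
}

#' Linear I-V fit through the origin
#'
#' Least-squares slope with zero intercept, `g = sum(V*I) / sum(V^2)` --
#' the ohmic conductance implied by a current-voltage table.
#'
#' @param voltages voltages in volt.
#' @param currents currents in ampere.
#' @return list with `slope` (siemens), `slope_pS`, and `residuals`
#'   (ampere).
#' @export
ivFitThroughOrigin <- function(voltages, currents) {
  if (length(voltages) != length(currents))
    stop("voltages and currents must have equal length")
  if (all(voltages == 0)) stop("degenerate fit: all voltages are zero")
  fit <- stats::lm(currents ~ 0 + voltages)
  slope <- unname(stats::coef(fit)[1])
  list(slope = slope, slope_pS = slope * 1e12,
       residuals = unname(stats::residuals(fit)))
}

#' Permeation selectivity ratio
#'
#' @param eventsA,eventsB event counts for the two species (A over B).
#' @return `eventsA / eventsB`; `Inf` (a tagged value, not an error) when
#'   `eventsB` is zero.
#' @examples
#' selectivityRatio(140, 4)   # 35
#' @export
selectivityRatio <- function(eventsA, eventsB) {
  if (eventsB < 0) stop("event counts must be >= 0")
  if (eventsB == 0) return(Inf)
  eventsA / eventsB
}

#' Mutant/wild-type conductance fold change
#'
#' First-order (delta-method) error propagation from the two replicate
#' SDs: for `r = gMut/gWt`,
#' `sd(r) = sqrt((sdMut/gWt)^2 + (gMut*sdWt/gWt^2)^2)`.
#'
#' @param gMut,gWt mutant and wild-type conductances (pS), `gWt > 0`.
#' @param sdMut,sdWt replicate SDs (pS), default 0.
#' @return list with `ratio` and `sd`.
#' @export
foldChange <- function(gMut, gWt, sdMut = 0, sdWt = 0) {
  if (gWt <= 0) stop("wild-type conductance must be positive")
  r <- gMut / gWt
  s <- sqrt((sdMut / gWt)^2 + (gMut * sdWt / gWt^2)^2)
  list(ratio = r, sd = s)
}

#' Pearson correlation of simulated vs experimental per-mutant values
#'
#' Experimental entries may be given as a list with several published
#' values per mutant; duplicates are averaged before the correlation is
#' computed.
#'
#' @param md numeric vector of simulated per-mutant values.
#' @param exper list (or numeric vector) of experimental values, one entry
#'   (possibly a vector of duplicates) per mutant, same order as `md`.
#' @return Pearson's r.
#' @export
pearsonVsExperiment <- function(md, exper) {
  if (!is.list(exper)) exper <- as.list(exper)
  if (length(md) != length(exper))
    stop("md and exper must pair one entry per mutant")
  if (length(md) < 3L) stop("need at least 3 mutants")
  ex <- vapply(exper, function(v) mean(as.numeric(v)), numeric(1))
  if (stats::sd(md) == 0 || stats::sd(ex) == 0)
    stop("undefined correlation: zero variance in one of the vectors")
  stats::cor(md, ex)
}

#' Arrhenius rate ratio from a barrier difference
#'
#' Rate ratio implied by a free-energy barrier difference:
#' `exp(ddG / RT)`.
#'
#' @param ddG barrier difference in kJ/mol.
#' @param temperature temperature in kelvin.
#' @return the rate ratio (dimensionless).
#' @examples
#' arrheniusRateRatio(19, 310)   # ~1.6e3
#' @export
arrheniusRateRatio <- function(ddG, temperature) {
  exp(ddG / thermalEnergy(temperature))
}
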