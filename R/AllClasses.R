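#' @import methods
NULL

## ---------------------------------------------------------------------------
## EnergyGrid: an N-dimensional regular grid of free energies (kJ/mol) with
## an optional exclusion mask. Axes are stored as a data.frame with one row
## per dimension: name, min, max, n (grid points), periodic.
## ---------------------------------------------------------------------------

#' EnergyGrid: gridded free-energy surface
#'
#' A regular N-dimensional grid of free energies in kJ/mol, as produced by
#' metadynamics post-processing tools, together with a boolean exclusion
#' mask (TRUE = node excluded from path searches, e.g. high-energy regions).
#'
#' Axis coordinates run from `min` to `max` with `n` points per axis:
#' `min + (0:(n-1)) * spacing`, where `spacing = (max - min)/(n - 1)` for
#' non-periodic axes and `(max - min)/n` for periodic ones.
#'
#' @slot axes data.frame with columns `name`, `min`, `max`, `n`, `periodic`.
#' @slot values numeric array of free energies, `dim(values) == axes$n`.
#' @slot mask logical array of the same shape; TRUE marks excluded nodes.
#' @slot unit axis length unit label (default `"A"` for angstrom).
#' @export
setClass("EnergyGrid",
  representation(axes = "data.frame", values = "array", mask = "array",
                 unit = "character"),
  validity = function(object) {
    ax <- object@axes
    msgs <- character()
    need <- c("name", "min", "max", "n", "periodic")
    if (!all(need %in% names(ax)))
      return(paste("axes must have columns", paste(need, collapse = ", ")))
    if (nrow(ax) < 1L) msgs <- c(msgs, "at least one axis required")
    if (any(ax$n < 2L)) msgs <- c(msgs, "each axis needs >= 2 grid points")
    if (any(!(ax$min < ax$max))) msgs <- c(msgs, "axis min must be < max")
    if (!identical(as.integer(dim(object@values)), as.integer(ax$n)))
      msgs <- c(msgs, "values shape does not match axes$n")
    if (!identical(dim(object@mask), dim(object@values)))
      msgs <- c(msgs, "mask shape does not match values shape")
    bad <- !object@mask & !is.finite(object@values)
    if (any(bad))
      msgs <- c(msgs, "non-finite energies on unmasked nodes")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
  })

#' Construct an EnergyGrid
#'
#' @param axes data.frame with columns `name`, `min`, `max`, `n`,
#'   `periodic` (one row per dimension).
#' @param values numeric array (or vector for 1D) of free energies in
#'   kJ/mol, fastest-varying index = first axis.
#' @param mask optional logical array, TRUE = excluded node.
#' @param unit axis unit label, default `"A"`.
#' @return an [EnergyGrid-class] object.
#' @examples
#' g <- energyGrid(gridAxes("x", 0, 2, 3), c(0, 2, 0))
#' gridValues(g)
#' @export
energyGrid <- function(axes, values, mask = NULL, unit = "A") {
  dims <- as.integer(axes$n)
  if (length(values) != prod(dims))
    stop("values shape does not match axes$n (", length(values), " vs ",
         prod(dims), " nodes)")
  values <- array(as.numeric(values), dim = dims)
  if (is.null(mask)) mask <- array(FALSE, dim = dims)
  if (length(mask) != prod(dims))
    stop("mask shape does not match axes$n")
  mask <- array(as.logical(mask), dim = dims)
  axes$n <- dims
  axes$periodic <- as.logical(axes$periodic)
  new("EnergyGrid", axes = axes, values = values, mask = mask, unit = unit)
}

#' Describe grid axes
#'
#' Convenience constructor for the `axes` data.frame of [energyGrid()].
#'
#' @param name axis names.
#' @param min,max axis ranges (same units for all axes).
#' @param n number of grid points per axis.
#' @param periodic logical, per-axis periodicity.
#' @return data.frame usable as the `axes` argument of [energyGrid()].
#' @export
gridAxes <- function(name, min, max, n, periodic = FALSE) {
  data.frame(name = as.character(name), min = as.numeric(min),
             max = as.numeric(max), n = as.integer(n),
             periodic = rep_len(as.logical(periodic), length(name)),
             stringsAsFactors = FALSE)
}

#' @describeIn EnergyGrid-class grid axes data.frame
#' @param x an EnergyGrid.
#' @export
gridAxesOf <- function(x) x@axes

#' @describeIn EnergyGrid-class free-energy array (kJ/mol)
#' @export
gridValues <- function(x) x@values

#' @describeIn EnergyGrid-class exclusion mask array
#' @export
gridMask <- function(x) x@mask

#' @describeIn EnergyGrid-class per-axis bin width
#' @export
gridSpacing <- function(x) {
  ax <- x@axes
  ifelse(ax$periodic, (ax$max - ax$min) / ax$n, (ax$max - ax$min) / (ax$n - 1L))
}

#' @describeIn EnergyGrid-class axis unit label
#' @export
gridUnit <- function(x) x@unit

setMethod("show", "EnergyGrid", function(object) {
  ax <- object@axes
  cat("EnergyGrid:", paste(ax$n, collapse = " x "), "nodes,",
      nrow(ax), "dimension(s) [", object@unit, "]\n")
  for (i in seq_len(nrow(ax)))
    cat(sprintf("  %s: [%g, %g] n=%d spacing=%g%s\n", ax$name[i], ax$min[i],
                ax$max[i], ax$n[i], gridSpacing(object)[i],
                if (ax$periodic[i]) " (periodic)" else ""))
  cat(sprintf("  energy range (unmasked): [%g, %g] kJ/mol; %d/%d masked\n",
              min(object@values[!object@mask]),
              max(object@values[!object@mask]),
              sum(object@mask), length(object@mask)))
})

## ---------------------------------------------------------------------------
## IonTrajectory: per-frame per-ion z positions with metadata needed for
## conductance computation (box, applied field, ECC factor).
## ---------------------------------------------------------------------------

#' IonTrajectory: time series of per-ion positions
#'
#' Holds per-frame z positions (angstrom) of tracked ions together with the
#' simulation metadata that the conductance equation needs: box length,
#' applied field E (V/nm), the z box length Lz (nm) so that the nominal
#' transmembrane voltage is `V = E * Lz`, and the ECC charge-scaling factor
#' f_ECC. Optional x/y coordinates may be attached for coordination
#' analysis.
#'
#' @slot times frame times in ps, strictly increasing.
#' @slot z numeric matrix frames x ions, z in angstrom.
#' @slot xy optional list with `x` and `y` matrices (may be empty).
#' @slot species character per-ion species label.
#' @slot charge numeric per-ion nominal integer charge (elementary charges).
#' @slot boxZ box length along z in angstrom.
#' @slot efield applied field E in V/nm (positive = drives cations to -z).
#' @slot lz box length along z in nm (for the voltage V = E*Lz).
#' @slot fEcc ECC scaling factor in (0, 1].
#' @export
setClass("IonTrajectory",
  representation(times = "numeric", z = "matrix", xy = "list",
                 species = "character", charge = "numeric", boxZ = "numeric",
                 efield = "numeric", lz = "numeric", fEcc = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(object@times) != nrow(object@z))
      msgs <- c(msgs, "length(times) != nrow(z)")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      msgs <- c(msgs, "times must be strictly increasing")
    if (any(!is.finite(object@z))) msgs <- c(msgs, "non-finite z positions")
    if (length(object@species) != ncol(object@z) ||
        length(object@charge) != ncol(object@z))
      msgs <- c(msgs, "species/charge length must equal number of ions")
    if (any(object@charge == 0)) msgs <- c(msgs, "ion charge must be nonzero")
    if (object@fEcc <= 0 || object@fEcc > 1)
      msgs <- c(msgs, "fEcc must be in (0, 1]")
    if (object@boxZ <= 0) msgs <- c(msgs, "boxZ must be positive")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
  })

#' Construct an IonTrajectory
#'
#' @param times frame times (ps), strictly increasing.
#' @param z matrix of z positions (angstrom), frames x ions.
#' @param species per-ion species labels (recycled).
#' @param charge per-ion nominal integer charges (recycled).
#' @param boxZ box length along z (angstrom).
#' @param efield applied field E (V/nm).
#' @param lz z box length (nm); nominal voltage is `efield * lz`.
#' @param fEcc ECC scaling factor in (0, 1].
#' @param xy optional list(x =, y =) coordinate matrices.
#' @return an [IonTrajectory-class].
#' @export
ionTrajectory <- function(times, z, species = "CA", charge = 2, boxZ = 120,
                          efield = 0.01, lz = 12, fEcc = 0.87, xy = list()) {
  z <- as.matrix(z)
  new("IonTrajectory", times = as.numeric(times), z = z, xy = xy,
      species = rep_len(as.character(species), ncol(z)),
      charge = rep_len(as.numeric(charge), ncol(z)),
      boxZ = boxZ, efield = efield, lz = lz, fEcc = fEcc)
}

#' @describeIn IonTrajectory-class number of frames
#' @param x an IonTrajectory.
#' @export
nFrames <- function(x) nrow(x@z)

#' @describeIn IonTrajectory-class number of tracked ions
#' @export
nIons <- function(x) ncol(x@z)

#' @describeIn IonTrajectory-class frame times (ps)
#' @export
trajTimes <- function(x) x@times

#' @describeIn IonTrajectory-class z-position matrix (angstrom)
#' @export
trajZ <- function(x) x@z

setMethod("show", "IonTrajectory", function(object) {
  cat(sprintf("IonTrajectory: %d frames x %d ions (%s), span %.1f ps\n",
              nFrames(object), nIons(object),
              paste(unique(object@species), collapse = ","),
              diff(range(object@times))))
  cat(sprintf("  boxZ=%g A, E=%g V/nm, Lz=%g nm (V=%g mV), f_ECC=%g\n",
              object@boxZ, object@efield, object@lz,
              1000 * object@efield * object@lz, object@fEcc))
})

## ---------------------------------------------------------------------------
## StateSequence: per-frame occupancy-state labels.
## ---------------------------------------------------------------------------

#' StateSequence: per-frame occupancy-state labels
#'
#' Frame-by-frame selectivity-filter occupancy labels, one of `"1"`, `"2U"`,
#' `"2L"` or `"other"`, at a fixed frame spacing `dt` (ps).
#'
#' @slot labels character vector of per-frame labels.
#' @slot dt frame spacing in ps (> 0).
#' @export
setClass("StateSequence",
  representation(labels = "character", dt = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (object@dt <= 0) msgs <- c(msgs, "dt must be > 0")
    if (anyNA(object@labels)) msgs <- c(msgs, "labels must be defined for every frame")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
  })

#' Construct a StateSequence
#'
#' @param labels per-frame state labels.
#' @param dt frame spacing in ps.
#' @return a [StateSequence-class].
#' @export
stateSequence <- function(labels, dt) {
  new("StateSequence", labels = as.character(labels), dt = as.numeric(dt))
}

#' @describeIn StateSequence-class per-frame labels
#' @param x a StateSequence.
#' @export
stateLabels <- function(x) x@labels

#' @describeIn StateSequence-class frame spacing (ps)
#' @export
stateDt <- function(x) x@dt

setMethod("show", "StateSequence", function(object) {
  cat(sprintf("StateSequence: %d frames, dt=%g ps\n", length(object@labels),
              object@dt))
  print(round(occupancyProbabilities(object), 4))
})

## ---------------------------------------------------------------------------
## ConductanceEstimate
## ---------------------------------------------------------------------------

#' ConductanceEstimate: single-channel conductance from event counting
#'
#' @slot n signed net permeation event count.
#' @slot current current in ampere.
#' @slot conductance conductance in pS.
#' @slot sd replicate SD of the conductance in pS (NA if unknown).
#' @slot voltage nominal voltage E*Lz in volt.
#' @slot fEcc ECC factor used.
#' @export
setClass("ConductanceEstimate",
  representation(n = "numeric", current = "numeric", conductance = "numeric",
                 sd = "numeric", voltage = "numeric", fEcc = "numeric"),
  validity = function(object) {
    msgs <- character()
    if ((object@n == 0) != (object@conductance == 0))
      msgs <- c(msgs, "conductance must be 0 exactly when N is 0")
    if (object@n != 0 && sign(object@conductance) != sign(object@n))
      msgs <- c(msgs, "conductance sign must follow net flux sign")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
  })

setMethod("show", "ConductanceEstimate", function(object) {
  cat(sprintf("ConductanceEstimate: g = %.4g pS (N = %g, I = %.4g A, V = %g mV, f_ECC = %g)\n",
              object@conductance, object@n, object@current,
              1000 * object@voltage, object@fEcc))
  if (is.finite(object@sd)) cat(sprintf("  replicate SD = %.4g pS\n", object@sd))
})

#' @describeIn ConductanceEstimate-class conductance in pS
#' @param x a ConductanceEstimate.
#' @export
conductancePs <- function(x) x@conductance

## ---------------------------------------------------------------------------
## MfepResult
## ---------------------------------------------------------------------------

#' MfepResult: minimum free energy path and its 1D profile
#'
#' Result of [mfep()]: the spliced grid path, its free-energy profile along
#' the normalised reaction coordinate, the barrier relative to the chosen
#' reference minimum, and the basin decomposition of the grid.
#'
#' @slot path data.frame: `node` (flat index), per-axis coordinates,
#'   `energy` (kJ/mol), `arclength`, `logCost` (cumulative log resistance).
#' @slot profile data.frame with `s` (normalised reaction coordinate in
#'   [0,1]) and `energy` (kJ/mol).
#' @slot barrier max(profile) minus the reference minimum energy, kJ/mol.
#' @slot logCost log of the total resistance cost of the path.
#' @slot basins list: `fixedPoints`, `basinLabel`, `cgAdjacency`.
#' @slot temperature temperature (K) used for the resistance weights.
#' @export
setClass("MfepResult",
  representation(path = "data.frame", profile = "data.frame",
                 barrier = "numeric", logCost = "numeric", basins = "list",
                 temperature = "numeric"),
  validity = function(object) {
    if (object@barrier < -1e-9) return("barrier must be >= 0")
    TRUE
  })

setMethod("show", "MfepResult", function(object) {
  cat(sprintf("MfepResult: %d path nodes, barrier = %.4g kJ/mol, log(cost) = %.4g, %d basins (T = %g K)\n",
              nrow(object@path), object@barrier, object@logCost,
              length(object@basins$fixedPoints), object@temperature))
})

#' @describeIn MfepResult-class path data.frame
#' @param x an MfepResult.
#' @export
mfepPath <- function(x) x@path

#' @describeIn MfepResult-class profile data.frame (s, energy)
#' @export
mfepProfile <- function(x) x@profile

#' @describeIn MfepResult-class barrier height (kJ/mol)
#' @export
mfepBarrier <- function(x) x@barrier

#' @describeIn MfepResult-class log of the total resistance cost
#' @export
mfepLogCost <- function(x) x@logCost
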