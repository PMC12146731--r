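## Pipeline orchestration: simulate -> analyze -> report. Each run writes
## its resolved configuration next to the outputs so deterministic stages
## can be reproduced bit-for-bit from the emitted file.

#' Run a simulate/analyze/report pipeline
#'
#' Executes the requested stages in dependency order and writes a
#' machine-readable JSON summary (conductances in pS, barriers in kJ/mol,
#' occupancies, rates in ns^-1) plus TSV tables into `outDir`, along with
#' the fully resolved configuration and per-stage timings.
#'
#' Stages:
#' * `"kmc"`: knock-on kinetic Monte Carlo, occupancy probabilities and
#'   transition rates.
#' * `"langevin"`: multi-ion Langevin trajectory, permeation events and
#'   ECC-corrected conductance.
#' * `"metad"`: 1D well-tempered metadynamics toy run on a double-well
#'   potential, reconstructed FES and barrier.
#' * `"mfep"`: MFEP on a free-energy grid -- either a toy landscape, a
#'   grid file, or the `"metad"` stage's reconstructed FES (which must
#'   then run first).
#'
#' @param config list with `stages` (character vector), `seed`,
#'   `temperature`, `outDir`, and optional per-stage parameter lists
#'   `kmc`, `langevin`, `metad`, `mfep` (see the stage functions for the
#'   parameters they accept).
#' @return the summary list, invisibly; side effect: files in `outDir`.
#' @export
runPipeline <- function(config) {
  stages <- config$stages %||% character(0)
  outDir <- config$outDir %||% "."
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (!length(stages)) {
    warning("empty stage list: nothing to do")
    return(invisible(list()))
  }
  seed <- config$seed %||% 1L
  temperature <- config$temperature %||% 310
  summary <- list(seed = seed, temperature_K = temperature)
  timings <- list()
  artefacts <- new.env(parent = emptyenv())

  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }

  if ("kmc" %in% stages) {
    p <- config$kmc %||% list()
    rates <- p$rates %||% c(10, 20, 5)
    sim <- tic("kmc", {
      model <- knockOnModel(rates[1], rates[2], rates[3])
      simulateKnockonKmc(model, duration = p$duration %||% 100,
                         dt = p$dt %||% 10, seed = seed)
    })
    tr <- transitionRates(sim$states)
    utils::write.table(
      data.frame(frame = seq_along(stateLabels(sim$states)),
                 state = stateLabels(sim$states)),
      file.path(outDir, "kmc_states.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    summary$kmc <- list(
      occupancy = as.list(tr$occupancy),
      rates_ns = as.list(stats::na.omit(as.data.frame(as.table(tr$rates)))$Freq),
      n_events = length(sim$events),
      event_rate_ns = length(sim$events) / (p$duration %||% 100))
    assign("kmc", sim, envir = artefacts)
  }

  if ("langevin" %in% stages) {
    p <- config$langevin %||% list()
    traj <- tic("langevin", {
      args <- p[intersect(names(p), names(formals(langevinConfig)))]
      args$seed <- seed
      simulateMultiIonLangevin(do.call(langevinConfig, args))
    })
    planes <- p$planes %||% c(8, -8)
    est <- trajectoryConductance(traj, planes[1], planes[2])
    ev <- countPermeationEvents(traj, planes[1], planes[2])
    utils::write.table(ev, file.path(outDir, "permeation_events.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary$langevin <- list(n_events_net = est@n,
                             conductance_pS = est@conductance,
                             voltage_mV = 1000 * est@voltage)
    assign("langevin", traj, envir = artefacts)
  }

  if ("metad" %in% stages) {
    p <- config$metad %||% list()
    barrier <- p$barrier %||% 10
    x0 <- p$wellPosition %||% 0.2
    res <- tic("metad", {
      args <- p[intersect(names(p), names(formals(metadConfig)))]
      args$seed <- seed
      args$temperature <- args$temperature %||% temperature
      U <- function(x) barrier * ((x / x0)^2 - 1)^2
      wtMetadynamics1d(U, do.call(metadConfig, args))
    })
    writeFesGrid(res$fes, file.path(outDir, "metad_fes.dat"), "plumed_grid")
    est <- metadBarrier(res$fes, x0)
    summary$metad <- list(true_barrier_kJmol = barrier,
                          estimated_barrier_kJmol = est,
                          n_hills = nrow(res$hills))
    assign("metad", res, envir = artefacts)
  }

  if ("mfep" %in% stages) {
    p <- config$mfep %||% list()
    src <- p$fes %||% "double_well_2d"
    if (identical(src, "metad")) {
      if (!exists("metad", envir = artefacts))
        stop("missing upstream artefact: run the 'metad' stage first")
      grid <- get("metad", envir = artefacts)$fes
      start <- p$start %||% -(p$wellPosition %||% 0.2)
      end <- p$end %||% (p$wellPosition %||% 0.2)
    } else if (is.character(src) && file.exists(src)) {
      grid <- readFesGrid(src, p$dialect %||% "plumed_grid")
      start <- p$start; end <- p$end
    } else {
      toy <- toyLandscape(src)
      grid <- toy$grid
      start <- p$start %||% toy$facts$wells[1, ]
      end <- p$end %||% toy$facts$wells[2, ]
    }
    if (!is.null(p$maskAbove)) grid <- maskHighEnergy(grid, p$maskAbove)
    res <- tic("mfep", mfep(grid, start, end, temperature,
                            connectivity = p$connectivity %||% "moore"))
    utils::write.table(mfepPath(res), file.path(outDir, "mfep_path.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(mfepProfile(res), file.path(outDir, "mfep_profile.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary$mfep <- list(barrier_kJmol = mfepBarrier(res),
                         log_cost = mfepLogCost(res),
                         n_basins = length(res@basins$fixedPoints))
  }

  summary$timings_s <- timings
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  resolved <- config
  resolved$seed <- seed
  resolved$temperature <- temperature
  jsonlite::write_json(resolved, file.path(outDir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}

#' Barrier of a reconstructed 1D double-well FES
#'
#' Barrier between the wells of a 1D profile: maximum of the inter-well
#' segment minus the deeper adjacent well minimum.
#'
#' @param fes 1D [EnergyGrid-class].
#' @param wellPosition |x| of the two wells (same axis unit as the grid).
#' @return barrier in kJ/mol.
#' @export
metadBarrier <- function(fes, wellPosition) {
  xs <- nodeCoordinates(fes)[, 1]
  v <- as.vector(gridValues(fes))
  leftMin <- min(v[abs(xs + wellPosition) <= wellPosition / 2])
  rightMin <- min(v[abs(xs - wellPosition) <= wellPosition / 2])
  mid <- max(v[abs(xs) <= wellPosition / 2])
  mid - min(leftMin, rightMin)
}
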