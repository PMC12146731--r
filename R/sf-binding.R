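## Selectivity-filter binding analysis: z-density profiles, binding-site
## peaks, coordination numbers, occupancy-state assignment and transition
## rates.

#' Default selectivity-filter site definition
#'
#' Named z-intervals (angstrom, origin at the filter centre, e.g. the COM
#' of the EEEE-locus C-alpha atoms) for the four filter sites and the outer
#' vestibule site. The defaults bracket the printed single/double-ion
#' binding-site peaks (-2.8 and 1.7 A); the exact boundaries are a
#' convention and freely tunable.
#'
#' @param sf filter extent.
#' @param s2l,s2u,s1l,s1u site intervals, lower to upper.
#' @param v1 vestibule interval (above the filter).
#' @return named list of intervals, validated.
#' @export
siteDefinition <- function(sf = c(-5, 5), s2l = c(-4, -1.5),
                           s2u = c(-1.5, 0.5), s1l = c(0.5, 2.5),
                           s1u = c(2.5, 5), v1 = c(5, 9)) {
  sites <- list(sf = sf, s2l = s2l, s2u = s2u, s1l = s1l, s1u = s1u, v1 = v1)
  for (nm in names(sites)) {
    iv <- sites[[nm]]
    if (length(iv) != 2L || iv[1] >= iv[2])
      stop("site ", nm, " must be an interval c(lo, hi) with lo < hi")
  }
  ## S1 above S2, U above L within each pair
  if (!(s1l[1] >= s2u[1]) || !(s1u[1] >= s2u[1]))
    stop("S1 intervals must lie above S2 intervals")
  if (!(s1u[1] >= s1l[1]) || !(s2u[1] >= s2l[1]))
    stop("U intervals must lie above L intervals")
  sites
}

inInterval <- function(z, iv) z >= iv[1] & z <= iv[2]

#' Time-averaged ion density along z
#'
#' Average number of ions per z-bin, so that the profile sums to the
#' time-averaged ion count in the profiled region.
#'
#' @param traj an [IonTrajectory-class] (or a frames x ions z matrix).
#' @param binWidth bin width in angstrom (default 0.2).
#' @param region z-interval `c(lo, hi)` to profile.
#' @return data.frame with `zlo`, `zhi`, `zmid` and `count` (mean ions per
#'   bin); bins are left-closed, right-open except the last.
#' @export
zDensity <- function(traj, binWidth = 0.2, region = c(-10, 10)) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (region[1] >= region[2]) stop("empty region")
  z <- if (is(traj, "IonTrajectory")) traj@z else as.matrix(traj)
  nb <- max(1L, ceiling((region[2] - region[1]) / binWidth - 1e-9))
  edges <- region[1] + (0:nb) * binWidth
  zz <- as.vector(z)
  zz <- zz[zz >= edges[1] & zz <= edges[nb + 1L]]
  idx <- pmin(nb, floor((zz - edges[1]) / binWidth) + 1L)
  counts <- tabulate(idx, nbins = nb) / nrow(z)
  data.frame(zlo = edges[-(nb + 1L)], zhi = edges[-1L],
             zmid = (edges[-1L] + edges[-(nb + 1L)]) / 2, count = counts)
}

#' Detect binding sites as density peaks
#'
#' Local maxima of a z-density profile, filtered by topographic prominence
#' and a minimum mutual separation (higher peaks win), ranked by height.
#'
#' @param profile data.frame from [zDensity()] (columns `zmid`, `count`).
#' @param minProminence minimum peak prominence (ions/bin).
#' @param minSeparation minimum distance between reported peaks (angstrom).
#' @return data.frame with `z`, `height`, `prominence`, sorted by height
#'   (may be empty).
#' @export
detectBindingSites <- function(profile, minProminence = 0,
                               minSeparation = 0) {
  y <- profile$count
  x <- profile$zmid
  if (!length(y)) stop("empty profile")
  pk <- pracma::findpeaks(y, zero = "0")
  if (is.null(pk))
    return(data.frame(z = numeric(), height = numeric(),
                      prominence = numeric()))
  loc <- pk[, 2]
  height <- pk[, 1]
  prominence <- vapply(seq_along(loc), function(i) {
    p <- loc[i]; h <- height[i]
    sideMin <- function(idx) {
      if (!length(idx)) return(min(y[p]))
      higher <- which(y[idx] > h)
      if (length(higher)) idx <- idx[seq_len(min(higher) - 1L)]
      if (!length(idx)) y[p] else min(y[idx])
    }
    lo <- sideMin(rev(seq_len(p - 1L)))
    hi <- sideMin(seq(p + 1L, length.out = length(y) - p))
    h - max(lo, hi)
  }, numeric(1))
  keep <- prominence >= minProminence
  loc <- loc[keep]; height <- height[keep]; prominence <- prominence[keep]
  o <- order(-height, x[loc])
  loc <- loc[o]; height <- height[o]; prominence <- prominence[o]
  sel <- logical(0)
  zs <- numeric(0)
  for (i in seq_along(loc)) {
    if (all(abs(x[loc[i]] - zs) >= minSeparation) || !length(zs)) {
      sel <- c(sel, TRUE); zs <- c(zs, x[loc[i]])
    } else sel <- c(sel, FALSE)
  }
  data.frame(z = x[loc[sel]], height = height[sel],
             prominence = prominence[sel])
}

#' Coordination-number profile along z
#'
#' Counts, per frame and per ion, the labelled oxygens within a distance
#' cutoff (closed comparison, minimum-image if a box is given) and averages
#' the counts in z-bins of the ion position, split by oxygen class and by
#' residue label.
#'
#' @param frames data.frame with columns `frame`, `atom_id`, `kind`
#'   (`"ion"` or an oxygen class such as `"ox_carboxylate"`,
#'   `"ox_carbonyl"`, `"ox_water"`), `residue_label`, `x`, `y`, `z`.
#' @param cutoff coordination cutoff in angstrom (default 3).
#' @param binWidth z-bin width (angstrom).
#' @param box optional c(Lx, Ly, Lz) for minimum-image distances.
#' @return list with `byClass` and `byResidue` data.frames (`zmid`, group,
#'   `mean_count`, `n_obs`), `perIon` (per frame/ion raw counts) and the
#'   `cutoff` used.
#' @export
coordinationProfile <- function(frames, cutoff = 3, binWidth = 0.5,
                                box = NULL) {
  need <- c("frame", "atom_id", "kind", "residue_label", "x", "y", "z")
  if (!all(need %in% names(frames)))
    stop("schema error: frames must have columns ",
         paste(need, collapse = ", "))
  if (cutoff <= 0) stop("cutoff must be > 0")
  obs <- list()
  for (fr in split(frames, frames$frame)) {
    ions <- fr[fr$kind == "ion", , drop = FALSE]
    oxy <- fr[startsWith(fr$kind, "ox_"), , drop = FALSE]
    if (!nrow(ions)) next
    for (i in seq_len(nrow(ions))) {
      d <- cbind(oxy$x - ions$x[i], oxy$y - ions$y[i], oxy$z - ions$z[i])
      if (!is.null(box))
        for (j in 1:3) d[, j] <- d[, j] - box[j] * round(d[, j] / box[j])
      within <- which(sqrt(rowSums(d^2)) <= cutoff)
      obs[[length(obs) + 1L]] <- data.frame(
        frame = rep(ions$frame[i], length(within)),
        ion = rep(ions$atom_id[i], length(within)),
        z = rep(ions$z[i], length(within)),
        kind = oxy$kind[within], residue_label = oxy$residue_label[within],
        stringsAsFactors = FALSE)
    }
  }
  perIon <- if (length(obs)) do.call(rbind, obs) else
    data.frame(frame = numeric(), ion = character(), z = numeric(),
               kind = character(), residue_label = character())
  ## per ion-frame totals per group, then z-binned means
  ionFrames <- unique(frames[frames$kind == "ion",
                             c("frame", "atom_id", "z")])
  zbin <- function(z) floor(z / binWidth) * binWidth + binWidth / 2
  summarise <- function(group) {
    key <- interaction(perIon$frame, perIon$ion, drop = FALSE)
    groups <- sort(unique(perIon[[group]]))
    out <- list()
    for (g in groups) {
      cnt <- table(factor(paste(perIon$frame, perIon$ion)[perIon[[group]] == g],
                          levels = paste(ionFrames$frame, ionFrames$atom_id)))
      df <- data.frame(zmid = zbin(ionFrames$z), count = as.vector(cnt))
      agg <- stats::aggregate(count ~ zmid, df, mean)
      nobs <- stats::aggregate(count ~ zmid, df, length)
      out[[length(out) + 1L]] <- data.frame(zmid = agg$zmid, group = g,
                                            mean_count = agg$count,
                                            n_obs = nobs$count)
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(zmid = numeric(), group = character(),
                 mean_count = numeric(), n_obs = integer())
  }
  list(byClass = summarise("kind"), byResidue = summarise("residue_label"),
       perIon = perIon, cutoff = cutoff)
}

#' Assign selectivity-filter occupancy states
#'
#' For each frame, counts the ions inside the filter extent: one ion gives
#' state `"1"`; two ions both within the upper sites (S1U/S2U) give
#' `"2U"`, both within the lower sites (S1L/S2L) give `"2L"`; any other
#' arrangement (including empty or >2-ion frames) is `"other"`. The
#' assignment is invariant to the order of the ion columns.
#'
#' @param z frames x ions z matrix (angstrom), or a vector for one frame.
#' @param sites site definition from [siteDefinition()].
#' @return character vector of per-frame labels (length 1 for a vector
#'   input).
#' @export
assignStates <- function(z, sites = siteDefinition()) {
  if (is(z, "IonTrajectory")) z <- z@z
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  upper <- function(zz) inInterval(zz, sites$s1u) | inInterval(zz, sites$s2u)
  lower <- function(zz) inInterval(zz, sites$s1l) | inInterval(zz, sites$s2l)
  apply(z, 1L, function(zr) {
    inSf <- zr[inInterval(zr, sites$sf)]
    if (length(inSf) == 1L) return("1")
    if (length(inSf) == 2L) {
      if (all(upper(inSf))) return("2U")
      if (all(lower(inSf))) return("2L")
    }
    "other"
  })
}

#' Occupancy probabilities of a state sequence
#'
#' @param seq a [StateSequence-class] (or character label vector).
#' @return named numeric vector of per-state frame fractions (sums to 1),
#'   canonical states first.
#' @export
occupancyProbabilities <- function(seq) {
  labels <- if (is(seq, "StateSequence")) seq@labels else as.character(seq)
  if (!length(labels)) stop("need at least one frame")
  canonical <- c("1", "2U", "2L", "other")
  lv <- c(intersect(canonical, unique(labels)),
          setdiff(unique(labels), canonical))
  p <- table(factor(labels, levels = lv)) / length(labels)
  stats::setNames(as.numeric(p), names(p))
}

#' Transition-rate matrix of a state sequence
#'
#' Per-time rate estimates: `k(s -> s') = (number of s -> s' frame
#' transitions) / (dt * frames labelled s, final frame excluded)`, with a
#' Poisson standard error `sqrt(count) / (dt * frames in s)`. Rates for
#' states never visited (outside the final frame) are reported as NA.
#'
#' @param seq a [StateSequence-class].
#' @return list with `rates` and `se` (ns^-1 matrices, from-state rows,
#'   diagonal NA), `occupancy` (frame fractions) and `dwell_frames`.
#' @export
transitionRates <- function(seq) {
  labels <- seq@labels
  if (length(labels) < 2L) stop("need at least 2 frames")
  dtNs <- seq@dt / 1000
  canonical <- c("1", "2U", "2L", "other")
  lv <- c(intersect(canonical, unique(labels)),
          setdiff(unique(labels), canonical))
  from <- factor(labels[-length(labels)], levels = lv)
  to <- factor(labels[-1L], levels = lv)
  C <- table(from, to)
  nFrom <- table(from)
  rates <- matrix(NA_real_, length(lv), length(lv),
                  dimnames = list(from = lv, to = lv))
  se <- rates
  for (i in seq_along(lv)) {
    if (nFrom[i] == 0) next
    denom <- dtNs * as.numeric(nFrom[i])
    for (j in seq_along(lv)) {
      if (i == j) next
      rates[i, j] <- C[i, j] / denom
      se[i, j] <- sqrt(C[i, j]) / denom
    }
  }
  list(rates = rates, se = se,
       occupancy = occupancyProbabilities(seq),
       dwell_frames = as.numeric(nFrom))
}
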