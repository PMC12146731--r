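## Shared fixtures and independent brute-force oracles for the test suite.

## --- topology fixture (synthetic, CHARMM-style restricted grammar) --------

writeFixtureTopology <- function(path) {
  writeLines(c(
    "; synthetic topology fixture",
    "[ defaults ]",
    "  1  2  yes  1.0  1.0",
    "",
    "[ atomtypes ]",
    ";name  at.num  mass      charge  ptype  sigma        epsilon",
    "CAL    20      40.08000  0.00    A      0.24357170954  0.50208",
    "SOD    11      22.98977  0.00    A      0.25160        0.19624",
    "OT     8       15.99940  0.00    A      0.31507        0.63639",
    "",
    "[ nonbond_params ]",
    "; i    j   func  sigma    epsilon",
    "CAL    OC  1     0.30     0.40",
    "CAL    OT  1     0.31     0.42",
    "SOD    OC  1     0.29     0.35",
    "POT    OC  1     0.32     0.30",
    "",
    "[ moleculetype ]",
    "PROT  3",
    "",
    "[ atoms ]",
    ";nr type resnr residu atom cgnr charge  mass",
    "  1  CT2   1   GLU    CB    1  -0.18  12.011",
    "  2  HA2   1   GLU    HB1   1   0.09   1.008",
    "  3  HA2   1   GLU    HB2   1   0.09   1.008",
    "  4  CT2   1   GLU    CG    2  -0.28  12.011",
    "  5  HA2   1   GLU    HG1   2   0.09   1.008",
    "  6  HA2   1   GLU    HG2   2   0.09   1.008",
    "  7  CC    1   GLU    CD    2   0.62  12.011",
    "  8  OC    1   GLU    OE1   2  -0.76  15.999",
    "  9  OC    1   GLU    OE2   2  -0.76  15.999",
    " 10  CAL   2   CA     CA    3   2.00  40.080",
    " 11  SOD   3   NA     NA    4   1.00  22.990",
    " 12  OT    4   SOL    OW    5  -0.834 15.999"), path)
  path
}

## --- brute-force minimum-resistance path over ALL simple paths ------------
## Exhaustive DFS enumeration; only usable on tiny grids (<= ~16 nodes).

enumMinResistance <- function(grid, a, b, temperature) {
  rt <- campath::thermalEnergy(temperature)
  vals <- as.vector(campath::gridValues(grid))
  mask <- as.vector(campath::gridMask(grid))
  dims <- as.integer(gridAxesOf(grid)$n)
  sp <- campath::gridSpacing(grid)
  V <- prod(dims)
  sub <- arrayInd(seq_len(V), dims)
  neighbors <- function(u) {
    out <- integer(0)
    for (v in seq_len(V)) {
      if (v == u || mask[v]) next
      d <- abs(sub[v, ] - sub[u, ])
      if (all(d <= 1) && any(d == 1)) out <- c(out, v)
    }
    out
  }
  edgeCost <- function(u, v) {
    len <- sqrt(sum(((sub[v, ] - sub[u, ]) * sp)^2))
    0.5 * (exp(vals[u] / rt) + exp(vals[v] / rt)) * len
  }
  best <- Inf
  visit <- function(u, cost, seen) {
    if (cost >= best) return(invisible())
    if (u == b) { best <<- cost; return(invisible()) }
    for (v in neighbors(u)) {
      if (seen[v]) next
      seen[v] <- TRUE
      visit(v, cost + edgeCost(u, v), seen)
      seen[v] <- FALSE
    }
  }
  seen <- logical(V); seen[a] <- TRUE
  visit(a, 0, seen)
  best
}

## --- brute-force threshold-percolation minimax barrier --------------------

minimaxOracle <- function(grid, a, b) {
  v <- as.vector(campath::gridValues(grid))
  mask <- as.vector(campath::gridMask(grid))
  dims <- as.integer(gridAxesOf(grid)$n)
  V <- prod(dims)
  sub <- arrayInd(seq_len(V), dims)
  ## adjacency lists (moore)
  adj <- vector("list", V)
  for (u in seq_len(V)) {
    out <- integer(0)
    for (w in seq_len(V)) {
      if (w == u || mask[w]) next
      d <- abs(sub[w, ] - sub[u, ])
      if (all(d <= 1) && any(d == 1)) out <- c(out, w)
    }
    adj[[u]] <- out
  }
  for (tau in sort(unique(v[v >= max(v[a], v[b])]))) {
    ok <- !mask & v <= tau
    if (!ok[a] || !ok[b]) next
    seen <- logical(V); seen[a] <- TRUE; q <- a
    while (length(q) && !seen[b]) {
      u <- q[1]; q <- q[-1]
      for (w in adj[[u]]) if (ok[w] && !seen[w]) { seen[w] <- TRUE; q <- c(q, w) }
    }
    if (seen[b]) return(tau)
  }
  Inf
}

## --- scripted permeation trajectory ---------------------------------------
## One ion doing 3 inward crossings, 1 reverse crossing, and one periodic
## wrap that must NOT be counted (planes at +-5, box 40).

scriptedPermeationTraj <- function() {
  z <- c(10, 6, 0, -6, -10,      # inward event 1
         -12, 12,                # periodic wrap (delta > box/2): no event
         8, 2, -8,               # inward event 2
         -4, 4, 9,               # reverse event
         7, -2, -9,              # inward event 3
         -9)
  campath::ionTrajectory(seq_along(z) * 10, matrix(z, ncol = 1),
                         boxZ = 40, efield = 0.01, lz = 4, fEcc = 1)
}
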