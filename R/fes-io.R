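## Reading and writing gridded free-energy surfaces.
##
## Two dialects are supported:
##  * "plumed_grid": the de-facto grid text layout written by metadynamics
##    post-processing tools -- "#!" header lines declaring FIELDS and
##    per-axis SET min/max/nbins/periodic, then data rows (CV values, the
##    free energy, optionally derivative columns), first CV varying
##    fastest, blank lines between outer-index blocks tolerated.
##  * "tsv": plain tab-separated grid with a one-line JSON header holding
##    the axis definitions, then columns <CVs...>, energy, mask.
##
## The plumed dialect has no mask column, so masked nodes are serialised
## with a large finite sentinel energy; the tsv dialect writes "Inf" plus an
## explicit mask column.

PLUMED_MASK_SENTINEL <- 1e9

#' Read a gridded free-energy surface
#'
#' @param path file path.
#' @param dialect `"plumed_grid"` or `"tsv"`.
#' @return an [EnergyGrid-class]; derivative columns, if present, are
#'   ignored.
#' @seealso [writeFesGrid()], [maskHighEnergy()]
#' @export
readFesGrid <- function(path, dialect = c("plumed_grid", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "plumed_grid") readPlumedGrid(path) else readTsvGrid(path)
}

readPlumedGrid <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#!", lines, value = TRUE)
  if (!length(hdr)) stop("format error: no '#!' header lines in ", path)
  fieldsLine <- grep("^#!\\s+FIELDS\\b", hdr, value = TRUE)
  if (length(fieldsLine) != 1L)
    stop("format error: expected exactly one FIELDS line, offending file: ",
         path)
  fields <- strsplit(trimws(sub("^#!\\s+FIELDS", "", fieldsLine)), "\\s+")[[1]]
  setKv <- list()
  for (ln in grep("^#!\\s+SET\\b", hdr, value = TRUE)) {
    tok <- strsplit(trimws(sub("^#!\\s+SET", "", ln)), "\\s+")[[1]]
    if (length(tok) != 2L) stop("format error in header line: ", ln)
    setKv[[tok[1]]] <- tok[2]
  }
  axNames <- fields[vapply(fields, function(f)
    !is.null(setKv[[paste0("nbins_", f)]]), logical(1))]
  if (!length(axNames))
    stop("format error: no axis with a 'SET nbins_<name>' entry found")
  eneField <- setdiff(fields, c(axNames, grep("^der_", fields, value = TRUE)))
  if (!length(eneField))
    stop("format error: no free-energy field in FIELDS line: ", fieldsLine)
  eneCol <- match(eneField[1], fields)

  getNum <- function(key, ln) {
    v <- setKv[[key]]
    if (is.null(v)) stop("format error: missing header key ", key)
    suppressWarnings(x <- as.numeric(v))
    if (is.na(x)) stop("format error: non-numeric value for ", key, ": ", v)
    x
  }
  axes <- gridAxes(
    name = axNames,
    min = vapply(axNames, function(a) getNum(paste0("min_", a)), 0),
    max = vapply(axNames, function(a) getNum(paste0("max_", a)), 0),
    n = vapply(axNames, function(a) as.integer(getNum(paste0("nbins_", a))), 0L),
    periodic = vapply(axNames, function(a) {
      v <- setKv[[paste0("periodic_", a)]] %||% "false"
      tolower(v) %in% c("true", "yes", "1")
    }, logical(1)))

  dataLines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  nExp <- prod(axes$n)
  if (length(dataLines) != nExp)
    stop(sprintf("dimension error: %d data rows but header declares %s = %d bins",
                 length(dataLines), paste(axes$n, collapse = "x"), nExp))
  rows <- utils::read.table(text = dataLines)
  if (ncol(rows) < eneCol)
    stop("format error: fewer data columns than declared FIELDS")
  vals <- as.numeric(rows[[eneCol]])
  mask <- vals >= PLUMED_MASK_SENTINEL
  energyGrid(axes, vals, mask = mask, unit = "A")
}

readTsvGrid <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("format error: tsv dialect requires a '# {json}' header as line 1")
  hdr <- tryCatch(jsonlite::fromJSON(sub("^#\\s*", "", lines[1]),
                                     simplifyDataFrame = TRUE),
                  error = function(e)
                    stop("format error: malformed JSON header line: ",
                         lines[1]))
  axes <- gridAxes(hdr$axes$name, hdr$axes$min, hdr$axes$max, hdr$axes$n,
                   hdr$axes$periodic)
  dataLines <- lines[-1][nzchar(trimws(lines[-1]))]
  nExp <- prod(axes$n)
  if (length(dataLines) != nExp)
    stop(sprintf("dimension error: %d data rows but header declares %d bins",
                 length(dataLines), nExp))
  rows <- utils::read.table(text = dataLines, sep = "\t")
  d <- nrow(axes)
  vals <- as.numeric(rows[[d + 1L]])
  mask <- as.logical(rows[[d + 2L]])
  vals[mask & !is.finite(vals)] <- Inf
  g <- energyGrid(axes, ifelse(mask, Inf, vals), mask = mask,
                  unit = hdr$unit %||% "A")
  g@values <- array(vals, dim = gridDim(g))
  g
}

#' Write a gridded free-energy surface
#'
#' The written file round-trips through [readFesGrid()]: axes, values and
#' mask are recovered exactly. In the plumed dialect, which has no mask
#' column, masked nodes are written with a sentinel energy of 1e9 kJ/mol;
#' the tsv dialect writes `Inf` plus an explicit mask column.
#'
#' @param grid an [EnergyGrid-class].
#' @param path output file path.
#' @param dialect `"plumed_grid"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeFesGrid <- function(grid, path, dialect = c("plumed_grid", "tsv")) {
  dialect <- match.arg(dialect)
  validObject(grid)
  ax <- grid@axes
  co <- nodeCoordinates(grid)
  vals <- as.vector(grid@values)
  mask <- as.vector(grid@mask)
  if (dialect == "plumed_grid") {
    out <- c(sprintf("#! FIELDS %s free", paste(ax$name, collapse = " ")))
    for (i in seq_len(nrow(ax)))
      out <- c(out,
               sprintf("#! SET min_%s %.17g", ax$name[i], ax$min[i]),
               sprintf("#! SET max_%s %.17g", ax$name[i], ax$max[i]),
               sprintf("#! SET nbins_%s %d", ax$name[i], ax$n[i]),
               sprintf("#! SET periodic_%s %s", ax$name[i],
                       ifelse(ax$periodic[i], "true", "false")))
    v <- ifelse(mask, PLUMED_MASK_SENTINEL, vals)
    rows <- apply(cbind(co, v), 1, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
    writeLines(c(out, rows), path)
  } else {
    hdr <- jsonlite::toJSON(list(axes = ax, unit = grid@unit),
                            auto_unbox = TRUE, digits = NA)
    v <- ifelse(mask & !is.finite(vals), Inf, vals)
    rows <- apply(cbind(co, v, as.integer(mask)), 1, function(r)
      paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(c(paste0("# ", hdr), rows), path)
  }
  invisible(path)
}

#' Mask high-energy grid regions
#'
#' Marks every node with energy above `threshold` as excluded, leaving the
#' stored energies untouched. Already-masked nodes stay masked, so the
#' operation is idempotent and monotone in the threshold.
#'
#' @param grid an [EnergyGrid-class].
#' @param threshold energy threshold in kJ/mol; nodes with `values >
#'   threshold` are masked.
#' @return a new [EnergyGrid-class] with the enlarged mask.
#' @examples
#' g <- energyGrid(gridAxes("x", 0, 2, 3), c(0, 2, 50))
#' gridMask(maskHighEnergy(g, 10))
#' @export
maskHighEnergy <- function(grid, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold))
    stop("threshold must be a single finite number (or +Inf for a no-op)")
  g <- grid
  g@mask <- grid@mask | (grid@values > threshold)
  g
}
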