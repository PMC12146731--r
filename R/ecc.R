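## Electronic continuum correction (ECC) edits to molecular-topology text
## files: charge scaling of ions and charged residues, the calcium sigma
## patch, and removal of pair-override (NBFIX-style) records.
##
## The supported dialect is the restricted topology grammar these edits
## need: bracketed section headers "[ name ]", whitespace-separated record
## lines, ";" comments. All untouched lines are preserved byte-for-byte;
## edits replace single numeric tokens in place so the rest of an edited
## line keeps its exact spacing.

#' TopologyDocument: a parsed molecular-topology text file
#'
#' Stores the raw lines verbatim plus a per-line section map, so that
#' re-serialisation reproduces the input byte-for-byte outside edited
#' records.
#'
#' @slot lines character vector, the file's lines.
#' @slot section character vector, the lower-cased section name each line
#'   belongs to ("" before the first header).
#' @export
setClass("TopologyDocument",
  representation(lines = "character", section = "character"),
  validity = function(object) {
    if (length(object@lines) != length(object@section))
      return("section map must have one entry per line")
    TRUE
  })

#' Read a topology file
#'
#' @param path topology file path.
#' @return a [TopologyDocument-class].
#' @export
readTopology <- function(path) {
  lines <- readLines(path)
  sec <- character(length(lines))
  cur <- ""
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^\\s*\\[\\s*([^]]+?)\\s*\\]", lines[i]))[[1]]
    if (length(m) == 2L) cur <- tolower(m[2])
    sec[i] <- cur
  }
  new("TopologyDocument", lines = lines, section = sec)
}

#' Write a topology document
#'
#' @param doc a [TopologyDocument-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTopology <- function(doc, path) {
  writeLines(doc@lines, path)
  invisible(path)
}

#' @describeIn TopologyDocument-class the raw lines
#' @param x a TopologyDocument.
#' @export
topologyLines <- function(x) x@lines

setMethod("show", "TopologyDocument", function(object) {
  cat(sprintf("TopologyDocument: %d lines, sections: %s\n",
              length(object@lines),
              paste(setdiff(unique(object@section), ""), collapse = ", ")))
})

## record lines (non-blank, non-comment, non-header) of a section
recordLines <- function(doc, section) {
  idx <- which(doc@section == tolower(section))
  txt <- doc@lines[idx]
  keep <- nzchar(trimws(sub(";.*$", "", txt))) & !grepl("^\\s*\\[", txt)
  idx[keep]
}

## tokenise the pre-comment part of a line, keeping character positions
lineTokens <- function(line) {
  body <- sub("(;.*)$", "", line)
  m <- gregexpr("\\S+", body)[[1]]
  if (m[1] == -1L) return(data.frame(token = character(), start = integer(),
                                     stop = integer()))
  data.frame(token = regmatches(body, gregexpr("\\S+", body))[[1]],
             start = as.integer(m),
             stop = as.integer(m) + attr(m, "match.length") - 1L,
             stringsAsFactors = FALSE)
}

## Replace one token in a line. When the replacement (plus a separating
## space) fits in the slot up to the next token, it is right-padded so the
## following columns keep their byte positions -- then an edit-and-revert
## cycle reproduces the original line exactly. Otherwise the token is
## swapped in place and the rest of the line shifts.
replaceToken <- function(line, tok, replacement, nextStart = NA) {
  if (!is.na(nextStart) && nchar(replacement) < nextStart - tok$start)
    return(paste0(substr(line, 1L, tok$start - 1L),
                  formatC(replacement, width = nextStart - tok$start,
                          flag = "-"),
                  substring(line, nextStart)))
  paste0(substr(line, 1L, tok$start - 1L), replacement,
         substring(line, tok$stop + 1L))
}

tokenNextStart <- function(tk, i) {
  if (i < nrow(tk)) tk$start[i + 1L] else NA
}

#' Default charged-residue terminal-atom table
#'
#' The side-chain terminal atom groups that carry the net +-1 charge of a
#' charged residue and are scaled together with the ions. The groups
#' follow the usual additive-force-field charge partitioning (carboxylate
#' group for Asp/Glu, ammonium for Lys, guanidinium for Arg, imidazolium
#' for doubly protonated His); the table is an editable convention.
#'
#' @return data.frame with columns `residue` and `atom`.
#' @export
chargedResidueAtoms <- function() {
  rbind(
    data.frame(residue = "GLU", atom = c("CG", "HG1", "HG2", "CD", "OE1", "OE2")),
    data.frame(residue = "ASP", atom = c("CB", "HB1", "HB2", "CG", "OD1", "OD2")),
    data.frame(residue = "LYS", atom = c("CE", "HE1", "HE2", "NZ", "HZ1", "HZ2", "HZ3")),
    data.frame(residue = "ARG", atom = c("CD", "HD1", "HD2", "NE", "HE", "CZ",
                                         "NH1", "HH11", "HH12", "NH2", "HH21", "HH22")),
    data.frame(residue = "HSP", atom = c("CB", "HB1", "HB2", "CD2", "HD2", "CG",
                                         "NE2", "HE2", "ND1", "HD1", "CE1", "HE1")))
}

#' ECC charge-scaling rule
#'
#' @param fEcc scaling factor in (0, 1].
#' @param ions ion residue/atom names to scale (matched against the
#'   residue or atom name of `[ atoms ]` records).
#' @param residueAtoms data.frame (`residue`, `atom`) of charged-residue
#'   terminal atoms; default [chargedResidueAtoms()].
#' @return validated rule list for [scaleCharges()].
#' @export
scalingRule <- function(fEcc = 0.87, ions = c("CA", "CAL", "NA", "SOD", "CL", "CLA"),
                        residueAtoms = chargedResidueAtoms()) {
  if (fEcc <= 0 || fEcc > 1) stop("fEcc must be in (0, 1]")
  list(fEcc = fEcc, ions = toupper(ions),
       residueAtoms = data.frame(residue = toupper(residueAtoms$residue),
                                 atom = toupper(residueAtoms$atom)))
}

## GROMACS [ atoms ] record: nr type resnr residue atom cgnr charge (mass..)
ATOMS_RESIDUE_COL <- 4L
ATOMS_ATOM_COL <- 5L
ATOMS_CHARGE_COL <- 7L

#' Scale charges of ions and charged-residue terminal atoms
#'
#' Multiplies the charge of every selected `[ atoms ]` record by the rule's
#' `fEcc`; all other records and all unedited bytes are untouched. A
#' selection that matches nothing is an error, so a typo cannot silently
#' skip the scaling.
#'
#' @param doc a [TopologyDocument-class].
#' @param rule a [scalingRule()].
#' @return list with `doc` (edited document) and `audit` (data.frame
#'   `line`, `residue`, `atom`, `old`, `new`).
#' @export
scaleCharges <- function(doc, rule) {
  idx <- recordLines(doc, "atoms")
  audit <- list()
  lines <- doc@lines
  for (i in idx) {
    tk <- lineTokens(lines[i])
    if (nrow(tk) < ATOMS_CHARGE_COL) next
    res <- toupper(tk$token[ATOMS_RESIDUE_COL])
    atm <- toupper(tk$token[ATOMS_ATOM_COL])
    hit <- res %in% rule$ions || atm %in% rule$ions ||
      any(rule$residueAtoms$residue == res & rule$residueAtoms$atom == atm)
    if (!hit) next
    old <- as.numeric(tk$token[ATOMS_CHARGE_COL])
    newV <- old * rule$fEcc
    lines[i] <- replaceToken(lines[i], tk[ATOMS_CHARGE_COL, ],
                             sprintf("%.10g", newV),
                             tokenNextStart(tk, ATOMS_CHARGE_COL))
    audit[[length(audit) + 1L]] <-
      data.frame(line = i, residue = res, atom = atm, old = old, new = newV)
  }
  if (!length(audit))
    stop("no-op: the scaling rule selected no atoms; check ion and residue names")
  doc@lines <- lines
  list(doc = doc, audit = do.call(rbind, audit))
}

#' Patch the calcium Lennard-Jones sigma
#'
#' Replaces the sigma of the calcium `[ atomtypes ]` record (second-to-last
#' numeric column, epsilon untouched), e.g. with the ECC-refit value of
#' 0.27 nm.
#'
#' @param doc a [TopologyDocument-class].
#' @param newSigma replacement sigma in nm (default 0.27).
#' @param caNames type names recognised as calcium.
#' @return list with `doc` and a one-row `audit` data.frame.
#' @export
patchCaSigma <- function(doc, newSigma = 0.27, caNames = c("CA", "CAL")) {
  idx <- recordLines(doc, "atomtypes")
  lines <- doc@lines
  for (i in idx) {
    tk <- lineTokens(lines[i])
    if (nrow(tk) < 3L) next
    if (!(toupper(tk$token[1]) %in% toupper(caNames))) next
    sigCol <- nrow(tk) - 1L
    old <- as.numeric(tk$token[sigCol])
    lines[i] <- replaceToken(lines[i], tk[sigCol, ],
                             sprintf("%.12g", newSigma),
                             tokenNextStart(tk, sigCol))
    doc@lines <- lines
    return(list(doc = doc,
                audit = data.frame(line = i, type = tk$token[1],
                                   old = old, new = newSigma)))
  }
  stop("not found: no calcium record in [ atomtypes ]")
}

#' Remove pair-override (NBFIX) records for given species
#'
#' Deletes `[ nonbond_params ]` / `[ pairtypes ]` records in which one
#' partner is a listed ion species and the other matches the oxygen
#' pattern; unrelated overrides are retained. Zero removals is allowed and
#' reported.
#'
#' @param doc a [TopologyDocument-class].
#' @param species ion type names whose oxygen overrides are removed.
#' @param oxygenPattern regex identifying oxygen type names (default
#'   `"^O"`).
#' @return list with `doc` and `removed` (count).
#' @export
stripNbfix <- function(doc, species = c("CA", "CAL", "NA", "SOD"),
                       oxygenPattern = "^O") {
  idx <- c(recordLines(doc, "nonbond_params"), recordLines(doc, "pairtypes"))
  drop <- integer(0)
  for (i in idx) {
    tk <- lineTokens(doc@lines[i])
    if (nrow(tk) < 2L) next
    a <- toupper(tk$token[1]); b <- toupper(tk$token[2])
    isIon <- c(a, b) %in% toupper(species)
    isOx <- grepl(oxygenPattern, c(a, b), ignore.case = TRUE)
    if ((isIon[1] && isOx[2]) || (isIon[2] && isOx[1]))
      drop <- c(drop, i)
  }
  if (length(drop)) {
    doc@lines <- doc@lines[-drop]
    doc@section <- doc@section[-drop]
  }
  list(doc = doc, removed = length(drop))
}

#' Total charge of the [ atoms ] records
#'
#' @param doc a [TopologyDocument-class].
#' @return sum of the charge column over all atom records.
#' @export
totalCharge <- function(doc) {
  idx <- recordLines(doc, "atoms")
  s <- 0
  for (i in idx) {
    tk <- lineTokens(doc@lines[i])
    if (nrow(tk) >= ATOMS_CHARGE_COL)
      s <- s + as.numeric(tk$token[ATOMS_CHARGE_COL])
  }
  s
}
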