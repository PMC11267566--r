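## Force-field table I/O and parameter lookup.

#' Read a force-field parameter table
#'
#' Parses the whitespace-delimited plain-text force-field format. The file
#' holds five sections, each introduced by a bracketed header:
#'
#' \preformatted{
#' [LJ]        type  C12  C6            # self-pair coefficients
#' [CHARGES]   type  q                  # default partial charge
#' [BONDS]     type_a  type_b  k  b0    # E = k (b - b0)^2
#' [ANGLES]    center  k  theta0        # E = k (theta - theta0)^2, degrees
#' [TORSIONS]  type_a  type_b  k  m  phase   # E = k (1 + cos(m phi - phase))
#' }
#'
#' Lines starting with `#` and blank lines are ignored. Cross-pair
#' Lennard-Jones coefficients are formed by geometric-mean combination of the
#' self terms. The parse is strict: wrong field counts, unknown sections or
#' non-numeric values raise an error naming the offending line.
#'
#' @param path file path; default is the bundled simplified united-atom set.
#' @return a [ForceField-class]
#' @export
readForceField <- function(path = system.file("extdata", "ff_ua.dat",
                                              package = "cleavescan")) {
  if (!file.exists(path)) stop("force-field file not found: ", path)
  raw <- readLines(path)
  lj <- data.frame(type = character(0), c12 = numeric(0), c6 = numeric(0))
  charges <- numeric(0)
  bonds <- data.frame(type_a = character(0), type_b = character(0),
                      k = numeric(0), b0 = numeric(0))
  angles <- data.frame(center = character(0), k = numeric(0), theta0 = numeric(0))
  torsions <- data.frame(type_a = character(0), type_b = character(0),
                         k = numeric(0), mult = integer(0), phase = numeric(0))
  section <- NA_character_
  for (i in seq_along(raw)) {
    line <- sub("#.*$", "", raw[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      section <- sub("^\\[(.*)\\]$", "\\1", line)
      if (!section %in% c("LJ", "CHARGES", "BONDS", "ANGLES", "TORSIONS"))
        stop("unknown section '", section, "' at line ", i)
      next
    }
    if (is.na(section)) stop("data before first section header at line ", i)
    tok <- strsplit(line, "\\s+")[[1]]
    num <- function(x) {
      v <- suppressWarnings(as.numeric(x))
      if (anyNA(v)) stop("non-numeric value at line ", i, ": ", raw[i])
      v
    }
    if (section == "LJ") {
      if (length(tok) != 3) stop("[LJ] line needs 3 fields at line ", i)
      lj <- rbind(lj, data.frame(type = tok[1], c12 = num(tok[2]), c6 = num(tok[3])))
    } else if (section == "CHARGES") {
      if (length(tok) != 2) stop("[CHARGES] line needs 2 fields at line ", i)
      charges[tok[1]] <- num(tok[2])
    } else if (section == "BONDS") {
      if (length(tok) != 4) stop("[BONDS] line needs 4 fields at line ", i)
      bonds <- rbind(bonds, data.frame(type_a = tok[1], type_b = tok[2],
                                       k = num(tok[3]), b0 = num(tok[4])))
    } else if (section == "ANGLES") {
      if (length(tok) != 3) stop("[ANGLES] line needs 3 fields at line ", i)
      angles <- rbind(angles, data.frame(center = tok[1], k = num(tok[2]),
                                         theta0 = num(tok[3])))
    } else {
      if (length(tok) != 5) stop("[TORSIONS] line needs 5 fields at line ", i)
      torsions <- rbind(torsions, data.frame(type_a = tok[1], type_b = tok[2],
                                             k = num(tok[3]),
                                             mult = as.integer(num(tok[4])),
                                             phase = num(tok[5])))
    }
  }
  new("ForceField", lj = lj, charges = charges, bonds = bonds,
      angles = angles, torsions = torsions, coulomb_prefactor = 138.935)
}

#' The bundled simplified united-atom force field
#'
#' Convenience wrapper around [readForceField()] for the parameter table
#' shipped with the package: ~13 nonbonded bead types covering the peptide
#' backbone (N, H, CA, C, O), terminal caps (CH3), one side-chain bead per
#' residue class (apolar CB, polar CBP, aromatic CBA, sulfur CBS, cationic
#' CBQ, anionic CBN) and a neutral wall type (WAL) used by the synthetic
#' receptor fixtures.
#'
#' @return a [ForceField-class]
#' @export
defaultForceField <- function() {
  ff <- getOption("cleavescan.ff.cache")
  if (!is.null(ff)) return(ff)
  ff <- readForceField()
  options(cleavescan.ff.cache = ff)
  ff
}

## LJ C12/C6 for arbitrary type pairs (geometric-mean combination).
ljPair <- function(ff, types_i, types_j) {
  idx_i <- match(types_i, ff@lj$type)
  idx_j <- match(types_j, ff@lj$type)
  bad <- unique(c(types_i[is.na(idx_i)], types_j[is.na(idx_j)]))
  if (length(bad) > 0)
    stop("no LJ parameters for nb type(s): ", paste(bad, collapse = ", "))
  list(c12 = sqrt(ff@lj$c12[idx_i] * ff@lj$c12[idx_j]),
       c6 = sqrt(ff@lj$c6[idx_i] * ff@lj$c6[idx_j]))
}

## Bond parameters for type pairs; key is order-independent.
bondPair <- function(ff, ta, tb) {
  key <- paste(pmin(ta, tb), pmax(ta, tb))
  tab_key <- paste(pmin(ff@bonds$type_a, ff@bonds$type_b),
                   pmax(ff@bonds$type_a, ff@bonds$type_b))
  idx <- match(key, tab_key)
  if (anyNA(idx))
    stop("no bond parameters for type pair(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  list(k = ff@bonds$k[idx], b0 = ff@bonds$b0[idx])
}

## Angle parameters keyed by the central atom's nb type.
angleCenter <- function(ff, center) {
  idx <- match(center, ff@angles$center)
  if (anyNA(idx))
    stop("no angle parameters for center type(s): ",
         paste(unique(center[is.na(idx)]), collapse = ", "))
  list(k = ff@angles$k[idx], theta0 = deg2rad(ff@angles$theta0[idx]))
}

## Torsion parameters for central-bond type pairs; NA row where no term applies.
torsionPair <- function(ff, ta, tb) {
  key <- paste(pmin(ta, tb), pmax(ta, tb))
  tab_key <- paste(pmin(ff@torsions$type_a, ff@torsions$type_b),
                   pmax(ff@torsions$type_a, ff@torsions$type_b))
  idx <- match(key, tab_key)
  list(k = ff@torsions$k[idx], mult = ff@torsions$mult[idx],
       phase = deg2rad(ff@torsions$phase[idx]))
}
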