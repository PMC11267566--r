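## Structure I/O (PDB dialect, bond sidecars), selection, flexible-span rule.

## Map PDB atom names (+ residue names) onto the bundled nb types.
sideBeadType <- function(resname) {
  switch(resname,
         ALA = , VAL = , LEU = , ILE = , PRO = "CB",
         SER = , THR = , ASN = , GLN = , HIS = "CBP",
         PHE = , TYR = , TRP = "CBA",
         MET = , CYS = "CBS",
         LYS = , ARG = "CBQ",
         ASP = , GLU = "CBN",
         "CB")
}

assignTypes <- function(atoms, ff = defaultForceField()) {
  nb <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    nm <- atoms$name[i]; rn <- atoms$resname[i]
    nb[i] <- if (rn == "WAL") "WAL"
    else if (nm %in% c("N", "H", "CA", "C", "O", "CH3")) nm
    else if (nm == "CB") sideBeadType(rn)
    else stop("cannot assign a nonbonded type to atom '", nm,
              "' in residue ", rn)
  }
  atoms$nb_type <- nb
  atoms$charge <- unname(ff@charges[nb])
  if (anyNA(atoms$charge))
    stop("no default charge for type(s): ",
         paste(unique(nb[is.na(atoms$charge)]), collapse = ", "))
  atoms
}

elementOf <- function(name) {
  ifelse(name == "H", "H",
         ifelse(name == "N", "N",
                ifelse(name == "O", "O",
                       ifelse(name == "W", "X", "C"))))
}

## Distance-based bond inference for structures lacking a sidecar:
## heavy-heavy pairs closer than 0.18 nm, X-H pairs closer than 0.12 nm.
inferBonds <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  out <- list()
  for (i in seq_len(n - 1)) {
    d2 <- rowSums(sweep(xyz[(i + 1):n, , drop = FALSE], 2, xyz[i, ])^2)
    lim <- ifelse(atoms$element[i] == "H" | atoms$element[(i + 1):n] == "H",
                  0.12^2, 0.18^2) # nm^2
    hit <- which(d2 < lim)
    if (length(hit) > 0) out[[length(out) + 1]] <- cbind(i, i + hit)
  }
  if (length(out) == 0) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, out)
  colnames(m) <- NULL
  m
}

bondSidecarPath <- function(path) paste0(path, ".bonds")

#' Read a PDB file into a Structure or Ensemble
#'
#' Parses ATOM/HETATM records (via bio3d), converting coordinates from
#' Angstrom to the package's internal nanometre unit. A file with more than
#' one MODEL block yields an [Ensemble-class]; a single-model file yields a
#' [Structure-class]. Insertion codes are rejected. Nonbonded types and
#' default charges are assigned from the force field by atom and residue
#' name. Bond topology is read from a two-column sidecar file
#' (`<path>.bonds`, 1-based atom serials) when present; otherwise bonds are
#' inferred from interatomic distances.
#'
#' @param path PDB file path
#' @param ff a [ForceField-class] used for type/charge assignment
#' @param label structure label (defaults to the file name)
#' @return a [Structure-class] or [Ensemble-class]
#' @export
readPDB <- function(path, ff = defaultForceField(),
                    label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  atom_lines <- grep("^(ATOM  |HETATM)", lines)
  for (i in atom_lines) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))))
      stop("malformed ATOM/HETATM record at line ", i, ": ", ln)
  }
  n_model <- sum(grepl("^MODEL", lines))
  if (n_model > 1) {
    counts <- integer(0)
    cur <- 0L; inmodel <- FALSE
    for (ln in lines) {
      if (grepl("^MODEL", ln)) { inmodel <- TRUE; cur <- 0L }
      else if (grepl("^ENDMDL", ln)) { inmodel <- FALSE; counts <- c(counts, cur) }
      else if (inmodel && grepl("^(ATOM  |HETATM)", ln)) cur <- cur + 1L
    }
    if (length(unique(counts)) > 1)
      stop("inconsistent atom count across MODEL blocks: ",
           paste(counts, collapse = ", "))
  }
  pdb <- bio3d::read.pdb(path, multi = n_model > 1, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported")
  atoms <- data.frame(
    name = at$elety,
    element = elementOf(at$elety),
    resid = as.integer(at$resno),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x / 10, y = at$y / 10, z = at$z / 10,
    charge = 0, nb_type = "",
    stringsAsFactors = FALSE)
  atoms <- assignTypes(atoms, ff)
  sidecar <- bondSidecarPath(path)
  bonds <- if (file.exists(sidecar)) {
    b <- as.matrix(read.table(sidecar, col.names = c("i", "j")))
    storage.mode(b) <- "integer"; colnames(b) <- NULL; b
  } else inferBonds(atoms)
  s <- Structure(atoms, bonds, label = label)
  if (n_model > 1) {
    xyz <- pdb$xyz / 10
    frames <- lapply(seq_len(nrow(xyz)),
                     function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE))
    coords(s) <- frames[[1]]
    return(Ensemble(s, frames,
                    provenance = data.frame(replicate = 1L,
                                            frame = seq_along(frames),
                                            seed = NA_integer_)))
  }
  s
}

formatAtomName <- function(name) {
  ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
}

pdbAtomLines <- function(atoms, xyz) {
  sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(atoms)), formatAtomName(atoms$name), "",
          atoms$resname, atoms$chain, atoms$resid, "",
          xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10, 1, 0,
          atoms$element)
}

#' Write a Structure or Ensemble as a PDB file
#'
#' Coordinates are converted from nm to Angstrom (3 decimals, the PDB fixed
#' format). An [Ensemble-class] is written as one MODEL/ENDMDL block per
#' frame. When the object carries bonds, a two-column sidecar file
#' (`<path>.bonds`, 1-based atom serials) is written alongside so that the
#' read/write round trip preserves topology. Chain ids longer than one
#' character do not fit the dialect and raise an error.
#'
#' @param x a [Structure-class] or [Ensemble-class]
#' @param path output file path
#' @return invisibly, `path`
#' @export
writePDB <- function(x, path) {
  topo <- if (is(x, "Ensemble")) x@topology else x
  atoms <- topo@atoms
  if (any(nchar(atoms$chain) != 1))
    stop("PDB chain ids must be exactly one character")
  if (any(atoms$resid > 9999)) stop("residue number exceeds PDB field width")
  lines <- character(0)
  if (is(x, "Ensemble")) {
    for (f in seq_along(x@frames)) {
      lines <- c(lines, sprintf("MODEL     %4d", f),
                 pdbAtomLines(atoms, x@frames[[f]]), "ENDMDL")
    }
  } else {
    lines <- pdbAtomLines(atoms, coords(x))
  }
  lines <- c(lines, "END")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  if (nrow(topo@bonds) > 0)
    write.table(topo@bonds, bondSidecarPath(path),
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Select atoms by a query expression
#'
#' The query is a conjunction of clauses joined with `" and "`:
#' \itemize{
#'   \item `name N CA C` — atom-name membership
#'   \item `resid 1:12` or `resid 3 7 9` — residue-index set (per chain)
#'   \item `chain A` — chain membership
#'   \item `backbone3` — shorthand for `name N CA C`
#'   \item `fit4` — shorthand for `name C O N H` (the ligation fit set)
#'   \item `all` — every atom
#' }
#' The result is an ordered atom-index vector in structure order; an empty
#' selection returns `integer(0)`, not an error.
#'
#' @param structure a [Structure-class]
#' @param query character selection expression
#' @return integer vector of atom indices
#' @examples
#' # selectAtoms(pep, "backbone3 and resid 1:4")
#' @export
selectAtoms <- function(structure, query) {
  a <- structure@atoms
  keep <- rep(TRUE, nrow(a))
  for (clause in strsplit(query, "\\s+and\\s+")[[1]]) {
    clause <- trimws(clause)
    if (clause == "backbone3") clause <- "name N CA C"
    if (clause == "fit4") clause <- "name C O N H"
    if (clause == "all") next
    tok <- strsplit(clause, "\\s+")[[1]]
    kind <- tok[1]; args <- tok[-1]
    if (kind == "name") {
      keep <- keep & a$name %in% args
    } else if (kind == "resid") {
      ids <- unlist(lapply(args, function(x) {
        if (grepl(":", x)) {
          rng <- as.integer(strsplit(x, ":")[[1]])
          seq(rng[1], rng[2])
        } else as.integer(x)
      }))
      keep <- keep & a$resid %in% ids
    } else if (kind == "chain") {
      keep <- keep & a$chain %in% args
    } else {
      stop("unknown selection clause: ", clause)
    }
  }
  which(keep)
}

#' Length of the flexible N-terminal span from secondary structure
#'
#' Counts the leading residues with no assigned secondary structure (coil,
#' 'C') in a per-residue H/E/C string starting at residue 1, flooring the
#' result at `min_len`: the active-site template binds at least four
#' substrate residues N-terminal of the body, so at least that many residues
#' are treated as flexible even when they sit in secondary structure.
#'
#' @param secondary_structure character scalar over the alphabet H/E/C
#' @param min_len minimum span (default 4)
#' @return integer residue count
#' @examples
#' determineFlexibleSpan("CCCCCCCCCCCCHHHHEEE")  # 12
#' determineFlexibleSpan("HHHHHHHH")             # 4 (floor)
#' @export
determineFlexibleSpan <- function(secondary_structure, min_len = 4L) {
  if (!is.character(secondary_structure) || length(secondary_structure) != 1 ||
      !nzchar(secondary_structure))
    stop("secondary_structure must be a non-empty string")
  ch <- strsplit(secondary_structure, "")[[1]]
  if (!all(ch %in% c("H", "E", "C")))
    stop("secondary structure string may contain only H, E, C")
  lead <- match(FALSE, ch == "C", nomatch = length(ch) + 1L) - 1L
  max(as.integer(lead), as.integer(min_len))
}
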