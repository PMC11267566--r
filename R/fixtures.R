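## Synthetic structure generators: ideal-geometry peptides, a rigid helical
## body stub, and grooved receptor templates with a bound 9-residue peptide.

aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

## Ideal internal coordinates (nm, degrees): literature-standard values.
GEO <- list(
  b_n_ca = 0.147, b_ca_c = 0.153, b_c_n = 0.133, b_c_o = 0.123,
  b_n_h = 0.100, b_ca_cb = 0.153, b_ca_cba = 0.200, b_c_ch3 = 0.152,
  a_ca_c_n = 116, a_c_n_ca = 122, a_n_ca_c = 111, a_ca_c_o = 121,
  a_c_n_h = 119, a_n_ca_cb = 110, omega = 180
)

resSequence <- function(sequence) {
  if (length(sequence) == 1 && !sequence %in% aa1to3) {
    codes <- strsplit(sequence, "")[[1]]
    res <- unname(aa1to3[codes])
    if (anyNA(res))
      stop("unknown residue code(s): ",
           paste(codes[is.na(res)], collapse = ", "))
    res
  } else {
    bad <- setdiff(sequence, aa1to3)
    if (length(bad) > 0) stop("unknown residue code(s): ",
                              paste(bad, collapse = ", "))
    sequence
  }
}

## Build a capped chain with given per-residue phi/psi (degrees).
## Atom order: ACE(CH3,C,O) resid 0; per residue N,H,CA,[CB],C,O; NME(N,H,CH3)
## resid n+1. Returns a Structure with full bond topology, or (coords_only)
## just the coordinate matrix in the same atom order.
buildChain <- function(resnames, phi, psi, chain = "A", label = "peptide",
                       coords_only = FALSE) {
  n <- length(resnames)
  stopifnot(length(phi) == n, length(psi) == n)
  n_max <- 3L + 6L * n + 3L
  xyz <- matrix(0, n_max, 3)
  a_name <- character(n_max); a_resid <- integer(n_max)
  a_resname <- character(n_max)
  bonds <- matrix(0L, n_max, 2); nb <- 0L
  idx <- 0L
  addAtom <- function(name, resid, resname, pos) {
    idx <<- idx + 1L
    xyz[idx, ] <<- pos
    if (!coords_only) {
      a_name[idx] <<- name; a_resid[idx] <<- resid; a_resname[idx] <<- resname
    }
    idx
  }
  addBond <- function(i, j) {
    if (!coords_only) { nb <<- nb + 1L; bonds[nb, ] <<- c(i, j) }
  }
  pos <- function(i) xyz[i, ]

  ## ACE cap, residue 0
  i_ch3 <- addAtom("CH3", 0L, "ACE", c(0, 0, 0))
  i_c <- addAtom("C", 0L, "ACE", c(GEO$b_c_ch3, 0, 0))
  o_dir <- c(cos(deg2rad(180 - 121)), sin(deg2rad(180 - 121)), 0)
  i_o <- addAtom("O", 0L, "ACE", pos(i_c) + GEO$b_c_o * o_dir)
  addBond(i_ch3, i_c); addBond(i_c, i_o)

  prev <- list(ca = i_ch3, c = i_c, o = i_o, psi_ref = i_o)
  for (r in seq_len(n)) {
    rn <- resnames[r]
    ## N from the previous carbonyl; for residue 1 the psi-like torsion is
    ## measured O(cap)-CH3-C-N = 180 (planar amide), afterwards psi_{r-1}.
    if (r == 1) {
      i_n <- addAtom("N", r, rn, placeAtom(pos(i_o), pos(i_ch3), pos(i_c),
                                           GEO$b_c_n, GEO$a_ca_c_n, 180))
    } else {
      i_n <- addAtom("N", r, rn, placeAtom(pos(prev$n), pos(prev$ca), pos(prev$c),
                                           GEO$b_c_n, GEO$a_ca_c_n, psi[r - 1]))
    }
    addBond(prev$c, i_n)
    i_h <- addAtom("H", r, rn, placeAtom(pos(prev$ca), pos(prev$c), pos(i_n),
                                         GEO$b_n_h, GEO$a_c_n_h, 0))
    addBond(i_n, i_h)
    i_ca <- addAtom("CA", r, rn, placeAtom(pos(prev$ca), pos(prev$c), pos(i_n),
                                           GEO$b_n_ca, GEO$a_c_n_ca, GEO$omega))
    addBond(i_n, i_ca)
    i_cb <- NA_integer_
    if (rn != "GLY") {
      blen <- if (sideBeadType(rn) == "CBA") GEO$b_ca_cba else GEO$b_ca_cb
      i_cb <- addAtom("CB", r, rn, placeAtom(pos(prev$c), pos(i_n), pos(i_ca),
                                             blen, GEO$a_n_ca_cb,
                                             phi[r] - 122))
      addBond(i_ca, i_cb)
    }
    i_cc <- addAtom("C", r, rn, placeAtom(pos(prev$c), pos(i_n), pos(i_ca),
                                          GEO$b_ca_c, GEO$a_n_ca_c, phi[r]))
    addBond(i_ca, i_cc)
    i_oo <- addAtom("O", r, rn, placeAtom(pos(i_n), pos(i_ca), pos(i_cc),
                                          GEO$b_c_o, GEO$a_ca_c_o,
                                          psi[r] + 180))
    addBond(i_cc, i_oo)
    prev <- list(n = i_n, ca = i_ca, c = i_cc)
  }

  ## NME cap, residue n+1
  i_n <- addAtom("N", n + 1L, "NME", placeAtom(pos(prev$n), pos(prev$ca),
                                               pos(prev$c), GEO$b_c_n,
                                               GEO$a_ca_c_n, psi[n]))
  addBond(prev$c, i_n)
  i_h <- addAtom("H", n + 1L, "NME", placeAtom(pos(prev$ca), pos(prev$c),
                                               pos(i_n), GEO$b_n_h,
                                               GEO$a_c_n_h, 0))
  addBond(i_n, i_h)
  i_me <- addAtom("CH3", n + 1L, "NME", placeAtom(pos(prev$ca), pos(prev$c),
                                                  pos(i_n), GEO$b_n_ca,
                                                  GEO$a_c_n_ca, GEO$omega))
  addBond(i_n, i_me)

  if (coords_only) return(xyz[seq_len(idx), , drop = FALSE])
  keep <- seq_len(idx)
  atoms <- data.frame(name = a_name[keep], element = elementOf(a_name[keep]),
                      resid = a_resid[keep], resname = a_resname[keep],
                      chain = chain, x = xyz[keep, 1], y = xyz[keep, 2],
                      z = xyz[keep, 3], charge = 0, nb_type = "",
                      stringsAsFactors = FALSE)
  atoms <- assignTypes(atoms)
  Structure(atoms, bonds[seq_len(nb), , drop = FALSE], label = label)
}

#' Build an ideal-geometry peptide
#'
#' Constructs a peptide with literature-standard bond lengths and angles in
#' either an extended (phi, psi = -120, 120 degrees) or alpha-helical
#' (-57, -47) backbone conformation. Side chains are single united-atom
#' beads at CB (none for glycine). With `capped = TRUE` (the default) the
#' chain carries a methyl-acetate cap (ACE: CH3, C, O; residue 0) at the
#' N-terminus and an N-methyl cap (NME: N, H, CH3; residue n+1) at the
#' C-terminus.
#'
#' @param sequence one-letter string (e.g. `"VRSSSRTPSDKPV"`) or character
#'   vector of 3-letter codes
#' @param conformation `"extended"` or `"helical"`
#' @param capped logical; add ACE/NME caps
#' @param chain chain id (single character)
#' @param phi,psi optional explicit per-residue backbone torsions (degrees),
#'   overriding `conformation`
#' @return a [Structure-class]
#' @examples
#' pep <- makePeptide("VRSSS", "extended")
#' @export
makePeptide <- function(sequence, conformation = c("extended", "helical"),
                        capped = TRUE, chain = "A", phi = NULL, psi = NULL) {
  conformation <- match.arg(conformation)
  res <- resSequence(sequence)
  n <- length(res)
  if (is.null(phi))
    phi <- rep(if (conformation == "extended") -120 else -57, n)
  if (is.null(psi))
    psi <- rep(if (conformation == "extended") 120 else -47, n)
  code1 <- setNames(names(aa1to3), aa1to3)
  s <- buildChain(res, phi, psi, chain = chain,
                  label = paste0("peptide-", paste0(code1[res], collapse = "")))
  if (!capped) s <- dropResidues(s, c(0L, n + 1L))
  s
}

## Remove whole residues (by resid) and remap bonds.
dropResidues <- function(structure, resids) {
  keep <- !(structure@atoms$resid %in% resids)
  keepStructureAtoms(structure, which(keep))
}

## Subset a structure to given atom indices (order preserved), remapping bonds.
keepStructureAtoms <- function(structure, idx) {
  map <- match(seq_len(nrow(structure@atoms)), idx)
  b <- structure@bonds
  if (nrow(b) > 0) {
    b2 <- cbind(map[b[, 1]], map[b[, 2]])
    b2 <- b2[!is.na(b2[, 1]) & !is.na(b2[, 2]), , drop = FALSE]
  } else b2 <- matrix(integer(0), 0, 2)
  Structure(structure@atoms[idx, , drop = FALSE], b2, label = structure@label)
}

#' Build a rigid body stub: a helical bulk with a native N-terminal tail
#'
#' Stands in for the folded bulk of a protein of interest. The first `tail`
#' residues adopt an extended conformation (the body's own, "native"
#' N-terminal conformation, available for self-ligation checks); the
#' remaining residues form an alpha helix. The sequence is drawn
#' reproducibly from a fixed residue alphabet under `seed`. The construction
#' is self-clash-free: all heavy-atom nonbonded pairs (more than three bonds
#' apart) are farther than 0.25 nm (helical hydrogen bonds bring amide H and
#' carbonyl O closer, which is a contact, not a clash).
#'
#' @param n_residues total residue count (default 30)
#' @param seed integer; same seed, identical body
#' @param tail residues in the extended N-terminal tail (default 5)
#' @param chain chain id
#' @return a capped [Structure-class]
#' @export
makeBody <- function(n_residues = 30L, seed = 1L, tail = 5L, chain = "A") {
  stopifnot(n_residues > tail + 3)
  alphabet <- c("ALA", "SER", "LEU", "LYS", "ASP", "VAL", "THR", "GLY")
  ## draw the sequence under a local RNG state
  old <- .Random.seed_exists()
  set.seed(seed)
  resnames <- sample(alphabet, n_residues, replace = TRUE)
  restoreSeed(old)
  phi <- c(rep(-120, tail), rep(-57, n_residues - tail))
  psi <- c(rep(120, tail), rep(-47, n_residues - tail))
  buildChain(resnames, phi, psi, chain = chain,
             label = sprintf("body-n%d-seed%d", n_residues, seed))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Build a synthetic grooved receptor with a bound 9-residue template peptide
#'
#' Stands in for a protease active-site template: an extended 9-residue
#' peptide (labelled P5..P1, P1'..P4'; the scissile bond joins the C of P1
#' to the N of P1') lies in a channel formed by neutral Lennard-Jones wall
#' atoms. Walls flank the recognition side (P5..P1' collar) so that grafted
#' substrate conformers must thread the channel near the scissile bond but
#' exit freely beyond it. `blocked = TRUE` places an obstruction atom inside
#' the S1' pocket, clashing with any grafted conformer.
#'
#' @param groove_width channel width (wall-to-wall, nm; default 1.2)
#' @param blocked logical; obstruct the S1' pocket
#' @param wall_spacing spacing of wall atoms (nm)
#' @return an [ActiveSiteTemplate-class]
#' @export
makeReceptor <- function(groove_width = 1.2, blocked = FALSE,
                         wall_spacing = 0.3) {
  pep <- makePeptide(strrep("A", 9), "extended", capped = FALSE, chain = "P")
  labels <- p_labels()
  ## P-labels map onto resids 1..9; scissile bond between resid 5 and 6
  resids <- setNames(1:9, labels)
  ## canonicalize: CA-trace centroid at the origin, principal axis along +x
  ## (N- to C-terminal), so the channel geometry below is well defined
  pa <- pep@atoms
  pxyz <- coords(pep)
  ca_idx <- which(pa$name == "CA")
  ctr <- colMeans(pxyz[ca_idx, , drop = FALSE])
  sv <- svd(sweep(pxyz[ca_idx, , drop = FALSE], 2, ctr))
  rot <- sv$v
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  pxyz <- sweep(pxyz, 2, ctr) %*% rot
  if (pxyz[ca_idx[9], 1] < pxyz[ca_idx[1], 1]) {
    pxyz[, 1] <- -pxyz[, 1]; pxyz[, 2] <- -pxyz[, 2]
  }
  coords(pep) <- pxyz
  pa <- pep@atoms
  ca_p1p <- pxyz[which(pa$resid == 6 & pa$name == "CA"), ]
  x_scissile <- pxyz[which(pa$resid == 5 & pa$name == "C"), 1]
  ## channel axis = CA trace axis (x, through the origin after canonicalization)
  xr <- range(pxyz[, 1]); yc <- 0; zc <- 0

  wall_rows <- list()
  addWall <- function(p) {
    wall_rows[[length(wall_rows) + 1L]] <<-
      data.frame(name = "W", element = "X",
                 resid = length(wall_rows) + 1L, resname = "WAL",
                 chain = "E", x = p[1], y = p[2], z = p[3],
                 charge = 0, nb_type = "WAL", stringsAsFactors = FALSE)
  }
  half <- groove_width / 2
  ## side walls over the recognition collar: from just before the peptide to
  ## just past the scissile bond; the primed (substrate-exit) side is open
  xs <- seq(xr[1] - 0.3, x_scissile + 0.15, by = wall_spacing)
  zs <- seq(zc - 0.45, zc + 0.45, by = wall_spacing)
  for (x in xs) for (z in zs) {
    addWall(c(x, yc - half, z))
    addWall(c(x, yc + half, z))
  }
  ## floor under the collar
  ys <- seq(yc - half + wall_spacing, yc + half - wall_spacing, by = wall_spacing)
  for (x in xs) for (y in ys) addWall(c(x, y, zc - 0.7))
  if (blocked) {
    ## obstruction plug filling the S1' pocket: a grid across the channel
    ## cross-section at the P1' position, so grafted conformers cannot
    ## relax around it
    for (dy in c(-0.3, 0, 0.3)) for (dz in c(-0.3, 0, 0.3))
      addWall(c(ca_p1p[1], yc + dy, zc + dz))
    addWall(ca_p1p + c(0, 0, 0.05))
    addWall(ca_p1p + c(0.1, 0, -0.05))
  }
  walls <- do.call(rbind, wall_rows)
  atoms <- rbind(walls, pa)
  bonds <- pep@bonds + nrow(walls)
  protease <- Structure(atoms, bonds,
                        label = if (blocked) "receptor-blocked" else "receptor-open")
  new("ActiveSiteTemplate", protease = protease, peptide_resids = resids,
      peptide_chain = "P",
      fit_atoms = c("P/5/C", "P/5/O", "P/6/N", "P/6/H"))
}
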