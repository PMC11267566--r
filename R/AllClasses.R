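#' @import methods
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils head read.table write.table packageVersion
NULL

## Internal length unit is nm throughout; PDB I/O converts to/from Angstrom.

#' Molecular structure: an ordered atom table plus bond topology
#'
#' A `Structure` holds an ordered list of atom records (one row per atom) and
#' a bond list. Coordinates are in nanometres. The atom table carries, per
#' atom: `name` (PDB atom naming, e.g. "N", "CA", "C", "O"), `element`,
#' `resid` (1-based residue index, per chain), `resname` (3-letter code),
#' `chain` (single character), `x`, `y`, `z` (nm), `charge` (elementary
#' charges) and `nb_type` (key into the nonbonded force-field table).
#'
#' Validity requires finite coordinates, unique (chain, resid, name) triples,
#' bonds that reference existing atoms with no self bonds, and residues whose
#' atoms are contiguous in atom order.
#'
#' @slot atoms data.frame with the columns listed above, one row per atom.
#' @slot bonds two-column integer matrix of 1-based atom indices (unordered
#'   pairs).
#' @slot label character scalar naming the structure.
#'
#' @seealso [readPDB()], [writePDB()], [selectAtoms()]
#' @export
setClass("Structure", representation(
  atoms = "data.frame",
  bonds = "matrix",
  label = "character"
))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("name", "element", "resid", "resname", "chain",
            "x", "y", "z", "charge", "nb_type")
  missing_cols <- setdiff(need, names(a))
  if (length(missing_cols) > 0)
    return(paste("atoms lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(a) > 0) {
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
      return("non-finite coordinates")
    key <- paste(a$chain, a$resid, a$name)
    if (anyDuplicated(key))
      return("duplicated (chain, resid, name) atom key")
    ## residues must be contiguous in atom order
    rkey <- paste(a$chain, a$resid)
    if (anyDuplicated(rle(rkey)$values))
      return("atoms of one residue are not contiguous")
  }
  b <- object@bonds
  if (length(b) > 0) {
    if (ncol(b) != 2) return("bonds must have two columns")
    if (any(b < 1L) || any(b > nrow(a))) return("bond index out of range")
    if (any(b[, 1] == b[, 2])) return("self-bond present")
  }
  TRUE
})

#' Conformational ensemble sharing one topology
#'
#' Frames are coordinate matrices (n_atoms x 3, nm) over the `topology`
#' Structure, whose own coordinates serve only as a reference. `provenance`
#' records, per frame, the replicate id, the step (or frame) index it was
#' taken at, and the seed of the run that produced it.
#'
#' @slot topology a [Structure-class].
#' @slot frames list of numeric matrices, each n_atoms x 3.
#' @slot provenance data.frame with columns `replicate`, `frame`, `seed`.
#' @export
setClass("Ensemble", representation(
  topology = "Structure",
  frames = "list",
  provenance = "data.frame"
))

setValidity("Ensemble", function(object) {
  n <- nrow(object@topology@atoms)
  for (f in object@frames) {
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      return("every frame must be an n_atoms x 3 matrix")
    if (!all(is.finite(f))) return("non-finite frame coordinates")
  }
  if (nrow(object@provenance) != length(object@frames))
    return("provenance rows must match frame count")
  TRUE
})

#' Simplified united-atom force-field parameter set
#'
#' Lennard-Jones parameters are stored per nonbonded type as self-pair
#' coefficients (C12 in kJ mol^-1 nm^12, C6 in kJ mol^-1 nm^6); cross pairs
#' use geometric-mean combination. Bonded terms: harmonic bonds
#' E = k (b - b0)^2 keyed by the sorted nb-type pair, harmonic angles
#' E = k (theta - theta0)^2 keyed by the central atom's nb type, and periodic
#' torsions E = k (1 + cos(m phi - delta)) keyed by the central bond's sorted
#' nb-type pair.
#'
#' @slot lj data.frame: `type`, `c12`, `c6`.
#' @slot charges named numeric, default partial charge per nb type.
#' @slot bonds data.frame: `type_a`, `type_b`, `k` (kJ mol^-1 nm^-2), `b0` (nm).
#' @slot angles data.frame: `center`, `k` (kJ mol^-1 rad^-2), `theta0` (degrees).
#' @slot torsions data.frame: `type_a`, `type_b`, `k` (kJ/mol), `mult`,
#'   `phase` (degrees).
#' @slot coulomb_prefactor numeric, 138.935 kJ mol^-1 nm e^-2.
#' @export
setClass("ForceField", representation(
  lj = "data.frame",
  charges = "numeric",
  bonds = "data.frame",
  angles = "data.frame",
  torsions = "data.frame",
  coulomb_prefactor = "numeric"
))

setValidity("ForceField", function(object) {
  if (any(object@lj$c12 < 0) || any(object@lj$c6 < 0))
    return("C12 and C6 must be non-negative")
  if (nrow(object@bonds) > 0 && (any(object@bonds$k < 0) || any(object@bonds$b0 <= 0)))
    return("bond k must be >= 0 and b0 > 0")
  if (nrow(object@angles) > 0 && any(object@angles$k < 0))
    return("angle k must be >= 0")
  TRUE
})

#' Steepest-descent minimizer settings
#'
#' Clash relaxation stops after `max_steps` accepted steps or as soon as the
#' energy change of an accepted step falls below `energy_tol`. The step size
#' adapts: it grows by `grow` after an energy-lowering step and shrinks by
#' `shrink` when a trial step would raise the energy (such rejected trials do
#' not count toward `max_steps` unless `count_rejected` is set).
#'
#' @slot max_steps integer, maximum accepted steps (default 100).
#' @slot energy_tol numeric, kJ/mol stop tolerance (default 0.5).
#' @slot initial_step numeric, nm, first displacement of the steepest atom.
#' @slot grow,shrink numeric step-size factors.
#' @slot count_rejected logical; if TRUE rejected trials consume steps.
#' @export
setClass("MinimizerConfig", representation(
  max_steps = "integer",
  energy_tol = "numeric",
  initial_step = "numeric",
  grow = "numeric",
  shrink = "numeric",
  count_rejected = "logical"
))

setValidity("MinimizerConfig", function(object) {
  if (object@max_steps < 1L) return("max_steps must be >= 1")
  if (object@energy_tol <= 0) return("energy_tol must be > 0")
  if (object@initial_step <= 0) return("initial_step must be > 0")
  TRUE
})

#' Local-elevation bias settings
#'
#' The bias acts on the terminal N-C distance over a uniform grid of `n_grid`
#' points spanning `[grid_min, grid_max]` nm (endpoints inclusive). `wles` is
#' the width of the local Gaussian in units of the grid spacing, `rles` its
#' truncation radius in the same units, and `cles` the penalty increment
#' (kJ/mol) deposited per visit.
#'
#' @slot grid_min,grid_max numeric, nm.
#' @slot n_grid integer, number of grid points (>= 2).
#' @slot wles,rles numeric, grid-spacing units.
#' @slot cles numeric, kJ/mol per visit.
#' @export
setClass("LEConfig", representation(
  grid_min = "numeric", grid_max = "numeric", n_grid = "integer",
  wles = "numeric", rles = "numeric", cles = "numeric"
))

setValidity("LEConfig", function(object) {
  if (!(object@grid_min < object@grid_max)) return("grid_min must be < grid_max")
  if (object@n_grid < 2L) return("n_grid must be >= 2")
  if (object@wles <= 0 || object@rles <= 0 || object@cles <= 0)
    return("wles, rles, cles must be > 0")
  TRUE
})

#' Local-elevation visit memory
#'
#' Per-grid-point visit counts; the bias contributed by point g is
#' `visits[g] * cles * exp(-(d - center_g)^2 / (2 (wles D)^2))` truncated at
#' `rles * D` where D is the grid spacing.
#'
#' @slot visits non-negative integer vector, one per grid point.
#' @slot config the [LEConfig-class] the memory is dimensioned to.
#' @export
setClass("LEMemory", representation(visits = "numeric", config = "LEConfig"))

setValidity("LEMemory", function(object) {
  if (length(object@visits) != object@config@n_grid)
    return("visit vector must match n_grid")
  if (any(object@visits < 0)) return("visit counts must be non-negative")
  TRUE
})

#' Conformational sampler settings
#'
#' Controls the stochastic torsional search: Metropolis moves over backbone
#' (and side-chain) torsions at `temperature` K, `n_steps` production steps,
#' `n_replicates` independent replicates with seeds derived from `seed`, and
#' a frame saved every `save_interval` production steps. The equilibration
#' ramp heats in stages from `equil_t_start` to `temperature` while a harmonic
#' positional restraint, starting at `equil_restraint_k` kJ mol^-1 nm^-2 and
#' divided by 10 each stage, pins atoms near the start conformation; the final
#' stage runs unrestrained.
#'
#' @slot temperature numeric, K (default 600).
#' @slot n_steps integer, production Metropolis steps.
#' @slot n_replicates integer (default 10).
#' @slot seed integer master seed.
#' @slot equil_stages integer, number of ramp stages (0 disables).
#' @slot equil_steps_per_stage integer.
#' @slot equil_t_start numeric, K (default 60).
#' @slot equil_restraint_k numeric, kJ mol^-1 nm^-2 (default 2.5e4).
#' @slot save_interval integer, production steps between saved frames.
#' @slot max_torsion_step numeric, degrees, Metropolis proposal width.
#' @export
setClass("SamplerConfig", representation(
  temperature = "numeric",
  n_steps = "integer",
  n_replicates = "integer",
  seed = "integer",
  equil_stages = "integer",
  equil_steps_per_stage = "integer",
  equil_t_start = "numeric",
  equil_restraint_k = "numeric",
  save_interval = "integer",
  max_torsion_step = "numeric"
))

setValidity("SamplerConfig", function(object) {
  if (object@temperature <= 0) return("temperature must be positive")
  if (object@equil_stages > 0L && object@equil_t_start > object@temperature)
    return("ramp temperatures must be non-decreasing")
  if (object@n_steps < 1L) return("n_steps must be >= 1")
  if (object@save_interval < 1L) return("save_interval must be >= 1")
  TRUE
})

#' Ligation plan: how a sampled N-terminus is joined to the rigid body
#'
#' Four fit atoms on the peptide's overlap residue region are least-squares
#' superposed onto four matching body atoms; the peptide's atoms after the
#' junction CA are replaced by the body's. Atom ids are (chain, resid, name)
#' keys encoded as "chain/resid/name" strings.
#'
#' @slot nterm_fit_atoms,body_fit_atoms character(4), same atom-name sequence.
#' @slot junction_ca character, atom id of the CA where replacement occurs
#'   (on the peptide for `nterm`, matched by resid on the body).
#' @slot mobile_resids integer vector: residues of the reattached N-terminus
#'   that the clash-relaxing minimizer may move.
#' @slot rmsd_warn numeric, nm; post-fit RMSD above this warns (default 0.05).
#' @export
setClass("LigationPlan", representation(
  nterm_fit_atoms = "character",
  body_fit_atoms = "character",
  junction_ca = "character",
  mobile_resids = "integer",
  rmsd_warn = "numeric"
))

setValidity("LigationPlan", function(object) {
  if (length(object@nterm_fit_atoms) != 4L || length(object@body_fit_atoms) != 4L)
    return("fit atom lists must have length 4")
  nm_a <- sub(".*/", "", object@nterm_fit_atoms)
  nm_b <- sub(".*/", "", object@body_fit_atoms)
  if (!identical(nm_a, nm_b))
    return("fit atom name sequences must match")
  TRUE
})

#' Protease active-site template
#'
#' A protease structure with a bound 9-residue template peptide whose
#' residues are labelled P5..P1 and P1'..P4' (Schechter-Berger convention);
#' the scissile bond connects the C of P1 to the N of P1'. `fit_atoms` names
#' the peptide-bond atom set used to align an incoming conformer (default
#' C, O of P1 and N, H-or-CA of P1').
#'
#' @slot protease a [Structure-class]: enzyme plus bound template peptide.
#' @slot peptide_resids named integer, labels "P5".."P1","P1'".."P4'" mapping
#'   to resid values on the template-peptide chain.
#' @slot peptide_chain character, chain id of the template peptide.
#' @slot fit_atoms character(4) of atom ids "chain/resid/name".
#' @export
setClass("ActiveSiteTemplate", representation(
  protease = "Structure",
  peptide_resids = "integer",
  peptide_chain = "character",
  fit_atoms = "character"
))

p_labels <- function() c("P5", "P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")

setValidity("ActiveSiteTemplate", function(object) {
  if (length(object@peptide_resids) != 9L ||
      !identical(sort(names(object@peptide_resids)), sort(p_labels())))
    return("exactly 9 labelled residues P5..P1,P1'..P4' required")
  if (length(object@fit_atoms) != 4L) return("fit_atoms must have length 4")
  TRUE
})

#' Pairwise RMSD matrix over an ensemble
#'
#' Symmetric, zero-diagonal matrix of backbone RMSD values (nm) between
#' frames, after alignment on `align_sel` and evaluation on `rmsd_sel`.
#'
#' @slot values symmetric numeric n x n matrix, nm.
#' @slot align_sel,rmsd_sel character, the selection queries used.
#' @export
setClass("RmsdMatrix", representation(
  values = "matrix", align_sel = "character", rmsd_sel = "character"
))

setValidity("RmsdMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (any(v < 0)) return("RMSD values must be non-negative")
  if (any(diag(v) != 0)) return("diagonal must be exactly zero")
  if (!isTRUE(all.equal(v, t(v), tolerance = 0))) {
    if (max(abs(v - t(v))) > 0) return("matrix must be symmetric")
  }
  TRUE
})

#' Neighbor-count clustering result
#'
#' Ordered list of clusters, each a set of member frame ids with a central
#' member; clusters partition all frames and singletons are included.
#'
#' @slot cutoff numeric, nm.
#' @slot centers integer vector of central-member frame ids, one per cluster.
#' @slot members list of integer vectors (each contains its center).
#' @export
setClass("Clustering", representation(
  cutoff = "numeric", centers = "integer", members = "list"
))

setValidity("Clustering", function(object) {
  if (length(object@centers) != length(object@members))
    return("one center per cluster required")
  all_members <- unlist(object@members)
  if (anyDuplicated(all_members) > 0)
    return("clusters must be disjoint")
  for (i in seq_along(object@centers))
    if (!(object@centers[i] %in% object@members[[i]]))
      return("center must be a member of its cluster")
  TRUE
})

#' Cleavability readout
#'
#' Aggregates the per-conformer active-site fit outcomes: the fraction of
#' conformers retained (protease-substrate nonbonded energy < 0 after graft
#' and relaxation) and the median protease-substrate interaction energy over
#' retained conformers with the flexible N-terminal atoms excluded from the
#' substrate group.
#'
#' @slot n_total,n_retained integers.
#' @slot fraction_fitted numeric in [0, 1].
#' @slot median_E_bulk numeric kJ/mol (NA when nothing was retained).
#' @slot mode character, "complete" or "clustered".
#' @export
setClass("CleavabilityReport", representation(
  n_total = "integer", n_retained = "integer",
  fraction_fitted = "numeric", median_E_bulk = "numeric", mode = "character"
))

setValidity("CleavabilityReport", function(object) {
  if (object@n_retained > object@n_total) return("n_retained must be <= n_total")
  if (object@fraction_fitted < 0 || object@fraction_fitted > 1)
    return("fraction_fitted must lie in [0, 1]")
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure", if (nzchar(object@label)) sQuote(object@label) else "",
      ":", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resid))), "residues,",
      nrow(object@bonds), "bonds\n")
})

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble:", length(object@frames), "frames over",
      nrow(object@topology@atoms), "atoms",
      sprintf("(%d replicate(s))\n",
              length(unique(object@provenance$replicate))))
})

setMethod("show", "Clustering", function(object) {
  sizes <- lengths(object@members)
  cat("Clustering:", length(object@centers), "clusters at cutoff",
      format(object@cutoff), "nm; sizes",
      paste(head(sizes, 8), collapse = ", "),
      if (length(sizes) > 8) "..." else "", "\n")
})

setMethod("show", "CleavabilityReport", function(object) {
  cat(sprintf("CleavabilityReport (%s set): %d/%d retained, fraction fitted %.4f (%.1f%%)\n",
              object@mode, object@n_retained, object@n_total,
              object@fraction_fitted, 100 * object@fraction_fitted))
  cat("  median bulk interaction energy:",
      if (is.na(object@median_E_bulk)) "undefined (nothing retained)"
      else sprintf("%.2f kJ/mol", object@median_E_bulk), "\n")
})

setMethod("show", "ActiveSiteTemplate", function(object) {
  cat("ActiveSiteTemplate:", nrow(object@protease@atoms), "atoms;",
      "template peptide chain", object@peptide_chain,
      "residues", paste(range(object@peptide_resids), collapse = "-"), "\n")
})

## ---- constructors / accessors ---------------------------------------------

#' Construct a Structure
#'
#' @param atoms atom data.frame (see [Structure-class]).
#' @param bonds two-column integer matrix of 1-based atom-index pairs.
#' @param label optional name.
#' @return a [Structure-class]
#' @export
Structure <- function(atoms, bonds = matrix(integer(0), 0, 2), label = "") {
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  storage.mode(bonds) <- "integer"
  new("Structure", atoms = atoms, bonds = bonds, label = label)
}

#' Construct an Ensemble
#'
#' @param topology the shared [Structure-class].
#' @param frames list of n_atoms x 3 coordinate matrices (nm).
#' @param provenance optional data.frame (`replicate`, `frame`, `seed`);
#'   defaults to replicate 1, sequential frame numbers, seed NA.
#' @return an [Ensemble-class]
#' @export
Ensemble <- function(topology, frames, provenance = NULL) {
  if (is.null(provenance))
    provenance <- data.frame(replicate = 1L, frame = seq_along(frames),
                             seed = NA_integer_)
  new("Ensemble", topology = topology, frames = frames, provenance = provenance)
}

#' Default minimizer settings (100 steps, 0.5 kJ/mol)
#'
#' @param max_steps,energy_tol,initial_step,grow,shrink,count_rejected see
#'   [MinimizerConfig-class].
#' @return a [MinimizerConfig-class]
#' @export
minimizerConfig <- function(max_steps = 100L, energy_tol = 0.5,
                            initial_step = 0.01, grow = 1.2, shrink = 0.5,
                            count_rejected = FALSE) {
  new("MinimizerConfig", max_steps = as.integer(max_steps),
      energy_tol = energy_tol, initial_step = initial_step,
      grow = grow, shrink = shrink, count_rejected = count_rejected)
}

#' Local-elevation settings
#'
#' Defaults follow the distance-grid setup used for a ~13-residue N-terminal
#' peptide: 100 grid points spanning 0.4-4.0 nm, local-function width 2.0 and
#' truncation 2.5 grid spacings, penalty increment 2.25e-5 kJ/mol per visit.
#'
#' @param grid_min,grid_max,n_grid,wles,rles,cles see [LEConfig-class].
#' @return an [LEConfig-class]
#' @export
leConfig <- function(grid_min = 0.4, grid_max = 4.0, n_grid = 100L,
                     wles = 2.0, rles = 2.5, cles = 2.25e-5) {
  new("LEConfig", grid_min = grid_min, grid_max = grid_max,
      n_grid = as.integer(n_grid), wles = wles, rles = rles, cles = cles)
}

#' Sampler settings
#'
#' @param temperature,n_steps,n_replicates,seed,equil_stages,equil_steps_per_stage,equil_t_start,equil_restraint_k,save_interval,max_torsion_step
#'   see [SamplerConfig-class].
#' @return a [SamplerConfig-class]
#' @export
samplerConfig <- function(temperature = 600, n_steps = 2000L,
                          n_replicates = 10L, seed = 1L,
                          equil_stages = 10L, equil_steps_per_stage = 50L,
                          equil_t_start = 60, equil_restraint_k = 2.5e4,
                          save_interval = 20L, max_torsion_step = 60) {
  new("SamplerConfig", temperature = temperature, n_steps = as.integer(n_steps),
      n_replicates = as.integer(n_replicates), seed = as.integer(seed),
      equil_stages = as.integer(equil_stages),
      equil_steps_per_stage = as.integer(equil_steps_per_stage),
      equil_t_start = equil_t_start, equil_restraint_k = equil_restraint_k,
      save_interval = as.integer(save_interval),
      max_torsion_step = max_torsion_step)
}

#' Number of atoms in a Structure or Ensemble topology
#' @param x a [Structure-class] or [Ensemble-class]
#' @return integer
#' @export
nAtoms <- function(x) {
  if (is(x, "Ensemble")) nrow(x@topology@atoms) else nrow(x@atoms)
}

#' Number of frames in an Ensemble
#' @param x an [Ensemble-class]
#' @return integer
#' @export
nFrames <- function(x) length(x@frames)

#' Atom table of a Structure (or Ensemble topology)
#' @param x a [Structure-class] or [Ensemble-class]
#' @return data.frame
#' @export
atoms <- function(x) {
  if (is(x, "Ensemble")) x@topology@atoms else x@atoms
}

#' Coordinates as an n x 3 matrix (nm)
#' @param x a [Structure-class], or an [Ensemble-class] with `frame` given
#' @param frame frame number for ensembles
#' @return numeric matrix
#' @export
coords <- function(x, frame = NULL) {
  if (is(x, "Ensemble")) {
    stopifnot(!is.null(frame))
    return(x@frames[[frame]])
  }
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of a Structure
#' @param x a [Structure-class]
#' @param value n x 3 numeric matrix (nm)
#' @return the updated Structure
#' @export
`coords<-` <- function(x, value) {
  stopifnot(is(x, "Structure"), nrow(value) == nrow(x@atoms), ncol(value) == 3)
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  x
}

#' Extract one frame of an Ensemble as a Structure
#' @param x an [Ensemble-class]
#' @param frame frame number
#' @return a [Structure-class]
#' @export
getFrame <- function(x, frame) {
  s <- x@topology
  coords(s) <- x@frames[[frame]]
  s
}

#' Atom ids ("chain/resid/name") for given atom indices
#' @param structure a [Structure-class]
#' @param idx integer atom indices (default all)
#' @return character vector
#' @export
atomIds <- function(structure, idx = seq_len(nrow(structure@atoms))) {
  a <- structure@atoms
  paste(a$chain[idx], a$resid[idx], a$name[idx], sep = "/")
}

#' Resolve atom ids ("chain/resid/name") to atom indices
#' @param structure a [Structure-class]
#' @param ids character vector of atom ids
#' @return integer vector; errors if any id is missing
#' @export
atomIndex <- function(structure, ids) {
  key <- atomIds(structure)
  idx <- match(ids, key)
  if (anyNA(idx))
    stop("atom id(s) not found: ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}
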