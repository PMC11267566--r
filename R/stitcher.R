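## Ligation of sampled N-terminus conformers onto the rigid protein body.

#' Default ligation plan for a body with a given flexible span
#'
#' The sampled peptide covers residues 1..span plus one overlap residue
#' (span+1), numbered and chained as in the body. The four fit atoms are the
#' carbonyl C and O of residue `span` and the amide N and H of the overlap
#' residue (CA substitutes for H when the body carries no amide hydrogen);
#' the junction is the overlap residue's CA. The minimizer's mobile set and
#' the retention filter's N-terminus group cover the ACE cap and residues
#' 1..span.
#'
#' @param body the rigid-body [Structure-class]
#' @param span flexible N-terminal residue count
#' @param chain chain id shared by peptide and body
#' @param rmsd_warn post-fit RMSD warning threshold (nm, default 0.05)
#' @return a [LigationPlan-class]
#' @export
ligationPlan <- function(body, span, chain = "A", rmsd_warn = 0.05) {
  ov <- span + 1L
  h_id <- paste(chain, ov, "H", sep = "/")
  has_h <- h_id %in% atomIds(body)
  fourth <- if (has_h) h_id else paste(chain, ov, "CA", sep = "/")
  fit <- c(paste(chain, span, "C", sep = "/"),
           paste(chain, span, "O", sep = "/"),
           paste(chain, ov, "N", sep = "/"),
           fourth)
  new("LigationPlan", nterm_fit_atoms = fit, body_fit_atoms = fit,
      junction_ca = paste(chain, ov, "CA", sep = "/"),
      mobile_resids = 0:span, rmsd_warn = rmsd_warn)
}

#' Ligate an N-terminus conformer onto the rigid body
#'
#' Rigid-body superposes the peptide onto the body via the plan's four fit
#' atoms, then joins the chains at the junction CA: the output keeps the
#' peptide's atoms up to and including the junction CA and the body's atoms
#' after it, with the bonds across the junction rewired onto the shared CA.
#' The output atom count is (peptide atoms before the junction) + 1 + (body
#' atoms after the junction). A post-fit RMSD of the four atoms above
#' `plan@rmsd_warn` warns (the peptide junction geometry strayed from the
#' body's) but does not fail.
#'
#' @param nterm peptide [Structure-class] (capped; residues numbered as in
#'   the body)
#' @param body rigid-body [Structure-class]
#' @param plan a [LigationPlan-class]
#' @return the ligated [Structure-class]; attribute `"fit_rmsd"` carries the
#'   post-fit RMSD (nm), attribute `"junction"` the output index of the
#'   junction CA
#' @export
ligate <- function(nterm, body, plan) {
  ip <- atomIndex(nterm, plan@nterm_fit_atoms)
  ib <- atomIndex(body, plan@body_fit_atoms)
  fit <- superpose(coords(nterm)[ip, , drop = FALSE],
                   coords(body)[ib, , drop = FALSE])
  if (fit$rmsd > plan@rmsd_warn)
    warning(sprintf("post-fit RMSD %.4f nm exceeds %.3f nm",
                    fit$rmsd, plan@rmsd_warn))
  pxyz <- applyFit(coords(nterm), fit)
  jp <- atomIndex(nterm, plan@junction_ca)
  jb <- atomIndex(body, plan@junction_ca)

  n_body <- nrow(body@atoms)
  keep_body <- (jb + 1L):n_body
  atoms_out <- rbind(
    {
      ap <- nterm@atoms[seq_len(jp), , drop = FALSE]
      ap$x <- pxyz[seq_len(jp), 1]; ap$y <- pxyz[seq_len(jp), 2]
      ap$z <- pxyz[seq_len(jp), 3]
      ap
    },
    body@atoms[keep_body, , drop = FALSE])

  ## bonds: peptide bonds among kept peptide atoms; body bonds among kept
  ## body atoms (offset); body bonds touching the body junction CA rewired
  ## onto the shared output CA (index jp)
  bp <- nterm@bonds
  bp <- bp[bp[, 1] <= jp & bp[, 2] <= jp, , drop = FALSE]
  bb <- body@bonds
  map_body <- rep(NA_integer_, n_body)
  map_body[keep_body] <- jp + seq_along(keep_body)
  map_body[jb] <- jp
  b1 <- map_body[bb[, 1]]; b2 <- map_body[bb[, 2]]
  ok <- !is.na(b1) & !is.na(b2) & !(b1 == jp & b2 == jp)
  bonds_out <- rbind(bp, cbind(b1[ok], b2[ok]))
  ## drop duplicates (junction-adjacent bonds present on both sides)
  keyed <- paste(pmin(bonds_out[, 1], bonds_out[, 2]),
                 pmax(bonds_out[, 1], bonds_out[, 2]))
  bonds_out <- bonds_out[!duplicated(keyed), , drop = FALSE]

  out <- Structure(atoms_out, bonds_out,
                   label = paste0(body@label, "+nterm"))
  attr(out, "fit_rmsd") <- fit$rmsd
  attr(out, "junction") <- jp
  out
}

#' Stitch a sampled ensemble onto the body, relax and filter
#'
#' For every frame: ligate the conformer onto the body, relax clashes with
#' steepest descent in which only the reattached N-terminal atoms (the
#' peptide-contributed atoms up to the junction CA) may move, evaluate the
#' nonbonded cross energy between the N-terminal group (ACE cap plus
#' residues `plan@mobile_resids`) and the rest of the structure, and retain
#' the frame only if that energy is strictly negative. Frames whose
#' minimization produces a non-finite energy are dropped with a message.
#'
#' @param ensemble sampled peptide [Ensemble-class] (shared topology)
#' @param body rigid-body [Structure-class]
#' @param plan a [LigationPlan-class]
#' @param params a [ForceField-class]
#' @param cfg a [MinimizerConfig-class]
#' @return list: `ensemble` (stitched, minimized frames, all frames kept in
#'   order), `energies` (data.frame `frame_id`, `E_nonbonded_kJmol`,
#'   `retained`, `n_min_steps`), `retained` (frame ids passing the filter)
#' @export
stitchEnsemble <- function(ensemble, body, plan,
                           params = defaultForceField(),
                           cfg = minimizerConfig()) {
  n_fr <- nFrames(ensemble)
  if (n_fr == 0) stop("empty ensemble")
  ## topology-level preparation from frame 1
  s1 <- ligate(getFrame(ensemble, 1), body, plan)
  jp <- attr(s1, "junction")
  mobile <- seq_len(jp)
  terms <- energyTerms(s1, params, mobile = mobile)
  a_out <- s1@atoms
  chain <- a_out$chain[1]
  g_nterm <- which(a_out$chain == chain & a_out$resid %in% plan@mobile_resids)
  g_rest <- setdiff(seq_len(nrow(a_out)), g_nterm)
  excl <- bondedWithin(nrow(a_out), s1@bonds, 3L)

  frames <- vector("list", n_fr)
  e_vec <- numeric(n_fr); nstep <- integer(n_fr); finite <- logical(n_fr)
  for (f in seq_len(n_fr)) {
    s <- ligate(getFrame(ensemble, f), body, plan)
    res <- tryCatch(
      steepestDescent(s, mobile, params, cfg, terms = terms),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$energy)) {
      message("frame ", f, " dropped: non-finite energy during minimization")
      frames[[f]] <- coords(s)
      e_vec[f] <- NA_real_; nstep[f] <- NA_integer_; finite[f] <- FALSE
      next
    }
    frames[[f]] <- coords(res$structure)
    e_vec[f] <- nonbondedEnergy(res$structure, g_nterm, g_rest, params,
                                excl = excl)
    nstep[f] <- res$n_steps
    finite[f] <- TRUE
  }
  retained_tab <- data.frame(id = seq_len(n_fr),
                             energy = ifelse(finite, e_vec, Inf))
  ## non-finite frames carry +Inf so the strict filter drops them
  retained_tab$energy[!is.finite(retained_tab$energy)] <- .Machine$double.xmax
  retained <- energyFilter(retained_tab)
  energies <- data.frame(frame_id = seq_len(n_fr),
                         E_nonbonded_kJmol = e_vec,
                         retained = seq_len(n_fr) %in% retained,
                         n_min_steps = nstep)
  out_ens <- Ensemble(s1, frames, provenance = ensemble@provenance)
  list(ensemble = out_ens, energies = energies, retained = retained)
}
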