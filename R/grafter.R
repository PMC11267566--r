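## Active-site grafting and protease-substrate interaction energies.

## Fit-atom ids on the conformer side: the ACE cap's carbonyl C and O stand
## in for the P1 carbonyl, the first residue's N and H (CA fallback) for P1'.
conformerFitIds <- function(conformer) {
  chain <- conformer@atoms$chain[1]
  ids <- atomIds(conformer)
  h_id <- paste(chain, 1L, "H", sep = "/")
  fourth <- if (h_id %in% ids) h_id else paste(chain, 1L, "CA", sep = "/")
  c(paste(chain, 0L, "C", sep = "/"), paste(chain, 0L, "O", sep = "/"),
    paste(chain, 1L, "N", sep = "/"), fourth)
}

#' Graft a conformer into the protease active-site template
#'
#' Superposes the conformer's N-terminal peptide-bond atoms (C, O of the ACE
#' cap; N, H of residue 1) onto the template's scissile-bond atoms (C, O of
#' P1; N, H of P1'), then replaces the template-peptide atoms from the fit
#' atoms through P4' with the full conformer: the complex keeps the
#' protease, the template peptide's P5..P1 remainder (P1 loses its carbonyl
#' C and O to the conformer's cap), and every conformer atom. A bond from
#' the P1 CA to the cap carbonyl C restores chain continuity across the
#' junction.
#'
#' @param conformer a stitched, capped [Structure-class] whose residue 1 is
#'   the P1'-side residue
#' @param template an [ActiveSiteTemplate-class]
#' @return the complex [Structure-class]; attributes `"protease_idx"`,
#'   `"poi_idx"` and `"template_idx"` give the atom index groups, and
#'   `"fit_rmsd"` the post-fit RMSD of the four atoms
#' @export
graft <- function(conformer, template) {
  prot <- template@protease
  fit_ids <- conformerFitIds(conformer)
  ic <- tryCatch(atomIndex(conformer, fit_ids), error = function(e)
    stop("conformer lacks fit atoms: ", conditionMessage(e)))
  it <- tryCatch(atomIndex(prot, template@fit_atoms), error = function(e)
    stop("template lacks fit atoms: ", conditionMessage(e)))
  fit <- superpose(coords(conformer)[ic, , drop = FALSE],
                   coords(prot)[it, , drop = FALSE])
  cxyz <- applyFit(coords(conformer), fit)

  pa <- prot@atoms
  pchain <- template@peptide_chain
  p1 <- template@peptide_resids[["P1"]]
  prime_resids <- template@peptide_resids[c("P1'", "P2'", "P3'", "P4'")]
  drop <- (pa$chain == pchain & pa$resid %in% prime_resids) |
    (pa$chain == pchain & pa$resid == p1 & pa$name %in% c("C", "O"))
  keep <- which(!drop)
  kept <- keepStructureAtoms(prot, keep)

  ca <- conformer@atoms
  ca$x <- cxyz[, 1]; ca$y <- cxyz[, 2]; ca$z <- cxyz[, 3]
  n_kept <- nrow(kept@atoms)
  atoms_out <- rbind(kept@atoms, ca)
  bonds_out <- rbind(kept@bonds, conformer@bonds + n_kept)
  ## junction bond: P1 CA -- conformer ACE C
  j1 <- atomIndex(kept, paste(pchain, p1, "CA", sep = "/"))
  j2 <- atomIndex(conformer, paste(ca$chain[1], 0L, "C", sep = "/")) + n_kept
  bonds_out <- rbind(bonds_out, c(j1, j2))

  out <- Structure(atoms_out, bonds_out,
                   label = paste0(prot@label, "+", conformer@label))
  tpl_idx <- which(atoms_out$chain == pchain)
  attr(out, "protease_idx") <- setdiff(seq_len(n_kept), tpl_idx)
  attr(out, "template_idx") <- tpl_idx
  attr(out, "poi_idx") <- n_kept + seq_len(nrow(ca))
  attr(out, "fit_rmsd") <- fit$rmsd
  out
}

#' Graft, relax and score every conformer of an ensemble
#'
#' For each conformer: graft into the template, steepest-descent relax with
#' only the substrate (POI) atoms mobile, then evaluate the protease-POI
#' nonbonded interaction energy. A conformer is retained when that energy is
#' strictly negative. `E_bulk` is the same interaction energy with the
#' flexible N-terminal atoms (ACE cap and residues `nterm_resids`) excluded
#' from the POI group — a partial sum of the same pair terms. The retained
#' template-peptide residues P5..P1 belong to neither energy group unless
#' `include_template` adds them to the protease group. Conformers whose
#' grafted geometry yields a non-finite energy are recorded as not retained
#' (`finite = FALSE`) rather than failing.
#'
#' @param ensemble stitched conformer [Ensemble-class]
#' @param template an [ActiveSiteTemplate-class]
#' @param params a [ForceField-class]
#' @param cfg a [MinimizerConfig-class]
#' @param nterm_resids residue ids of the flexible N-terminal span (default
#'   `0:4`: the cap plus four residues)
#' @param include_template logical; count P5..P1 with the protease group
#' @return data.frame of fit outcomes: `conformer_id`,
#'   `E_interaction_kJmol`, `E_bulk_kJmol`, `retained`, `n_min_steps`,
#'   `finite`
#' @export
fitEnsemble <- function(ensemble, template, params = defaultForceField(),
                        cfg = minimizerConfig(), nterm_resids = 0:4,
                        include_template = FALSE) {
  n_fr <- nFrames(ensemble)
  if (n_fr == 0) stop("empty ensemble")
  c1 <- getFrame(ensemble, 1)
  g1 <- graft(c1, template)
  poi <- attr(g1, "poi_idx")
  prot_grp <- attr(g1, "protease_idx")
  if (include_template) prot_grp <- sort(c(prot_grp, attr(g1, "template_idx")))
  a_out <- g1@atoms
  poi_chain <- a_out$chain[poi[1]]
  bulk <- poi[!(a_out$resid[poi] %in% nterm_resids &
                  a_out$chain[poi] == poi_chain)]
  terms <- energyTerms(g1, params, mobile = poi)
  excl <- bondedWithin(nrow(a_out), g1@bonds, 3L)

  out <- vector("list", n_fr)
  for (f in seq_len(n_fr)) {
    cplx <- if (f == 1) g1 else graft(getFrame(ensemble, f), template)
    res <- tryCatch(steepestDescent(cplx, poi, params, cfg, terms = terms),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$energy)) {
      out[[f]] <- data.frame(conformer_id = f, E_interaction_kJmol = NA_real_,
                             E_bulk_kJmol = NA_real_, retained = FALSE,
                             n_min_steps = NA_integer_, finite = FALSE)
      next
    }
    e_int <- nonbondedEnergy(res$structure, prot_grp, poi, params,
                             excl = excl)
    e_bulk <- nonbondedEnergy(res$structure, prot_grp, bulk, params,
                              excl = excl)
    out[[f]] <- data.frame(conformer_id = f, E_interaction_kJmol = e_int,
                           E_bulk_kJmol = e_bulk,
                           retained = is.finite(e_int) && e_int < 0,
                           n_min_steps = res$n_steps, finite = TRUE)
  }
  do.call(rbind, out)
}
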