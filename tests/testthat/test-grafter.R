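test_that("receptor fixtures carry nine labelled residues and a marked scissile bond", {
  tpl <- makeReceptor(1.2)
  expect_length(tpl@peptide_resids, 9)
  expect_setequal(names(tpl@peptide_resids),
                  c("P5", "P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'"))
  ## scissile-bond fit atoms sit on P1 and P1'
  expect_identical(tpl@fit_atoms,
                   c("P/5/C", "P/5/O", "P/6/N", "P/6/H"))
  ## deterministic construction
  expect_identical(coords(makeReceptor(1.2)@protease),
                   coords(tpl@protease))
})

test_that("graft bookkeeping: complex = protease + P5..P1 remainder + full POI", {
  body <- makeBody(20, seed = 7L, tail = 5L)
  tpl <- makeReceptor(1.2)
  g <- graft(body, tpl)
  pa <- atoms(tpl@protease)
  prime <- tpl@peptide_resids[c("P1'", "P2'", "P3'", "P4'")]
  dropped <- sum(pa$chain == "P" & pa$resid %in% prime) +
    sum(pa$chain == "P" & pa$resid == tpl@peptide_resids[["P1"]] &
          pa$name %in% c("C", "O"))
  expect_equal(nAtoms(g), nAtoms(tpl@protease) - dropped + nAtoms(body))
  expect_lt(attr(g, "fit_rmsd"), 0.2)
  ## index groups partition the complex
  expect_identical(sort(c(attr(g, "protease_idx"), attr(g, "template_idx"),
                          attr(g, "poi_idx"))), seq_len(nAtoms(g)))
})

test_that("grafting is invariant to prior rigid transforms of the conformer", {
  body <- makeBody(18, seed = 5L, tail = 5L)
  tpl <- makeReceptor(1.2)
  ref <- coords(graft(body, tpl))
  set.seed(19)
  for (k in 1:3) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    b2 <- body
    coords(b2) <- sweep(coords(body) %*% t(q), 2, rnorm(3), "+")
    expect_lt(max(abs(coords(graft(b2, tpl)) - ref)), 1e-9)
  }
})

test_that("graft errors name missing fit atoms", {
  body <- makeBody(18, seed = 5L, tail = 5L)
  noCap <- cleavescan:::dropResidues(body, 0L)
  expect_error(graft(noCap, makeReceptor(1.2)), "fit atoms")
})

test_that("open grooves retain the self-graft, blocked grooves reject it", {
  body <- makeBody(20, seed = 7L, tail = 5L)
  ens <- Ensemble(body, list(coords(body)))
  open_oc <- fitEnsemble(ens, makeReceptor(1.2, blocked = FALSE),
                         nterm_resids = 0:4)
  expect_true(open_oc$retained[1])
  expect_lt(open_oc$E_interaction_kJmol[1], 0)
  blk_oc <- fitEnsemble(ens, makeReceptor(1.2, blocked = TRUE),
                        nterm_resids = 0:4)
  expect_false(blk_oc$retained[1])
  expect_gt(blk_oc$E_interaction_kJmol[1], 0)
})

test_that("minimization leaves protease coordinates bitwise unchanged", {
  fx <- stitchedFixture(seed = 11L, n_frames = 5L)
  st <- fx$stitch
  kept <- Ensemble(st$ensemble@topology, st$ensemble@frames[st$retained],
                   st$ensemble@provenance[st$retained, , drop = FALSE])
  tpl <- makeReceptor(1.2)
  g0 <- graft(getFrame(kept, 1), tpl)
  prot_idx <- c(attr(g0, "protease_idx"), attr(g0, "template_idx"))
  res <- steepestDescent(g0, attr(g0, "poi_idx"))
  expect_identical(coords(res$structure)[prot_idx, ],
                   coords(g0)[prot_idx, ])
})

test_that("retention flags and bulk energies decompose as pair sums", {
  fx <- stitchedFixture(seed = 11L, n_frames = 5L)
  st <- fx$stitch
  kept <- Ensemble(st$ensemble@topology, st$ensemble@frames[st$retained],
                   st$ensemble@provenance[st$retained, , drop = FALSE])
  tpl <- makeReceptor(1.2)
  oc <- fitEnsemble(kept, tpl, nterm_resids = 0:fx$span)
  ## retained set equals a brute-force scan of the outcome table
  expect_identical(which(oc$retained),
                   which(!is.na(oc$E_interaction_kJmol) &
                           oc$E_interaction_kJmol < 0))
  ## E_bulk is the partial pair sum of E_interaction: check by the
  ## loop-and-formula oracle on the relaxed first complex
  g0 <- graft(getFrame(kept, 1), tpl)
  res <- steepestDescent(g0, attr(g0, "poi_idx"),
                         terms = cleavescan:::energyTerms(
                           g0, defaultForceField(),
                           mobile = attr(g0, "poi_idx")))
  s <- res$structure
  aa <- atoms(s)
  poi <- attr(g0, "poi_idx")
  prot <- attr(g0, "protease_idx")
  nterm <- poi[aa$resid[poi] %in% 0:fx$span]
  bulk <- setdiff(poi, nterm)
  ff <- defaultForceField()
  e_int_o <- oracleCrossEnergy(s, prot, poi, ff)
  e_bulk_o <- oracleCrossEnergy(s, prot, bulk, ff)
  e_nterm_o <- oracleCrossEnergy(s, prot, nterm, ff)
  expect_equal(oc$E_interaction_kJmol[1], e_int_o, tolerance = 1e-9)
  expect_equal(oc$E_bulk_kJmol[1], e_bulk_o, tolerance = 1e-9)
  expect_equal(e_int_o, e_bulk_o + e_nterm_o, tolerance = 1e-9)
})
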