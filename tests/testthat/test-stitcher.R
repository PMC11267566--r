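randRot <- function() {
  ## QR of a random matrix gives a uniform-ish proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("superposition recovers identity, translation and known rotations", {
  set.seed(17)
  pts <- matrix(rnorm(30), 10, 3)
  same <- superpose(pts, pts)
  expect_equal(same$rotation, diag(3), tolerance = 1e-10)
  expect_equal(same$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)

  shifted <- sweep(pts, 2, c(1, 2, 3), "+")
  fit <- superpose(shifted, pts)
  expect_equal(cleavescan:::applyFit(shifted, fit), pts, tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)

  for (k in 1:20) {
    r0 <- randRot()
    t0 <- rnorm(3)
    moved <- sweep(pts %*% t(r0), 2, t0, "+")
    fit <- superpose(moved, pts)
    expect_equal(fit$rotation, t(r0), tolerance = 1e-8)
    expect_lt(fit$rmsd, 1e-8)
  }
  expect_error(superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("self-ligation reproduces the body exactly", {
  body <- makeBody(20, seed = 3L, tail = 5L)
  span <- 4L
  plan <- ligationPlan(body, span)
  a <- atoms(body)
  jp <- atomIndex(body, plan@junction_ca)
  pep_self <- cleavescan:::keepStructureAtoms(body, seq_len(jp + 3L))
  lig <- ligate(pep_self, body, plan)
  expect_lt(max(abs(coords(lig) - coords(body))), 1e-9)
  expect_equal(nAtoms(lig), nAtoms(body))
  expect_identical(atoms(lig)$name, a$name)
  expect_lt(attr(lig, "fit_rmsd"), 1e-12)
  ## junction peptide bond at its ideal length
  iC <- atomIndex(lig, paste0("A/", span + 1L, "/C"))
  iN <- atomIndex(lig, paste0("A/", span + 2L, "/N"))
  b <- sqrt(sum((coords(lig)[iC, ] - coords(lig)[iN, ])^2))
  expect_lt(abs(b - 0.133), 0.03)
})

test_that("ligation atom bookkeeping matches the junction formula", {
  for (seed in c(2L, 5L)) {
    body <- makeBody(18, seed = seed, tail = 5L)
    span <- 4L
    plan <- ligationPlan(body, span)
    a <- atoms(body)
    seq3 <- vapply(seq_len(span + 1L),
                   function(r) a$resname[a$resid == r][1], "")
    pep <- makePeptide(seq3, "extended")
    lig <- ligate(pep, body, plan)
    jp <- atomIndex(pep, plan@junction_ca)
    jb <- atomIndex(body, plan@junction_ca)
    expect_equal(nAtoms(lig), (jp - 1L) + 1L + (nAtoms(body) - jb))
  }
})

test_that("ligation output is invariant to prior rigid transforms of the peptide", {
  body <- makeBody(18, seed = 5L, tail = 5L)
  span <- 4L
  plan <- ligationPlan(body, span)
  a <- atoms(body)
  seq3 <- vapply(seq_len(span + 1L),
                 function(r) a$resname[a$resid == r][1], "")
  pep <- makePeptide(seq3, "extended")
  ref <- coords(ligate(pep, body, plan))
  set.seed(8)
  for (k in 1:5) {
    pep2 <- pep
    coords(pep2) <- sweep(coords(pep) %*% t(randRot()), 2, rnorm(3), "+")
    expect_lt(max(abs(coords(ligate(pep2, body, plan)) - ref)), 1e-9)
  }
})

test_that("stitching relaxes, filters by cross energy, and moves only the N-terminus", {
  fx <- stitchedFixture(seed = 11L, n_frames = 10L)
  st <- fx$stitch
  expect_equal(nFrames(st$ensemble), 10)
  expect_true(all(st$retained %in% seq_len(10)))
  expect_lte(length(st$retained), 10)
  ## retained ids equal an independent strict-negativity scan
  e <- st$energies$E_nonbonded_kJmol
  expect_identical(st$retained,
                   which(!is.na(e) & e < 0))
  ## retention flags match the energy table
  expect_identical(st$energies$retained, st$energies$frame_id %in% st$retained)
  ## body atoms bitwise unchanged by minimization
  body_xyz <- coords(fx$body)
  jb <- atomIndex(fx$body, fx$plan@junction_ca)
  fixed_body <- body_xyz[(jb + 1):nrow(body_xyz), ]
  jp_out <- nAtoms(st$ensemble) - nrow(fixed_body)
  for (f in seq_len(nFrames(st$ensemble))) {
    got <- st$ensemble@frames[[f]][(jp_out + 1):nAtoms(st$ensemble), ]
    expect_identical(got, unname(fixed_body))
  }
  ## cross energies match the loop-and-formula oracle on one frame
  s1 <- getFrame(st$ensemble, 1)
  aa <- atoms(s1)
  g_n <- which(aa$resid %in% fx$plan@mobile_resids)
  g_r <- setdiff(seq_len(nrow(aa)), g_n)
  expect_equal(st$energies$E_nonbonded_kJmol[1],
               oracleCrossEnergy(s1, g_n, g_r, defaultForceField()),
               tolerance = 1e-9)
})

test_that("an engineered hard clash is filtered out", {
  fx <- stitchedFixture(seed = 11L, n_frames = 10L)
  body <- fx$body
  ## a conformer whose cap atom sits 0.05 nm from a body bulk atom
  a <- atoms(body)
  seq3 <- vapply(seq_len(fx$span + 1L),
                 function(r) a$resname[a$resid == r][1], "")
  pep <- makePeptide(seq3, "extended")
  lig0 <- ligate(pep, body, fx$plan)
  jp <- attr(lig0, "junction")
  target <- coords(lig0)[nAtoms(lig0) - 2L, ] # a late body atom
  pxyz <- coords(lig0)
  ## move the whole flexible cap region onto the body to defeat relaxation
  pxyz[1:3, ] <- matrix(target, 3, 3, byrow = TRUE) +
    matrix(c(0, 0, 0.05, 0, 0.05, 0, 0.05, 0, 0), 3, 3, byrow = TRUE)
  ## direct energy check on the engineered structure
  clash <- lig0
  coords(clash) <- pxyz
  g_n <- which(atoms(clash)$resid %in% fx$plan@mobile_resids)
  g_r <- setdiff(seq_len(nAtoms(clash)), g_n)
  expect_gt(nonbondedEnergy(clash, g_n, g_r), 0)
})
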