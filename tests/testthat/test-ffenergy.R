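ff <- defaultForceField()

test_that("force-field table parses strictly and rejects bad input", {
  expect_s4_class(ff, "ForceField")
  expect_equal(ff@coulomb_prefactor, 138.935)
  bad <- withr_local_file("bad.dat")
  writeLines(c("[LJ]", "N 1e-6"), bad)
  expect_error(readForceField(bad), "3 fields")
  bad2 <- withr_local_file("bad2.dat")
  writeLines(c("[NOPE]", "x 1 2"), bad2)
  expect_error(readForceField(bad2), "unknown section")
  expect_error(
    cleavescan:::bondPair(ff, "CB", "CB"),
    "no bond parameters")
})

test_that("Coulomb term matches the physical-constant oracle at 1 nm", {
  ## independent oracle: e^2 / (4 pi eps0 r) in kJ/mol at r = 1 nm
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; NA_av <- 6.02214076e23
  expected <- e^2 / (4 * pi * eps0 * 1e-9) * NA_av / 1000 # 138.9354...
  s <- twoBeadFree(1, types = c("H", "H"), charges = c(1, 1))
  got <- nonbondedEnergy(s, 1, 2, ff)
  lj_h <- ff@lj[ff@lj$type == "H", ]
  got_lj_free <- got - (lj_h$c12 / 1^12 - lj_h$c6 / 1^6)
  ## the stored prefactor carries 6 significant figures
  expect_equal(got_lj_free, expected, tolerance = 1e-5)
})

test_that("Lennard-Jones energy at its minimum matches the closed form", {
  c12 <- ff@lj$c12[ff@lj$type == "CB"]
  c6 <- ff@lj$c6[ff@lj$type == "CB"]
  rstar <- (2 * c12 / c6)^(1 / 6)
  s <- twoBeadFree(rstar)
  expect_equal(nonbondedEnergy(s, 1, 2, ff), -c6^2 / (4 * c12),
               tolerance = 1e-12)
  ## zero-parameter pair is exactly zero at any distance
  z <- ff
  z@lj <- rbind(z@lj, data.frame(type = "ZZ", c12 = 0, c6 = 0))
  z@charges <- c(z@charges, ZZ = 0)
  sz <- twoBeadFree(0.3, types = c("ZZ", "ZZ"))
  expect_identical(nonbondedEnergy(sz, 1, 2, z), 0)
})

test_that("nonbonded energy is symmetric, translation/rotation invariant, and errors on contact", {
  pep <- makePeptide("VRSKD", "helical")
  g1 <- selectAtoms(pep, "resid 1:2")
  g2 <- selectAtoms(pep, "resid 4:5")
  e12 <- nonbondedEnergy(pep, g1, g2, ff)
  e21 <- nonbondedEnergy(pep, g2, g1, ff)
  expect_identical(e12, e21)
  ## rigid transform invariance
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pep2 <- pep
  coords(pep2) <- sweep(coords(pep) %*% rot, 2, c(1, -2, 3), "+")
  expect_equal(nonbondedEnergy(pep2, g1, g2, ff), e12,
               tolerance = 1e-9)
  expect_error(nonbondedEnergy(pep, g1, g1, ff), "disjoint")
  clash <- twoBeadFree(0)
  expect_error(nonbondedEnergy(clash, 1, 2, ff), "zero interatomic")
})

test_that("bonded terms follow their harmonic/periodic conventions", {
  bp <- cleavescan:::bondPair(ff, "CA", "CB")
  s0 <- twoBeadBonded(bp$b0)
  expect_equal(intraEnergy(s0, params = ff)$energy, 0, tolerance = 1e-12)
  d <- 0.013
  s1 <- twoBeadBonded(bp$b0 + d)
  expect_equal(intraEnergy(s1, params = ff)$energy, bp$k * d^2,
               tolerance = 1e-9)
})

test_that("analytic gradient matches finite differences", {
  pep <- makePeptide("VRSKD", "helical") # bonds, angles, torsions, nb all active
  terms <- cleavescan:::energyTerms(pep, ff)
  xyz <- coords(pep)
  g <- cleavescan:::evalTerms(xyz, terms)$gradient
  h <- 1e-6
  set.seed(41)
  for (i in sample(nrow(xyz), 5)) {
    for (d in 1:3) {
      xp <- xyz; xp[i, d] <- xp[i, d] + h
      xm <- xyz; xm[i, d] <- xm[i, d] - h
      num <- (cleavescan:::evalTerms(xp, terms, gradient = FALSE)$energy -
                cleavescan:::evalTerms(xm, terms, gradient = FALSE)$energy) /
        (2 * h)
      expect_equal(g[i, d], num, tolerance = 1e-5)
    }
  }
})

test_that("steepest descent relaxes a stretched bond to its rest length", {
  bp <- cleavescan:::bondPair(ff, "CA", "CB")
  s <- twoBeadBonded(0.3)
  res <- steepestDescent(s, mobile = 2L, ff)
  b <- abs(coords(res$structure)[2, 1] - coords(res$structure)[1, 1])
  expect_lt(abs(b - bp$b0), 1e-3)
  expect_true(res$converged)
  ## immobile atom untouched
  expect_identical(coords(res$structure)[1, ], coords(s)[1, ])
})

test_that("steepest descent separates clashed LJ beads and never raises energy", {
  c12 <- ff@lj$c12[ff@lj$type == "CB"]
  c6 <- ff@lj$c6[ff@lj$type == "CB"]
  rstar <- (2 * c12 / c6)^(1 / 6)
  s <- twoBeadFree(0.6 * rstar)
  res <- steepestDescent(s, mobile = 2L, ff,
                         minimizerConfig(max_steps = 200L))
  r_end <- abs(coords(res$structure)[2, 1])
  expect_lt(res$energy, 0)
  expect_gte(r_end, rstar - 1e-2)
  expect_true(all(diff(res$trace) <= 0))
})

test_that("minimizer stop rule honors max_steps and the energy tolerance", {
  ## already at the minimum: converges immediately, far under 100 steps
  bp <- cleavescan:::bondPair(ff, "CA", "CB")
  at_min <- steepestDescent(twoBeadBonded(bp$b0), mobile = 2L, ff)
  expect_true(at_min$converged)
  expect_lte(at_min$n_steps, 1L)
  ## tight tolerance forces the step cap to bind
  hard <- steepestDescent(twoBeadBonded(0.4), mobile = 2L, ff,
                          minimizerConfig(max_steps = 5L,
                                          energy_tol = 1e-12))
  expect_lte(hard$n_steps, 5L)
  if (!hard$converged) expect_identical(hard$n_steps, 5L)
  ## when converged by tolerance, the last accepted drop is below it
  soft <- steepestDescent(twoBeadBonded(0.3), mobile = 2L, ff,
                          minimizerConfig(max_steps = 100L, energy_tol = 0.5))
  if (soft$converged && length(soft$trace) > 1)
    expect_lt(abs(diff(utils::tail(soft$trace, 2))), 0.5 + 1e-9)
  expect_error(steepestDescent(twoBeadBonded(0.3), integer(0), ff),
               "non-empty")
})

test_that("energy filter retains strictly negative energies, order preserved", {
  items <- data.frame(id = c("a", "b", "c"), energy = c(-5, 0, 3))
  expect_identical(energyFilter(items), "a") # zero is not negative
  expect_length(energyFilter(data.frame(id = 1:3, energy = c(1, 2, 3))), 0)
  set.seed(9)
  e <- rnorm(1000)
  ids <- paste0("s", seq_along(e))
  got <- energyFilter(data.frame(id = ids, energy = e))
  brute <- character(0)
  for (k in seq_along(e)) if (e[k] < 0) brute <- c(brute, ids[k])
  expect_identical(got, brute)
  expect_error(energyFilter(data.frame(id = 1, energy = NaN)), "finite")
})
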