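test_that("LE grid has inclusive endpoints and uniform spacing", {
  g <- buildLEGrid(leConfig(0.4, 4.0, 100))
  expect_length(g, 100)
  expect_equal(g[1], 0.4)
  expect_equal(g[100], 4.0)
  expect_equal(unique(round(diff(g), 12)), round(3.6 / 99, 12))
  g2 <- buildLEGrid(leConfig(0, 1, 2, cles = 1e-5))
  expect_equal(g2, c(0, 1))
  g3 <- buildLEGrid(leConfig(0.4, 1.7, 40, cles = 8.75e-6))
  expect_length(g3, 40)
  expect_equal(diff(g3)[1], 1.3 / 39)
  expect_error(leConfig(2, 1, 10), "grid_min")
})

test_that("LE bias follows the per-visit Gaussian law", {
  cfg <- leConfig(0.4, 4.0, 100, cles = 2.25e-5)
  mem <- leMemory(cfg)
  centers <- buildLEGrid(cfg)
  ## empty memory: zero everywhere
  expect_identical(leBias(centers[c(1, 50, 100)], mem), c(0, 0, 0))
  ## V visits at one point, neighbors unvisited: bias at center = V * cles
  V <- 7
  mem@visits[40] <- V
  expect_equal(leBias(centers[40], mem), V * cfg@cles, tolerance = 1e-12)
  ## beyond the truncation radius: exactly zero
  delta <- diff(centers)[1]
  far <- centers[40] + (cfg@rles + 1.1) * delta
  expect_identical(leBias(far, mem), 0)
  ## non-negative and continuous on a dense sweep
  mem@visits[c(10, 41, 90)] <- c(3, 2, 11)
  d <- seq(cfg@grid_min, cfg@grid_max, length.out = 4000)
  b <- leBias(d, mem)
  expect_true(all(b >= 0))
  ## continuity: jumps on the dense sweep are bounded by the local slope
  ## times the sweep step, not by the truncation radius
  expect_lt(max(abs(diff(b))), 0.02 * max(b))
  b2 <- leBias(seq(cfg@grid_min, cfg@grid_max, length.out = 16000), mem)
  expect_lt(max(abs(diff(b2))), max(abs(diff(b))))
})

test_that("out-of-range distances are clamped with a message", {
  cfg <- leConfig(0.4, 2.0, 20, cles = 1e-5)
  mem <- leMemory(cfg)
  mem@visits[1] <- 4
  expect_message(b <- leBias(0.1, mem), "clamped")
  expect_equal(b, 4 * cfg@cles, tolerance = 1e-12)
})

test_that("sampling is deterministic given seeds and visits count production steps", {
  pep <- makePeptide("VRSSS", "extended")
  cfg <- samplerConfig(n_steps = 120L, n_replicates = 2L, seed = 5L,
                       save_interval = 10L, equil_stages = 2L,
                       equil_steps_per_stage = 20L)
  le <- leConfig(0.4, 2.5, 40)
  e1 <- sampleConformers(pep, cfg, le)
  e2 <- sampleConformers(pep, cfg, le)
  expect_equal(nFrames(e1), 24) # 120/10 per replicate, 2 replicates
  expect_identical(e1@frames, e2@frames)
  expect_identical(e1@provenance, e2@provenance)
  ## one visit deposited per production step
  mems <- attr(e1, "le_memory")
  for (m in mems) expect_equal(sum(m@visits), 120)
  ## a nonrigid peptide occupies at least two distance bins
  d <- endToEnd(e1)
  expect_gte(length(unique(cut(d, breaks = seq(0, 3, by = 0.1)))), 2)
})

test_that("random frame selection is uniform, seeded, and pool-limited", {
  pep <- makePeptide("VRSS", "extended")
  xyz <- coords(pep)
  mk <- function(rep_id, n) {
    Ensemble(pep, replicate(n, xyz + rnorm(1), simplify = FALSE),
             provenance = data.frame(replicate = rep_id, frame = seq_len(n),
                                     seed = rep_id))
  }
  set.seed(1)
  ens <- lapply(1:10, mk, n = 20)
  sel <- randomFrameSelection(ens, n = 100, seed = 3L)
  expect_equal(nFrames(sel), 100)
  expect_equal(anyDuplicated(sel@provenance[, c("replicate", "frame")]), 0)
  sel2 <- randomFrameSelection(ens, n = 100, seed = 3L)
  expect_identical(sel@provenance, sel2@provenance)
  expect_warning(all_of_it <- randomFrameSelection(ens[[1]], n = 50, seed = 1L),
                 "fewer")
  expect_equal(nFrames(all_of_it), 20)
})

test_that("LE flattens the end-to-end distance occupancy", {
  ## at equal step budgets the biased search spreads over more distance
  ## bins: higher occupancy entropy, lower top-bin occupancy (median of 5
  ## seeds). The penalty increment is scaled to the short search so the
  ## accumulated bias is comparable to kT, the same role the much smaller
  ## per-step increments play over runs eight orders of magnitude longer.
  pep <- makePeptide("SSSSS", "extended")
  breaks <- seq(0, 3, by = 0.1)
  ent_on <- ent_off <- top_on <- top_off <- numeric(5)
  for (k in 1:5) {
    cfg <- samplerConfig(n_steps = 400L, n_replicates = 1L,
                         seed = 100L + k, save_interval = 2L,
                         equil_stages = 2L, equil_steps_per_stage = 20L)
    d_on <- endToEnd(sampleConformers(pep, cfg, leConfig(0.4, 2.5, 40,
                                                         cles = 0.05)))
    d_off <- endToEnd(sampleConformers(pep, cfg, NULL))
    ent_on[k] <- binEntropy(d_on, breaks)
    ent_off[k] <- binEntropy(d_off, breaks)
    top_on[k] <- max(hist(d_on, breaks, plot = FALSE)$counts) / length(d_on)
    top_off[k] <- max(hist(d_off, breaks, plot = FALSE)$counts) / length(d_off)
  }
  expect_gt(median(ent_on), median(ent_off))
  expect_lt(median(top_on), median(top_off))
})
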