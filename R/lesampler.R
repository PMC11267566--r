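## Conformational search: stochastic torsional Metropolis sampling with a
## local-elevation memory bias on the terminal N-C distance.

KB <- 0.0083144621 # kJ/mol/K

#' Local-elevation grid point centers
#'
#' Uniform grid of `n_grid` points spanning `[grid_min, grid_max]` nm with
#' both endpoints included; spacing is `(grid_max - grid_min) / (n_grid - 1)`.
#'
#' @param cfg an [LEConfig-class]
#' @return numeric vector of grid centers (nm)
#' @examples
#' length(buildLEGrid(leConfig(0.4, 4.0, 100)))  # 100
#' @export
buildLEGrid <- function(cfg) {
  seq(cfg@grid_min, cfg@grid_max, length.out = cfg@n_grid)
}

#' Create an empty local-elevation visit memory
#' @param cfg an [LEConfig-class]
#' @return an [LEMemory-class] with all visit counts zero
#' @export
leMemory <- function(cfg) {
  new("LEMemory", visits = numeric(cfg@n_grid), config = cfg)
}

#' Evaluate the local-elevation bias at a distance
#'
#' Each visit deposits one repulsive local function of height `cles` at its
#' grid point, discouraging the sampler from revisiting that end-to-end
#' distance. The local function is a Gaussian of width `wles` grid spacings,
#' truncated at `rles` grid spacings and shifted/rescaled so it is exactly 1
#' at its center and exactly 0 at the truncation radius (continuous in the
#' distance): with D the grid spacing and
#' `C = exp(-rles^2 / (2 wles^2))`, point g contributes
#' `visits[g] * cles * (exp(-(d - center_g)^2 / (2 (wles D)^2)) - C) / (1 - C)`
#' for `|d - center_g| <= rles D` and nothing beyond. Distances outside the
#' grid range are clamped to the nearest grid point (with a message).
#' Vectorized over `distance`.
#'
#' @param distance numeric vector, nm
#' @param memory an [LEMemory-class]
#' @param cfg the matching [LEConfig-class] (defaults to `memory@config`)
#' @return bias energies, kJ/mol (non-negative)
#' @export
leBias <- function(distance, memory, cfg = memory@config) {
  if (cfg@n_grid != memory@config@n_grid)
    stop("memory is not dimensioned to this configuration")
  centers <- buildLEGrid(cfg)
  delta <- (cfg@grid_max - cfg@grid_min) / (cfg@n_grid - 1)
  out_of_range <- distance < cfg@grid_min | distance > cfg@grid_max
  if (any(out_of_range)) {
    message(sum(out_of_range),
            " distance(s) outside the LE grid range; clamped")
    distance <- pmin(pmax(distance, cfg@grid_min), cfg@grid_max)
  }
  w2 <- 2 * (cfg@wles * delta)^2
  rcut <- cfg@rles * delta
  cshift <- exp(-rcut^2 / w2)
  vapply(distance, function(d) {
    dd <- d - centers
    act <- abs(dd) <= rcut
    if (!any(act)) return(0)
    g <- (exp(-dd[act]^2 / w2) - cshift) / (1 - cshift)
    sum(memory@visits[act] * cfg@cles * g)
  }, numeric(1))
}

## Deposit one visit at the grid point nearest to `distance`
## (ties resolved toward the lower-index point by which.min).
leDeposit <- function(memory, distance) {
  centers <- buildLEGrid(memory@config)
  g <- which.min(abs(distance - centers))
  memory@visits[g] <- memory@visits[g] + 1
  memory
}

## Extract the residue names and measured backbone torsions of a capped
## peptide built in the package's atom scheme.
peptideTorsionState <- function(peptide) {
  a <- peptide@atoms
  resids <- sort(unique(a$resid))
  if (!(0L %in% resids) || !any(a$resname == "NME"))
    stop("peptide must be capped (ACE/NME) for torsional sampling")
  core <- setdiff(resids, range(resids))
  resnames <- vapply(core, function(r) a$resname[a$resid == r][1], "")
  xyz <- coords(peptide)
  at <- function(r, nm) {
    i <- which(a$resid == r & a$name == nm)
    if (length(i) != 1) stop("missing backbone atom ", nm, " in residue ", r)
    xyz[i, ]
  }
  n <- length(core)
  phi <- psi <- numeric(n)
  for (k in seq_len(n)) {
    r <- core[k]
    prevC <- if (k == 1) at(0L, "C") else at(core[k - 1], "C")
    nextN <- if (k == n) at(max(resids), "N") else at(core[k + 1], "N")
    phi[k] <- measureTorsion(prevC, at(r, "N"), at(r, "CA"), at(r, "C"))
    psi[k] <- measureTorsion(at(r, "N"), at(r, "CA"), at(r, "C"), nextN)
  }
  list(resnames = resnames, phi = phi, psi = psi)
}

## Coordinates of a capped chain with given torsions, in buildChain atom order.
rebuildCoords <- function(resnames, phi, psi) {
  buildChain(resnames, phi, psi, coords_only = TRUE)
}

#' Sample a conformational ensemble of a capped peptide
#'
#' Runs `n_replicates` independent stochastic torsional searches. Each
#' replicate proposes Metropolis moves on single backbone torsions (phi or
#' psi) while bonds, angles and omega stay at their ideal values; the
#' acceptance energy is the intramolecular energy (torsional plus nonbonded
#' over pairs more than three bonds apart) plus, during production, the
#' local-elevation bias on the terminal N-C distance (N of the first
#' residue to C of the last). An equilibration ramp heats the search from
#' `equil_t_start` to `temperature` in stages while a harmonic positional
#' restraint toward the start conformation, divided by 10 each stage and
#' released in the last, damps early rearrangement. One LE visit is
#' deposited per production step at the grid point nearest the current
#' end-to-end distance; a frame is saved every `save_interval` production
#' steps. Runs are deterministic given `s_cfg@seed`.
#'
#' @param peptide a capped [Structure-class] from [makePeptide()]
#' @param s_cfg a [SamplerConfig-class]
#' @param le_cfg an [LEConfig-class], or `NULL` to disable the bias
#' @param params a [ForceField-class]
#' @return an [Ensemble-class]; attribute `"le_memory"` holds the final
#'   per-replicate [LEMemory-class] objects
#' @export
sampleConformers <- function(peptide, s_cfg = samplerConfig(),
                             le_cfg = leConfig(), params = defaultForceField()) {
  st <- peptideTorsionState(peptide)
  n_res <- length(st$resnames)
  ## template topology in canonical build order
  topo <- buildChain(st$resnames, st$phi, st$psi, chain = peptide@atoms$chain[1],
                     label = peptide@label)
  terms <- energyTerms(topo, params)
  terms$bonds <- NULL; terms$angles <- NULL # constant under ideal geometry
  a <- topo@atoms
  core <- setdiff(sort(unique(a$resid)), range(unique(a$resid)))
  i_nterm <- which(a$resid == min(core) & a$name == "N")
  i_cterm <- which(a$resid == max(core) & a$name == "C")

  old_seed <- .Random.seed_exists()
  on.exit(restoreSeed(old_seed))

  frames <- list(); prov <- list(); memories <- list()
  for (rep_i in seq_len(s_cfg@n_replicates)) {
    rep_seed <- (s_cfg@seed + 10007L * rep_i) %% .Machine$integer.max
    set.seed(rep_seed)
    phi <- st$phi; psi <- st$psi
    xyz <- rebuildCoords(st$resnames, phi, psi)
    xyz0 <- xyz
    memory <- if (!is.null(le_cfg)) leMemory(le_cfg) else NULL

    energyAt <- function(xyz, restraint_k, use_le) {
      e <- evalTerms(xyz, terms, gradient = FALSE)$energy
      if (restraint_k > 0)
        e <- e + 0.5 * restraint_k * sum((xyz - xyz0)^2)
      if (use_le && !is.null(memory)) {
        d <- sqrt(sum((xyz[i_nterm, ] - xyz[i_cterm, ])^2))
        e <- e + suppressMessages(leBias(d, memory))
      }
      e
    }

    mcStep <- function(temp, restraint_k, use_le) {
      tor <- sample.int(2L * n_res, 1L)
      delta <- runif(1, -s_cfg@max_torsion_step, s_cfg@max_torsion_step)
      phi_t <- phi; psi_t <- psi
      if (tor <= n_res) phi_t[tor] <- phi_t[tor] + delta
      else psi_t[tor - n_res] <- psi_t[tor - n_res] + delta
      xyz_t <- rebuildCoords(st$resnames, phi_t, psi_t)
      e_t <- energyAt(xyz_t, restraint_k, use_le)
      if (is.finite(e_t) &&
          (e_t <= e_cur || runif(1) < exp(-(e_t - e_cur) / (KB * temp)))) {
        phi <<- phi_t; psi <<- psi_t; xyz <<- xyz_t; e_cur <<- e_t
        TRUE
      } else FALSE
    }

    ## equilibration ramp
    if (s_cfg@equil_stages > 0L) {
      temps <- if (s_cfg@equil_stages == 1L) s_cfg@temperature
      else seq(s_cfg@equil_t_start, s_cfg@temperature,
               length.out = s_cfg@equil_stages)
      for (stage in seq_len(s_cfg@equil_stages)) {
        rk <- if (stage == s_cfg@equil_stages) 0
        else s_cfg@equil_restraint_k / 10^(stage - 1)
        e_cur <- energyAt(xyz, rk, FALSE)
        for (step in seq_len(s_cfg@equil_steps_per_stage))
          mcStep(temps[stage], rk, FALSE)
      }
    }

    ## production with LE
    e_cur <- energyAt(xyz, 0, TRUE)
    acc_window <- 0L
    for (step in seq_len(s_cfg@n_steps)) {
      if (mcStep(s_cfg@temperature, 0, TRUE)) acc_window <- acc_window + 1L
      if (!is.null(memory)) {
        d <- sqrt(sum((xyz[i_nterm, ] - xyz[i_cterm, ])^2))
        memory <- leDeposit(memory, d)
        ## bias memory grew: refresh the current-state energy
        e_cur <- energyAt(xyz, 0, TRUE)
      }
      if (step %% 500L == 0L) {
        if (acc_window == 0L)
          stop("no accepted moves in 500 steps; review temperature or ",
               "max_torsion_step")
        acc_window <- 0L
      }
      if (step %% s_cfg@save_interval == 0L) {
        frames[[length(frames) + 1L]] <- xyz
        prov[[length(prov) + 1L]] <- data.frame(replicate = rep_i,
                                                frame = step,
                                                seed = rep_seed)
      }
    }
    memories[[rep_i]] <- memory
  }
  ens <- Ensemble(topo, frames, provenance = do.call(rbind, prov))
  attr(ens, "le_memory") <- memories
  ens
}

#' Randomly select frames from one or more ensembles
#'
#' Pools the frames of all replicates and draws `n` uniformly without
#' replacement, retaining per-frame provenance. If the pool holds fewer
#' than `n` frames the whole pool is returned with a warning.
#'
#' @param ensembles an [Ensemble-class] or list of ensembles sharing a
#'   topology
#' @param n number of frames to draw (default 10000)
#' @param seed integer RNG seed for the draw
#' @return an [Ensemble-class]
#' @export
randomFrameSelection <- function(ensembles, n = 10000L, seed = 1L) {
  if (is(ensembles, "Ensemble")) ensembles <- list(ensembles)
  topo <- ensembles[[1]]@topology
  frames <- do.call(c, lapply(ensembles, function(e) e@frames))
  prov <- do.call(rbind, lapply(ensembles, function(e) e@provenance))
  total <- length(frames)
  old_seed <- .Random.seed_exists()
  on.exit(restoreSeed(old_seed))
  set.seed(seed)
  if (total <= n) {
    if (total < n)
      warning("pool holds ", total, " frames, fewer than requested ", n,
              "; returning all")
    sel <- seq_len(total)
  } else {
    sel <- sort(sample.int(total, n))
  }
  Ensemble(topo, frames[sel], provenance = prov[sel, , drop = FALSE])
}
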