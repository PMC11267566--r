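## Molecular-mechanics energy terms, gradients, and clash relaxation.

## Row-wise cross product of n x 3 matrices.
crossM <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## Adjacency list from a bond matrix.
adjacencyList <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

## Pairs of atoms within `depth` bonds of each other (BFS per atom).
## Returns a character set of "i:j" keys with i < j.
bondedWithin <- function(n, bonds, depth = 3L) {
  adj <- adjacencyList(n, bonds)
  keys <- character(0)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    for (d in seq_len(depth)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (length(nxt) == 0) break
      dist[nxt] <- d
      frontier <- nxt
    }
    near <- which(!is.na(dist) & seq_len(n) > s)
    if (length(near) > 0) keys <- c(keys, paste(s, near, sep = ":"))
  }
  keys
}

## Precompute all energy terms of a structure under a force field.
## When `mobile` is given, only terms touching at least one mobile atom are
## kept (the dropped fixed-fixed terms are a constant of the minimization).
energyTerms <- function(structure, ff, mobile = NULL) {
  a <- structure@atoms
  n <- nrow(a)
  bonds <- structure@bonds
  adj <- adjacencyList(n, bonds)

  ## ---- harmonic bonds
  bt <- NULL
  if (nrow(bonds) > 0) {
    bp <- bondPair(ff, a$nb_type[bonds[, 1]], a$nb_type[bonds[, 2]])
    bt <- data.frame(i = bonds[, 1], j = bonds[, 2], k = bp$k, b0 = bp$b0)
  }

  ## ---- harmonic angles: all connected triples i-j-k, j the center
  ai <- integer(0); aj <- integer(0); ak <- integer(0)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      ai <- c(ai, cmb[1, ]); aj <- c(aj, rep(j, ncol(cmb))); ak <- c(ak, cmb[2, ])
    }
  }
  at <- NULL
  if (length(aj) > 0) {
    ap <- angleCenter(ff, a$nb_type[aj])
    at <- data.frame(i = ai, j = aj, k = ak, kth = ap$k, theta0 = ap$theta0)
  }

  ## ---- periodic torsions: one proper per central bond with a defined term,
  ## using the lowest-index flanking neighbors (deterministic)
  ti <- integer(0); tj <- integer(0); tk <- integer(0); tl <- integer(0)
  if (nrow(bonds) > 0) {
    tp_all <- torsionPair(ff, a$nb_type[bonds[, 1]], a$nb_type[bonds[, 2]])
    for (r in seq_len(nrow(bonds))) {
      if (is.na(tp_all$k[r])) next
      bj <- bonds[r, 1]; bk <- bonds[r, 2]
      ni <- setdiff(adj[[bj]], bk); nl <- setdiff(adj[[bk]], bj)
      if (length(ni) == 0 || length(nl) == 0) next
      ti <- c(ti, min(ni)); tj <- c(tj, bj); tk <- c(tk, bk); tl <- c(tl, min(nl))
    }
  }
  tt <- NULL
  if (length(tj) > 0) {
    tp <- torsionPair(ff, a$nb_type[tj], a$nb_type[tk])
    tt <- data.frame(i = ti, j = tj, k = tk, l = tl,
                     kphi = tp$k, mult = tp$mult, phase = tp$phase)
  }

  ## ---- nonbonded pairs: all i<j separated by more than 3 bonds
  nb_t <- NULL
  if (n > 1) {
    excl <- bondedWithin(n, bonds, 3L)
    pi_ <- rep(seq_len(n - 1), times = (n - 1):1)
    pj_ <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
    keep <- !(paste(pi_, pj_, sep = ":") %in% excl)
    pi_ <- pi_[keep]; pj_ <- pj_[keep]
    if (length(pi_) > 0) {
      lj <- ljPair(ff, a$nb_type[pi_], a$nb_type[pj_])
      nb_t <- data.frame(i = pi_, j = pj_, c12 = lj$c12, c6 = lj$c6,
                         qq = ff@coulomb_prefactor * a$charge[pi_] * a$charge[pj_])
    }
  }

  terms <- list(bonds = bt, angles = at, torsions = tt, nb = nb_t, n = n)
  if (!is.null(mobile)) terms <- restrictTerms(terms, mobile)
  terms
}

## Drop terms not touching any mobile atom.
restrictTerms <- function(terms, mobile) {
  touch <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0) return(df)
    keep <- Reduce(`|`, lapply(cols, function(cl) df[[cl]] %in% mobile))
    df[keep, , drop = FALSE]
  }
  terms$bonds <- touch(terms$bonds, c("i", "j"))
  terms$angles <- touch(terms$angles, c("i", "j", "k"))
  terms$torsions <- touch(terms$torsions, c("i", "j", "k", "l"))
  terms$nb <- touch(terms$nb, c("i", "j"))
  terms
}

## Energy and full-dimension gradient of precomputed terms at coordinates xyz.
evalTerms <- function(xyz, terms, gradient = TRUE) {
  n <- terms$n
  E <- 0
  G <- if (gradient) matrix(0, n, 3) else NULL
  addG <- function(idx, g) {
    ## accumulate rows of g into G at (possibly repeated) indices
    for (d in 1:3) G[, d] <<- G[, d] + unname(tapply2(g[, d], idx, n))
  }

  bt <- terms$bonds
  if (!is.null(bt) && nrow(bt) > 0) {
    r <- xyz[bt$i, , drop = FALSE] - xyz[bt$j, , drop = FALSE]
    b <- sqrt(rowSums(r * r))
    E <- E + sum(bt$k * (b - bt$b0)^2)
    if (gradient) {
      f <- 2 * bt$k * (b - bt$b0) / b
      gi <- r * f
      addG(bt$i, gi); addG(bt$j, -gi)
    }
  }

  at <- terms$angles
  if (!is.null(at) && nrow(at) > 0) {
    u <- xyz[at$i, , drop = FALSE] - xyz[at$j, , drop = FALSE]
    v <- xyz[at$k, , drop = FALSE] - xyz[at$j, , drop = FALSE]
    nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
    uh <- u / nu; vh <- v / nv
    ct <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rowSums(uh * vh)))
    th <- acos(ct)
    E <- E + sum(at$kth * (th - at$theta0)^2)
    if (gradient) {
      st <- sqrt(1 - ct^2)
      pref <- 2 * at$kth * (th - at$theta0)
      dthi <- (uh * ct - vh) / (nu * st)
      dthk <- (vh * ct - uh) / (nv * st)
      gi <- dthi * pref; gk <- dthk * pref
      addG(at$i, gi); addG(at$k, gk); addG(at$j, -(gi + gk))
    }
  }

  tt <- terms$torsions
  if (!is.null(tt) && nrow(tt) > 0) {
    b1 <- xyz[tt$j, , drop = FALSE] - xyz[tt$i, , drop = FALSE]
    b2 <- xyz[tt$k, , drop = FALSE] - xyz[tt$j, , drop = FALSE]
    b3 <- xyz[tt$l, , drop = FALSE] - xyz[tt$k, , drop = FALSE]
    n1 <- crossM(b1, b2); n2 <- crossM(b2, b3)
    nb2 <- sqrt(rowSums(b2 * b2))
    x <- rowSums(n1 * n2)
    y <- rowSums(crossM(n1, n2) * (b2 / nb2))
    phi <- atan2(y, x)
    E <- E + sum(tt$kphi * (1 + cos(tt$mult * phi - tt$phase)))
    if (gradient) {
      dEdphi <- -tt$kphi * tt$mult * sin(tt$mult * phi - tt$phase)
      sn1 <- rowSums(n1 * n1); sn2 <- rowSums(n2 * n2)
      dpi <- -n1 * (nb2 / sn1)
      dpl <- n2 * (nb2 / sn2)
      c12_ <- rowSums(b1 * b2) / nb2^2
      c32_ <- rowSums(b3 * b2) / nb2^2
      dpj <- -dpi * (1 + c12_) + dpl * c32_
      dpk <- dpi * c12_ - dpl * (1 + c32_)
      addG(tt$i, dpi * dEdphi); addG(tt$j, dpj * dEdphi)
      addG(tt$k, dpk * dEdphi); addG(tt$l, dpl * dEdphi)
    }
  }

  nbt <- terms$nb
  if (!is.null(nbt) && nrow(nbt) > 0) {
    r <- xyz[nbt$i, , drop = FALSE] - xyz[nbt$j, , drop = FALSE]
    r2 <- rowSums(r * r)
    if (any(r2 == 0)) stop("zero interatomic distance in nonbonded pair")
    ir2 <- 1 / r2
    ir6 <- ir2^3
    dist <- sqrt(r2)
    E <- E + sum(nbt$c12 * ir6^2 - nbt$c6 * ir6 + nbt$qq / dist)
    if (gradient) {
      ## dE/dr * 1/r, applied to the separation vector
      f <- (-12 * nbt$c12 * ir6^2 + 6 * nbt$c6 * ir6 - nbt$qq / dist) * ir2
      gi <- r * f
      addG(nbt$i, gi); addG(nbt$j, -gi)
    }
  }

  list(energy = E, gradient = G)
}

## Fast grouped sum: sum `vals` by integer index into a length-n vector.
tapply2 <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Pairwise nonbonded interaction energy between two atom groups
#'
#' Sums Lennard-Jones (C12/r^12 - C6/r^6) and Coulomb
#' (138.935 q_i q_j / r, relative permittivity 1) over all cross pairs
#' between two disjoint atom groups, with no distance cutoff. This is the
#' quantity the retention filters threshold: after clash relaxation, a
#' conformer is kept only when this energy is negative.
#'
#' When the two groups are covalently connected (e.g. the reattached
#' N-terminus against the rest of the chain), cross pairs separated by three
#' bonds or fewer are excluded, as in the intramolecular potential;
#' `exclude_bonded = FALSE` disables this.
#'
#' @param structure a [Structure-class]
#' @param group_a,group_b disjoint integer atom-index vectors
#' @param params a [ForceField-class]
#' @param exclude_bonded drop cross pairs within 3 bonds (default TRUE)
#' @param excl optional precomputed exclusion key set (internal reuse)
#' @return energy in kJ/mol
#' @export
nonbondedEnergy <- function(structure, group_a, group_b,
                            params = defaultForceField(),
                            exclude_bonded = TRUE, excl = NULL) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint")
  if (length(group_a) == 0 || length(group_b) == 0) return(0)
  a <- structure@atoms
  xyz <- coords(structure)
  ii <- rep(group_a, times = length(group_b))
  jj <- rep(group_b, each = length(group_a))
  if (exclude_bonded && nrow(structure@bonds) > 0) {
    if (is.null(excl)) excl <- bondedWithin(nrow(a), structure@bonds, 3L)
    keep <- !(paste(pmin(ii, jj), pmax(ii, jj), sep = ":") %in% excl)
    ii <- ii[keep]; jj <- jj[keep]
    if (length(ii) == 0) return(0)
  }
  ## canonical pair order: the sum is bitwise-identical under group swap
  lo <- pmin(ii, jj); hi <- pmax(ii, jj)
  ord <- order(lo, hi)
  ii <- lo[ord]; jj <- hi[ord]
  r <- xyz[ii, , drop = FALSE] - xyz[jj, , drop = FALSE]
  r2 <- rowSums(r * r)
  if (any(r2 == 0)) stop("zero interatomic distance between groups")
  lj <- ljPair(params, a$nb_type[ii], a$nb_type[jj])
  ir6 <- (1 / r2)^3
  sum(lj$c12 * ir6^2 - lj$c6 * ir6 +
        params@coulomb_prefactor * a$charge[ii] * a$charge[jj] / sqrt(r2))
}

#' Internal energy and gradient of a structure
#'
#' Evaluates harmonic bonds, harmonic angles, periodic torsions and
#' nonbonded interactions over atom pairs separated by more than three
#' bonds, returning the total and the analytic gradient for the mobile
#' atoms (gradient rows of non-mobile atoms are zeroed). Terms involving no
#' mobile atom are omitted; they are constant in any minimization over the
#' mobile set.
#'
#' @param structure a [Structure-class] with bond topology
#' @param mobile integer atom indices whose gradient is wanted (default all)
#' @param params a [ForceField-class]
#' @return list with `energy` (kJ/mol) and `gradient` (n x 3, kJ/mol/nm)
#' @export
intraEnergy <- function(structure, mobile = seq_len(nAtoms(structure)),
                        params = defaultForceField()) {
  terms <- energyTerms(structure, params, mobile = mobile)
  ev <- evalTerms(coords(structure), terms, gradient = TRUE)
  fixed <- setdiff(seq_len(terms$n), mobile)
  if (length(fixed) > 0) ev$gradient[fixed, ] <- 0
  ev
}

#' Steepest-descent clash relaxation
#'
#' Moves only the `mobile` atoms downhill along the negative energy
#' gradient with an adaptive step length. A trial step that lowers the
#' energy is accepted and the step grows; a trial that would raise it is
#' rejected and the step shrinks (rejected trials do not count toward
#' `max_steps` unless configured). The run stops when an accepted step
#' changes the energy by less than `energy_tol` (default 0.5 kJ/mol), when
#' `max_steps` accepted steps (default 100) have been taken, or when the
#' step length underflows because no downhill direction remains.
#'
#' @param structure a [Structure-class]
#' @param mobile non-empty integer vector of movable atom indices
#' @param params a [ForceField-class]
#' @param cfg a [MinimizerConfig-class]
#' @param terms optional precomputed term set from `energyTerms` (internal
#'   reuse across frames that share a topology)
#' @return list: `structure` (relaxed), `n_steps` (accepted steps),
#'   `converged` (TRUE unless stopped by max_steps), `energy` (final, kJ/mol),
#'   `trace` (energies of accepted iterates, starting energy first)
#' @export
steepestDescent <- function(structure, mobile, params = defaultForceField(),
                            cfg = minimizerConfig(), terms = NULL) {
  if (length(mobile) == 0) stop("mobile set must be non-empty")
  if (is.null(terms)) terms <- energyTerms(structure, params, mobile = mobile)
  xyz <- coords(structure)
  ev <- evalTerms(xyz, terms, gradient = TRUE)
  if (!is.finite(ev$energy)) stop("non-finite energy at start of minimization")
  e <- ev$energy
  trace <- e
  step <- cfg@initial_step
  n_acc <- 0L
  converged <- FALSE
  mob_mask <- matrix(0, terms$n, 3)
  mob_mask[mobile, ] <- 1
  repeat {
    if (n_acc >= cfg@max_steps) break
    g <- ev$gradient * mob_mask
    gmax <- max(abs(g))
    if (gmax == 0) { converged <- TRUE; break }
    ## displace so the steepest atom moves `step` nm
    trial <- xyz - g * (step / gmax)
    ev_t <- evalTerms(trial, terms, gradient = FALSE)
    if (is.finite(ev_t$energy) && ev_t$energy <= e) {
      de <- e - ev_t$energy
      xyz <- trial
      e <- ev_t$energy
      trace <- c(trace, e)
      n_acc <- n_acc + 1L
      step <- step * cfg@grow
      ev <- evalTerms(xyz, terms, gradient = TRUE)
      if (de < cfg@energy_tol) { converged <- TRUE; break }
    } else {
      step <- step * cfg@shrink
      if (cfg@count_rejected) n_acc <- n_acc + 1L
      if (step < 1e-10) { converged <- TRUE; break }
    }
  }
  coords(structure) <- xyz
  list(structure = structure, n_steps = n_acc, converged = converged,
       energy = e, trace = trace)
}

#' Strict negative-energy retention filter
#'
#' Keeps the items whose energy is strictly below the threshold (default
#' 0 kJ/mol): an energy of exactly zero is not negative and is dropped.
#' Input order is preserved.
#'
#' @param items data.frame with columns `id` and `energy`, or a named
#'   numeric vector of energies
#' @param threshold kJ/mol (default 0)
#' @return the retained ids, in input order
#' @export
energyFilter <- function(items, threshold = 0) {
  if (is.numeric(items) && !is.null(names(items)))
    items <- data.frame(id = names(items), energy = unname(items))
  if (!all(c("id", "energy") %in% names(items)))
    stop("items must have 'id' and 'energy'")
  if (!all(is.finite(items$energy))) stop("energies must be finite")
  items$id[items$energy < threshold]
}
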