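## Independent reference implementations used as oracles. These deliberately
## take the slow, literal route (explicit loops, textbook formulas) so they
## share no code path with the package functions they check.

## Plain cross-group nonbonded energy: double loop, explicit formula,
## optional exclusion of pairs within 3 bonds (precomputed by a literal
## triple expansion of the bond list).
oracleCrossEnergy <- function(structure, ga, gb, ff, exclude_bonded = TRUE) {
  a <- atoms(structure)
  xyz <- coords(structure)
  excl <- character(0)
  if (exclude_bonded && nrow(structure@bonds) > 0) {
    b <- structure@bonds
    nb1 <- lapply(seq_len(nrow(a)), function(i)
      unique(c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])))
    reach <- function(i, depth) {
      seen <- i
      frontier <- i
      for (d in seq_len(depth)) {
        frontier <- setdiff(unique(unlist(nb1[frontier])), seen)
        seen <- c(seen, frontier)
      }
      setdiff(seen, i)
    }
    for (i in seq_len(nrow(a)))
      for (j in reach(i, 3))
        excl <- c(excl, paste(min(i, j), max(i, j)))
    excl <- unique(excl)
  }
  e <- 0
  for (i in ga) for (j in gb) {
    if (paste(min(i, j), max(i, j)) %in% excl) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ti <- a$nb_type[i]; tj <- a$nb_type[j]
    c12 <- sqrt(ff@lj$c12[ff@lj$type == ti] * ff@lj$c12[ff@lj$type == tj])
    c6 <- sqrt(ff@lj$c6[ff@lj$type == ti] * ff@lj$c6[ff@lj$type == tj])
    e <- e + c12 / r^12 - c6 / r^6 +
      ff@coulomb_prefactor * a$charge[i] * a$charge[j] / r
  }
  e
}

## Literal greedy neighbor-count clustering: rescan the full matrix each
## round with explicit loops.
oracleDaura <- function(v, cutoff) {
  n <- nrow(v)
  remaining <- seq_len(n)
  centers <- integer(0); members <- list()
  while (length(remaining) > 0) {
    best <- NA_integer_; best_count <- -1L
    for (i in remaining) {
      cnt <- 0L
      for (j in remaining) if (j != i && v[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best_count) { best_count <- cnt; best <- i }
      ## ties: first i in ascending order wins, i.e. lowest frame id
    }
    cl <- best
    for (j in remaining) if (j != best && v[best, j] <= cutoff) cl <- c(cl, j)
    centers <- c(centers, best)
    members[[length(members) + 1L]] <- sort(cl)
    remaining <- setdiff(remaining, cl)
  }
  list(centers = centers, members = members)
}

## Random symmetric zero-diagonal "RMSD" matrix.
randomRmsdMatrix <- function(n, scale = 1) {
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2, 0, scale)
  v + t(v)
}

## Planted-group matrix: g groups of m frames on a line, tight within
## groups, far between them.
plantedMatrix <- function(g = 5, m = 10, intra = 0.05, inter = 2.0) {
  x <- as.vector(vapply(seq_len(g), function(k)
    (k - 1) * inter + runif(m, 0, intra), numeric(m)))
  list(values = abs(outer(x, x, "-")),
       group = rep(seq_len(g), each = m))
}

## Two-bead structure bonded at distance d (types with a defined bond).
twoBeadBonded <- function(d, types = c("CA", "CB")) {
  a <- data.frame(name = c("CA", "CB"), element = "C", resid = c(1L, 1L),
                  resname = "ALA", chain = "A",
                  x = c(0, d), y = 0, z = 0, charge = 0, nb_type = types,
                  stringsAsFactors = FALSE)
  Structure(a, matrix(c(1L, 2L), 1, 2))
}

## Unbonded two-bead structure at distance d.
twoBeadFree <- function(d, types = c("CB", "CB"), charges = c(0, 0)) {
  a <- data.frame(name = c("X1", "X2"), element = "C", resid = 1:2,
                  resname = "ALA", chain = "A",
                  x = c(0, d), y = 0, z = 0, charge = charges,
                  nb_type = types, stringsAsFactors = FALSE)
  a$name <- c("CB", "CB")
  Structure(a)
}

## Shannon entropy of a histogram of end-to-end distances.
binEntropy <- function(d, breaks) {
  h <- hist(d, breaks = breaks, plot = FALSE)$counts
  p <- h[h > 0] / sum(h)
  -sum(p * log(p))
}

## End-to-end (first N to last C) distances of an ensemble's frames.
endToEnd <- function(ens) {
  a <- atoms(ens)
  core <- setdiff(sort(unique(a$resid)), range(unique(a$resid)))
  i_n <- which(a$resid == min(core) & a$name == "N")
  i_c <- which(a$resid == max(core) & a$name == "C")
  vapply(ens@frames, function(f) sqrt(sum((f[i_n, ] - f[i_c, ])^2)),
         numeric(1))
}

## A small sampled + stitched conformer set over the standard toy body.
## Cached per (seed, n) within a test session.
stitchedFixture <- local({
  cache <- list()
  function(seed = 11L, n_frames = 20L, span = 4L, body_seed = 7L) {
    key <- paste(seed, n_frames, span, body_seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    body <- makeBody(20, seed = body_seed, tail = span + 1L)
    a <- atoms(body)
    seq3 <- vapply(seq_len(span + 1L),
                   function(r) a$resname[a$resid == r][1], "")
    pep <- makePeptide(seq3, "extended")
    s_cfg <- samplerConfig(n_steps = n_frames * 10L, n_replicates = 1L,
                           seed = seed, save_interval = 10L,
                           equil_stages = 3L, equil_steps_per_stage = 30L)
    ens <- sampleConformers(pep, s_cfg, leConfig(0.4, 2.5, 40))
    plan <- ligationPlan(body, span)
    st <- stitchEnsemble(ens, body, plan)
    out <- list(body = body, plan = plan, ensemble = ens, stitch = st,
                span = span)
    cache[[key]] <<- out
    out
  }
})

## Fresh per-call temp path for file round-trip tests.
withr_local_file <- function(name) {
  d <- tempfile("cleavescan")
  dir.create(d)
  file.path(d, name)
}
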