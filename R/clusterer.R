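## Backbone-RMSD neighbor-count clustering with cutoff search.

#' Pairwise RMSD matrix over an ensemble
#'
#' Aligns every frame once onto the first frame using the `align_sel`
#' selection (the rigid bulk backbone), then evaluates pairwise RMSD on the
#' `rmsd_sel` selection (the reattached N-terminal backbone N, CA, C).
#' Because the bulk is rigid and shared across frames, single-reference
#' alignment is equivalent to pairwise optimal alignment on the bulk.
#'
#' @param ensemble an [Ensemble-class] with at least 2 frames
#' @param align_sel,rmsd_sel selection queries (see [selectAtoms()])
#' @return an [RmsdMatrix-class] (nm)
#' @export
rmsdMatrix <- function(ensemble, align_sel, rmsd_sel) {
  n <- nFrames(ensemble)
  if (n < 2) stop("at least 2 frames required")
  topo <- ensemble@topology
  ia <- selectAtoms(topo, align_sel)
  ir <- selectAtoms(topo, rmsd_sel)
  if (length(ia) == 0 || length(ir) == 0) stop("empty selection")
  ref <- ensemble@frames[[1]][ia, , drop = FALSE]
  sel_coords <- lapply(ensemble@frames, function(f) {
    fit <- superpose(f[ia, , drop = FALSE], ref)
    applyFit(f, fit)[ir, , drop = FALSE]
  })
  v <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v[i, j] <- v[j, i] <- rmsdRaw(sel_coords[[i]], sel_coords[[j]])
    }
  }
  new("RmsdMatrix", values = v, align_sel = align_sel, rmsd_sel = rmsd_sel)
}

#' Neighbor-count greedy clustering
#'
#' Iteratively takes the structure with the most neighbors within the RMSD
#' cutoff as a cluster center, removes it and its neighbors, and repeats
#' until no structures remain. Singletons form their own clusters, so the
#' clusters partition all frames. Ties in neighbor count are broken toward
#' the lowest frame id, making the result deterministic.
#'
#' @param matrix an [RmsdMatrix-class] or a plain symmetric numeric matrix
#'   (nm)
#' @param cutoff neighbor cutoff, nm (> 0); neighbors satisfy distance <=
#'   cutoff
#' @return a [Clustering-class]
#' @export
dauraCluster <- function(matrix, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  v <- if (is(matrix, "RmsdMatrix")) matrix@values else matrix
  n <- nrow(v)
  adj <- v <= cutoff
  diag(adj) <- FALSE
  remaining <- rep(TRUE, n)
  centers <- integer(0); members <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- if (length(idx) == 1) 0L
    else rowSums(adj[idx, idx, drop = FALSE])
    center <- idx[which.max(counts)] # which.max: first max = lowest id
    neigh <- idx[adj[center, idx]]
    cl <- sort(unique(c(center, neigh)))
    centers <- c(centers, center)
    members[[length(members) + 1L]] <- cl
    remaining[cl] <- FALSE
  }
  new("Clustering", cutoff = cutoff, centers = centers, members = members)
}

clusterCount <- function(v, cutoff) length(dauraCluster(v, cutoff)@centers)

#' Find the cutoff that yields a target cluster count
#'
#' The cluster count is non-increasing in the cutoff but can skip values, so
#' an exact `k` may be unattainable. Bisection over the cutoff at 1e-4 nm
#' resolution returns a cutoff achieving exactly `k` clusters when possible;
#' otherwise the nearest achievable count, with a warning.
#'
#' @param matrix an [RmsdMatrix-class] or symmetric numeric matrix (nm)
#' @param k target cluster count (default 100)
#' @return list: `cutoff` (nm), `achieved_k`, `clustering` (the
#'   [Clustering-class] at the returned cutoff)
#' @export
cutoffForTargetK <- function(matrix, k = 100L) {
  v <- if (is(matrix, "RmsdMatrix")) matrix@values else matrix
  n <- nrow(v)
  if (k < 1) stop("k must be >= 1")
  res <- 1e-4
  lo <- res                       # count here is (near) n
  hi <- max(v) + res              # count here is 1
  ## invariant: count(lo) >= k target region >= count(hi)
  while (hi - lo > res) {
    mid <- round((lo + hi) / 2 / res) * res
    if (mid <= lo || mid >= hi) break
    if (clusterCount(v, mid) >= k) lo <- mid else hi <- mid
  }
  c_lo <- clusterCount(v, lo); c_hi <- clusterCount(v, hi)
  if (c_lo == k) {
    cutoff <- lo; achieved <- c_lo
  } else if (c_hi == k) {
    cutoff <- hi; achieved <- c_hi
  } else {
    ## k skipped: pick the nearest achievable count
    if (abs(c_lo - k) <= abs(c_hi - k)) { cutoff <- lo; achieved <- c_lo }
    else { cutoff <- hi; achieved <- c_hi }
    warning("target cluster count ", k, " not attainable; nearest is ",
            achieved, " at cutoff ", format(cutoff), " nm")
  }
  list(cutoff = cutoff, achieved_k = achieved,
       clustering = dauraCluster(v, cutoff))
}

#' Smallest cutoff whose top clusters reach a coverage fraction
#'
#' Finds a small grid cutoff (1e-4 nm resolution) at which the `top_n`
#' most-populated clusters jointly contain at least `coverage` of all
#' frames: bisection over the cutoff followed by downward refinement to the
#' lower edge of the qualifying interval. Coverage under the greedy
#' neighbor-count algorithm is non-decreasing in the cutoff up to rare
#' local bumps, so the result is locally minimal (the next grid value below
#' it does not qualify).
#'
#' @param matrix an [RmsdMatrix-class] or symmetric numeric matrix (nm)
#' @param top_n number of most-populated clusters counted (default 100)
#' @param coverage required fraction in (0, 1] (default 0.80)
#' @return list: `cutoff` (nm), `coverage` (achieved), `clustering`
#' @export
cutoffForCoverage <- function(matrix, top_n = 100L, coverage = 0.80) {
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  v <- if (is(matrix, "RmsdMatrix")) matrix@values else matrix
  n <- nrow(v)
  res <- 1e-4
  cov_at <- function(cutoff) {
    sizes <- sort(lengths(dauraCluster(v, cutoff)@members), decreasing = TRUE)
    sum(head(sizes, top_n)) / n
  }
  hi <- max(v) + res
  if (cov_at(hi) < coverage)
    stop("coverage ", coverage, " unreachable even at the maximum cutoff")
  lo <- res
  if (cov_at(lo) >= coverage) hi <- lo
  while (hi - lo > res) {
    mid <- round((lo + hi) / 2 / res) * res
    if (mid <= lo || mid >= hi) break
    if (cov_at(mid) >= coverage) hi <- mid else lo <- mid
  }
  ## walk down to the lower edge of the qualifying interval
  while (hi - res > 0 && cov_at(hi - res) >= coverage) hi <- hi - res
  list(cutoff = hi, coverage = cov_at(hi), clustering = dauraCluster(v, hi))
}

#' Extract the central member structures of a clustering
#'
#' Returns the cluster centers as an ensemble, ordered by descending cluster
#' size with ties broken by lowest center frame id.
#'
#' @param clustering a [Clustering-class] over the ensemble's frames
#' @param ensemble the clustered [Ensemble-class]
#' @return an [Ensemble-class] of center frames; attribute
#'   `"cluster_sizes"` carries the matching cluster sizes
#' @export
centralMembers <- function(clustering, ensemble) {
  if (length(unlist(clustering@members)) != nFrames(ensemble))
    stop("clustering does not cover the ensemble")
  sizes <- lengths(clustering@members)
  ord <- order(-sizes, clustering@centers)
  ids <- clustering@centers[ord]
  out <- Ensemble(ensemble@topology, ensemble@frames[ids],
                  provenance = ensemble@provenance[ids, , drop = FALSE])
  attr(out, "cluster_sizes") <- sizes[ord]
  out
}
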