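## Internal-coordinate geometry and least-squares superposition.

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Place atom D given positions of A, B, C and the internal coordinates
## |CD| (nm), angle B-C-D (deg) and torsion A-B-C-D (deg). Natural-extension
## reference-frame construction.
placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- c - b; bc <- bc / vnorm(bc)
  ab <- b - a
  n <- cross3(ab, bc); n <- n / vnorm(n)
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Measured torsion angle (deg, in (-180, 180]) of four points.
measureTorsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R %*% mobile + t` onto `reference`. Points are rows of n x 3 matrices.
#'
#' @param mobile,reference numeric n x 3 matrices, n >= 3, equal n,
#'   non-degenerate (not collinear).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   and `rmsd` (nm) of the fitted points. Apply as
#'   `sweep(mobile %*% t(rotation), 2, translation, "+")`.
#' @examples
#' pts <- matrix(rnorm(12), 4, 3)
#' fit <- superpose(pts, pts)
#' fit$rmsd  # 0
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3)
    stop("mobile and reference must be equal-size n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("at least 3 points required for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  x <- sweep(mobile, 2, cm); y <- sweep(reference, 2, cr)
  ## collinearity check: rank of the centered reference point cloud
  if (min(svd(x)$d[2], svd(y)$d[2]) < 1e-12)
    stop("degenerate (collinear) point set")
  h <- t(x) %*% y
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- sweep(x %*% t(rot), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

## Apply a superposition fit to an n x 3 coordinate matrix.
applyFit <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
}

## Plain RMSD between equal-size coordinate matrices (no fitting).
rmsdRaw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
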