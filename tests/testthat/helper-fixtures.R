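# Shared fixtures, built in code.

REF_SPACING <- c(0.645, 0.645, 2.0)

# regular tetrahedron with edge length `edge`, centered at the origin
regularTet <- function(edge = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v * edge / (2 * sqrt(2))
}

# exactly coplanar 4-point set (unit square at z = 0)
flatTet <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
}

rotationMatrix <- function(theta, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# small random point cloud with known convex hull (box corners included)
boxCloud <- function(n = 200, side = 100, seed = 42) {
  set.seed(seed)
  rbind(as.matrix(expand.grid(c(0, side), c(0, side), c(0, side))),
        matrix(runif(3 * n, 0, side), ncol = 3))
}

# mesh + pure-noise field helper used by the baseline-cancellation tests
noiseDisplacements <- function(n, sigma, seed) {
  set.seed(seed)
  cbind(rnorm(n, 0, sigma[1]), rnorm(n, 0, sigma[2]), rnorm(n, 0, sigma[3]))
}

# brute-force circumsphere check: largest relative penetration of any
# non-element point into any element's circumsphere (<= 0 means Delaunay)
worstCircumsphereViolation <- function(pts, el) {
  worst <- -Inf
  for (e in seq_len(nrow(el))) {
    v <- pts[el[e, ], , drop = FALSE]
    a <- v[1, ]
    M <- 2 * sweep(v[2:4, , drop = FALSE], 2, a)
    rhs <- rowSums(sweep(v[2:4, , drop = FALSE], 2, a)^2)
    y <- tryCatch(solve(M, rhs), error = function(err) NULL)
    if (is.null(y)) next
    cc <- a + y
    r2 <- sum(y^2)
    d2 <- rowSums(sweep(pts, 2, cc)^2)
    others <- setdiff(seq_len(nrow(pts)), el[e, ])
    worst <- max(worst, max((r2 - d2[others]) / r2))
  }
  worst
}
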