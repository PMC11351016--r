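# Independent oracles used by the test suite. Each deliberately takes a
# different computational route from the implementation it checks.

# Betti number via rank-nullity on boundary-matrix ranks (QR, no eigensolver):
# beta_k = #k-simplices - rank(B_k) - rank(B_{k+1})
betti_rank_oracle <- function(cplx, k) {
  cells <- cplx$dims[[as.character(k)]]
  nk <- if (is.null(cells)) 0L else nrow(cells)
  if (nk == 0) return(0L)
  rank_of <- function(B) {
    if (nrow(B) == 0 || ncol(B) == 0) return(0L)
    qr(B)$rank
  }
  nk - (if (k >= 1) rank_of(boundary_matrix(cplx, k)) else 0L) -
    (if (k + 1 <= 3) rank_of(boundary_matrix(cplx, k + 1)) else 0L)
}

# Standard persistent-homology boundary-matrix reduction over Z/2.
# Returns per-simplex: positive flag (creates a class), killer column index
# (NA when essential). Columns as sorted integer index sets.
ph_reduce_oracle <- function(filt) {
  m <- length(filt$simplices)
  keys <- vapply(filt$simplices, paste, "", collapse = ".")
  idx <- setNames(seq_len(m), keys)
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    v <- filt$simplices[[j]]
    if (length(v) > 1) {
      faces <- vapply(seq_along(v), function(i) paste(v[-i], collapse = "."), "")
      cols[[j]] <- sort(unname(idx[faces]))
    } else cols[[j]] <- integer(0)
  }
  low_owner <- rep(NA_integer_, m)   # pivot row -> reducing column
  reduced <- vector("list", m)
  for (j in seq_len(m)) {
    cj <- cols[[j]]
    repeat {
      if (length(cj) == 0) break
      l <- max(cj)
      j2 <- low_owner[l]
      if (is.na(j2)) break
      o <- reduced[[j2]]
      cj <- sort(c(setdiff(cj, o), setdiff(o, cj)))   # Z/2 addition
    }
    reduced[[j]] <- cj
    if (length(cj) > 0) low_owner[max(cj)] <- j
  }
  positive <- lengths(reduced) == 0
  killer <- rep(NA_integer_, m)
  paired_rows <- which(!is.na(low_owner))
  killer[paired_rows] <- low_owner[paired_rows]
  list(positive = positive, killer = killer,
       dim = filt$dim, value = filt$value)
}

# Betti number at scale t from the reduction: positive k-simplices alive at t
betti_ph_oracle <- function(ph, k, t) {
  alive <- ph$positive & ph$dim == k & ph$value <= t &
    (is.na(ph$killer) | ph$value[ph$killer] > t)
  sum(alive)
}

# Brute-force Vietoris-Rips enumeration: all pairs/triples passing the
# diameter rule on a distance matrix (exclusions = non-finite entries)
vr_brute_oracle <- function(d, max_scale, max_dim = 2) {
  n <- nrow(d)
  out <- list()
  for (i in seq_len(n)) out[[length(out) + 1]] <- list(v = i, val = 0)
  if (max_dim >= 1 && n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (is.finite(d[i, j]) && d[i, j] <= max_scale)
        out[[length(out) + 1]] <- list(v = c(i, j), val = d[i, j])
  if (max_dim >= 2 && n >= 3)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      dd <- c(d[i, j], d[i, k], d[j, k])
      if (all(is.finite(dd)) && max(dd) <= max_scale)
        out[[length(out) + 1]] <- list(v = c(i, j, k), val = max(dd))
    }
  out
}

# Brute-force Delaunay: every 4-subset whose circumsphere contains no other
# point strictly inside (valid for points in general position)
delaunay_brute_oracle <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  combs <- combn(n, 4)
  keep <- list()
  for (c4 in seq_len(ncol(combs))) {
    v <- combs[, c4]
    P <- pts[v, , drop = FALSE]
    M <- sweep(P[-1, , drop = FALSE], 2, P[1, ])
    if (abs(det(M)) < 1e-10) next   # degenerate tetra
    cs <- tryCatch(plddg:::.circumsphere(P), error = function(e) NULL)
    if (is.null(cs)) next
    others <- setdiff(seq_len(n), v)
    d2 <- rowSums(sweep(pts[others, , drop = FALSE], 2, cs$center)^2)
    if (all(d2 > cs$r2 - tol * max(1, cs$r2)))
      keep[[length(keep) + 1]] <- sort(v)
  }
  do.call(rbind, keep)
}

# Smallest empty circumscribing sphere of a simplex (numeric minimisation):
# the alpha filtration value of a Delaunay simplex, squared-radius scale.
alpha_value_oracle <- function(pts, v) {
  P <- pts[v, , drop = FALSE]
  cs <- plddg:::.circumsphere(P)
  k <- length(v) - 1
  others <- setdiff(seq_len(nrow(pts)), v)
  radius2_at <- function(s, U) {
    cc <- cs$center + if (length(s)) drop(U %*% s) else 0
    r2 <- sum((P[1, ] - cc)^2)
    pen <- 0
    if (length(others)) {
      d2 <- rowSums(sweep(pts[others, , drop = FALSE], 2, cc)^2)
      viol <- pmax(r2 - d2, 0)
      pen <- 1e6 * sum(viol^2)
    }
    r2 + pen
  }
  if (k == 3) return(cs$r2)
  # orthonormal basis of the complement of the simplex's affine hull
  M <- t(sweep(P[-1, , drop = FALSE], 2, P[1, ]))
  U <- svd(M, nu = 3)$u[, (k + 1):3, drop = FALSE]
  q <- ncol(U)
  best <- Inf
  for (start in list(rep(0, q), rep(0.5, q), rep(-0.5, q), rep(2, q),
                     rep(-2, q), seq_len(q))) {
    o <- suppressWarnings(optim(start, radius2_at, U = U,
                                method = "Nelder-Mead",
                                control = list(maxit = 5000, reltol = 1e-14)))
    best <- min(best, o$value)
  }
  best
}

# Rigid-superposition RMSD by direct numeric minimisation over rotations
# (Euler angles) and translations
kabsch_brute_oracle <- function(ref, mov) {
  rot <- function(a) {
    Rz <- rbind(c(cos(a[1]), -sin(a[1]), 0), c(sin(a[1]), cos(a[1]), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
    Rx <- rbind(c(1, 0, 0), c(0, cos(a[3]), -sin(a[3])), c(0, sin(a[3]), cos(a[3])))
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    R <- rot(par[1:3]); tr <- par[4:6]
    sqrt(mean(rowSums((mov %*% t(R) +
                         matrix(tr, nrow(mov), 3, byrow = TRUE) - ref)^2)))
  }
  best <- Inf
  set.seed(42)
  for (s in 1:12) {
    start <- c(runif(3, -pi, pi), colMeans(ref) - colMeans(mov))
    o <- optim(start, obj, method = "BFGS", control = list(maxit = 2000,
                                                           reltol = 1e-15))
    o2 <- optim(o$par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-15))
    best <- min(best, o$value, o2$value)
  }
  best
}

# random small face-closed complex: VR snapshot of a random cloud
random_complex <- function(n = 8, max_dim = 3, scale = NULL) {
  pts <- matrix(runif(3 * n, 0, 2), n, 3)
  d <- as.matrix(dist(pts))
  if (is.null(scale)) scale <- quantile(d[upper.tri(d)], runif(1, 0.2, 0.7))
  snapshot(build_vr_filtration(d, max_scale = max(d) + 1, max_dim = max_dim),
           scale)
}
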