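# Filtered simplicial complexes: Vietoris-Rips on (possibly modified)
# distance matrices for dimension-0 features, Alpha complexes on embedded
# 3-D coordinates for dimensions 1-2.
#
# Scale conventions: the VR parameter is an edge length (diameter
# convention); Alpha filtration values are reported on the radius scale in
# Angstrom, converted from the squared-radius convention internally, so both
# grids share units without silent factor-of-2 surprises.

#' @noRd
.new_filtration <- function(simplices, dim, value, kind, n_vertices) {
  ord <- order(value, dim)
  structure(list(simplices = simplices[ord], dim = dim[ord],
                 value = value[ord], kind = kind,
                 max_dim = if (length(dim)) max(dim) else 0L,
                 n_vertices = n_vertices),
            class = "filtration")
}

#' @export
print.filtration <- function(x, ...) {
  cat("filtration (", x$kind, "): ", x$n_vertices, " vertices, ",
      length(x$simplices), " simplices, max dim ", x$max_dim, "\n", sep = "")
  tab <- table(x$dim)
  cat("  by dim:", paste(names(tab), "=", tab, collapse = ", "), "\n")
  invisible(x)
}

#' Build a Vietoris-Rips filtration
#'
#' Vertices enter at scale 0; an edge enters at the pairwise distance of its
#' endpoints when that distance is finite and does not exceed `max_scale`
#' (excluded pairs of a modified distance matrix are non-finite and never
#' form simplices); each higher simplex enters at the maximum of its edge
#' values (diameter rule).
#'
#' @param x a [dmod_matrix()] result, a symmetric distance matrix, or an
#'   `n x 3` coordinate matrix (Euclidean distances are computed).
#' @param max_scale largest edge length admitted (Angstrom).
#' @param max_dim highest simplex dimension to build (0-3; default 1, which
#'   is sufficient for dimension-0 Laplacians).
#' @return a `filtration` object of kind `"vietoris_rips"`.
#' @export
build_vr_filtration <- function(x, max_scale, max_dim = 1) {
  if (!is.numeric(max_scale) || max_scale <= 0) stop("max_scale must be positive")
  if (max_dim < 0 || max_dim > 3) stop("max_dim must be in 0..3")
  if (inherits(x, "pair_distance_matrix")) {
    d <- x$values
  } else if (is.matrix(x) && ncol(x) == 3 && (nrow(x) != 3 || !isSymmetric(unname(x)))) {
    d <- as.matrix(dist(x))
  } else {
    d <- as.matrix(x)
    if (nrow(d) != ncol(d) ||
        !isTRUE(all.equal(d[is.finite(d) & is.finite(t(d))],
                          t(d)[is.finite(d) & is.finite(t(d))])) ||
        any(is.finite(d) != is.finite(t(d))))
      stop("distance matrix must be symmetric")
  }
  n <- nrow(d)
  simp <- lapply(seq_len(n), function(i) i)
  dims <- rep(0L, n)
  vals <- rep(0, n)

  edges <- NULL
  if (max_dim >= 1 && n >= 2) {
    idx <- which(upper.tri(d) & is.finite(d) & d <= max_scale, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      ev <- d[idx]
      edges <- cbind(idx[, 1], idx[, 2])
      simp <- c(simp, lapply(seq_len(nrow(edges)), function(k) edges[k, ]))
      dims <- c(dims, rep(1L, nrow(edges)))
      vals <- c(vals, ev)
    }
  }
  if (max_dim >= 2 && !is.null(edges) && nrow(edges) >= 3) {
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE
    adj <- adj | t(adj)
    tri <- list(); trival <- numeric(0)
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      common <- which(adj[i, ] & adj[j, ])
      common <- common[common > j]
      for (l in common) {
        tri[[length(tri) + 1]] <- c(i, j, l)
        trival <- c(trival, max(d[i, j], d[i, l], d[j, l]))
      }
    }
    if (length(tri)) {
      simp <- c(simp, tri); dims <- c(dims, rep(2L, length(tri)))
      vals <- c(vals, trival)
      if (max_dim >= 3) {
        tets <- list(); tetval <- numeric(0)
        for (t3 in seq_along(tri)) {
          v <- tri[[t3]]
          cand <- which(adj[v[1], ] & adj[v[2], ] & adj[v[3], ])
          cand <- cand[cand > v[3]]
          for (l in cand) {
            tets[[length(tets) + 1]] <- c(v, l)
            tetval <- c(tetval, max(d[c(v, l), c(v, l)][upper.tri(diag(4))]))
          }
        }
        if (length(tets)) {
          simp <- c(simp, tets); dims <- c(dims, rep(3L, length(tets)))
          vals <- c(vals, tetval)
        }
      }
    }
  }
  .new_filtration(simp, dims, vals, "vietoris_rips", n)
}

# circumsphere of a k-simplex in 3-D: center in the affine hull, squared
# radius; returns list(r2, center)
#' @noRd
.circumsphere <- function(P) {
  p0 <- P[1, ]
  if (nrow(P) == 1) return(list(r2 = 0, center = p0))
  M <- sweep(P[-1, , drop = FALSE], 2, p0)
  G <- tcrossprod(M)
  w <- tryCatch(solve(G, rowSums(M^2) / 2),
                error = function(e) qr.solve(G, rowSums(M^2) / 2, tol = 1e-300))
  off <- drop(crossprod(M, w))
  list(r2 = sum(off^2), center = p0 + off)
}

#' Build an Alpha filtration
#'
#' Computes the Delaunay triangulation of a 3-D point cloud (incremental
#' Bowyer-Watson) and assigns standard Alpha-complex filtration values:
#' top-dimensional simplices enter at their circumradius, and each face at
#' either its own circumradius (when its circumsphere is empty with respect
#' to its cofaces, the Gabriel condition) or the smallest value of its
#' cofaces. Values are reported on the radius scale (Angstrom). Degenerate
#' (collinear/coplanar/cospherical) clouds receive a deterministic jitter of
#' `1e-6` Angstrom from a fixed-seed generator before triangulation.
#'
#' @param points an `n x 3` coordinate matrix, `n >= 2`.
#' @param jitter_sd jitter amplitude (Angstrom) applied when the
#'   triangulation reports a degeneracy.
#' @return a `filtration` object of kind `"alpha"`, with simplices up to
#'   dimension 3.
#' @export
build_alpha_filtration <- function(points, jitter_sd = 1e-6) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix")
  if (!all(is.finite(points))) stop("points must be finite")
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points for an Alpha filtration")

  if (n >= 4) {
    res <- .delaunay3d_cpp(points)
    if (res$degenerate || nrow(res$tetrahedra) == 0) {
      pts2 <- points + .with_seed(900913L,
                                  matrix(rnorm(3 * n, sd = jitter_sd), n, 3))
      res <- .delaunay3d_cpp(pts2)
      if (res$degenerate && nrow(res$tetrahedra) == 0)
        stop("Delaunay triangulation failed on degenerate input")
      points <- pts2
    }
    tets <- res$tetrahedra
  } else {
    tets <- matrix(integer(0), 0, 4)
  }

  # enumerate simplices: for tiny clouds (n < 4, or no tetrahedra formed)
  # the Delaunay complex is the full simplex on the points
  key <- function(v) paste(v, collapse = ".")
  simplex_env <- new.env(parent = emptyenv())
  add <- function(v) {
    v <- sort(v)
    assign(key(v), v, envir = simplex_env)
  }
  if (nrow(tets) > 0) {
    for (i in seq_len(nrow(tets))) {
      v <- tets[i, ]
      add(v)
      for (drop1 in 1:4) add(v[-drop1])
      for (a in 1:3) for (b in (a + 1):4) add(v[c(a, b)])
    }
    for (i in seq_len(n)) add(i)
  } else {
    vv <- seq_len(n)
    for (i in vv) add(i)
    if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) add(c(i, j))
    if (n >= 3) add(1:3)
  }

  simp <- as.list(simplex_env)
  simp <- simp[order(names(simp))]
  simp <- unname(simp)
  dims <- vapply(simp, length, 0L) - 1L

  # alpha values on the squared-radius scale, top dimension downward
  vals <- rep(NA_real_, length(simp))
  keys <- vapply(simp, key, "")
  lookup <- setNames(seq_along(simp), keys)
  cs <- lapply(simp, function(v) if (length(v) >= 2)
    .circumsphere(points[v, , drop = FALSE]) else NULL)

  for (k in sort(unique(dims[dims >= 1]), decreasing = TRUE)) {
    for (i in which(dims == k)) {
      if (is.na(vals[i])) vals[i] <- cs[[i]]$r2
      if (k == 1) next
      v <- simp[[i]]
      for (dropj in seq_along(v)) {
        tau <- v[-dropj]
        ti <- lookup[[key(tau)]]
        if (!is.na(vals[ti])) {
          vals[ti] <- min(vals[ti], vals[i])
        } else {
          extra <- points[v[dropj], ]
          sph <- cs[[ti]]
          inside <- sum((extra - sph$center)^2) < sph$r2
          if (inside) vals[ti] <- vals[i]
        }
      }
    }
  }
  vals[dims == 0] <- 0
  # edges still NA are Gabriel edges never visited from a coface
  todo <- which(is.na(vals))
  if (length(todo)) vals[todo] <- vapply(todo, function(i) cs[[i]]$r2, 0)

  .new_filtration(simp, dims, sqrt(pmax(vals, 0)), "alpha", n)
}

#' Snapshot of a filtration at a scale
#'
#' Returns the simplicial complex containing every simplex whose filtration
#' value does not exceed `t`; face-closure is inherited from the monotone
#' filtration values.
#'
#' @param filtration a `filtration` object.
#' @param t scale (same units/convention as the filtration values).
#' @return a `simplicial_complex`: list with `dims` (per dimension `k`, an
#'   integer matrix with `k + 1` sorted vertex columns, one simplex per row)
#'   and `n_vertices`.
#' @export
snapshot <- function(filtration, t) {
  stopifnot(inherits(filtration, "filtration"))
  if (!is.numeric(t) || t < 0) stop("t must be >= 0")
  keep <- filtration$value <= t
  simp <- filtration$simplices[keep]
  dims <- filtration$dim[keep]
  out <- list()
  for (k in sort(unique(dims))) {
    m <- do.call(rbind, simp[dims == k])
    # stable row order for reproducible boundary matrices
    ord <- do.call(order, as.data.frame(m))
    out[[as.character(k)]] <- m[ord, , drop = FALSE]
  }
  structure(list(dims = out, n_vertices = filtration$n_vertices),
            class = "simplicial_complex")
}

#' @export
print.simplicial_complex <- function(x, ...) {
  counts <- vapply(x$dims, nrow, 0L)
  cat("simplicial_complex on", x$n_vertices, "vertices;",
      if (length(counts)) paste0("dim ", names(counts), ": ", counts,
                                 collapse = ", ") else "empty", "\n")
  invisible(x)
}

#' Write a filtration as CSV
#'
#' Debugging serialization: one row per simplex with `vertices` (dot
#' separated, 1-based), `dim` and `value` columns.
#'
#' @param filtration a `filtration` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filtration_csv <- function(filtration, path) {
  df <- data.frame(
    vertices = vapply(filtration$simplices, paste, "", collapse = "."),
    dim = filtration$dim, value = filtration$value)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
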