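# Combinatorial Laplacian spectra over filtrations: boundary matrices,
# L_k = B_{k+1} B_{k+1}^T + B_k^T B_k (L_0 = B_1 B_1^T), harmonic
# (zero-eigenvalue / Betti) and nonharmonic spectra, and the assembled
# per-mutation feature vectors.

#' @noRd
.simplex_keys <- function(m) apply(m, 1, paste, collapse = ".")

#' Signed boundary matrix of a simplicial complex
#'
#' Standard convention over the reals with sorted-vertex orientation: the
#' column of a k-simplex `[v0, ..., vk]` has entry `(-1)^i` in the row of
#' the face omitting `v_i`. Rows index the (k-1)-simplices, columns the
#' k-simplices, both in the complex's stored (sorted) order.
#'
#' @param cplx a `simplicial_complex` (see [snapshot()]).
#' @param k dimension, `k >= 1`.
#' @return a dense numeric matrix with `rownames`/`colnames` set to
#'   dot-separated vertex keys. When the complex has no k-simplices the
#'   matrix has zero columns (and the correct row count).
#' @export
boundary_matrix <- function(cplx, k) {
  stopifnot(inherits(cplx, "simplicial_complex"), k >= 1)
  faces <- cplx$dims[[as.character(k - 1)]]
  cells <- cplx$dims[[as.character(k)]]
  nr <- if (is.null(faces)) 0L else nrow(faces)
  nc <- if (is.null(cells)) 0L else nrow(cells)
  B <- matrix(0, nr, nc)
  if (nr > 0) rownames(B) <- .simplex_keys(faces)
  if (nc > 0) colnames(B) <- .simplex_keys(cells)
  if (nr == 0 || nc == 0) return(B)
  fidx <- setNames(seq_len(nr), rownames(B))
  for (j in seq_len(nc)) {
    v <- cells[j, ]
    for (i in seq_along(v)) {
      key <- paste(v[-i], collapse = ".")
      B[fidx[[key]], j] <- (-1)^(i - 1)
    }
  }
  B
}

#' Combinatorial Laplacian of a simplicial complex
#'
#' `L_k = B_{k+1} B_{k+1}^T + B_k^T B_k` for `k >= 1`; for `k = 0` the
#' boundary operator below is the zero map, so `L_0 = B_1 B_1^T`. The
#' result is symmetric positive semidefinite of order equal to the number
#' of k-simplices (order 0 when there are none).
#'
#' @inheritParams boundary_matrix
#' @param k dimension, `k >= 0`.
#' @return symmetric numeric matrix.
#' @export
combinatorial_laplacian <- function(cplx, k) {
  stopifnot(inherits(cplx, "simplicial_complex"), k >= 0)
  cells <- cplx$dims[[as.character(k)]]
  n <- if (is.null(cells)) 0L else nrow(cells)
  if (n == 0) return(matrix(0, 0, 0))
  Bup <- boundary_matrix(cplx, k + 1)
  L <- tcrossprod(Bup)            # B_{k+1} B_{k+1}^T (n x n even if 0 cols)
  if (k >= 1) {
    Bk <- boundary_matrix(cplx, k)
    L <- L + crossprod(Bk)        # + B_k^T B_k
  }
  (L + t(L)) / 2
}

#' Harmonic and nonharmonic spectrum of a Laplacian
#'
#' Eigenvalues in ascending order; the zero-eigenvalue multiplicity (the
#' harmonic spectrum) equals the Betti number by the combinatorial Hodge
#' theorem, and the remaining positive eigenvalues form the nonharmonic
#' spectrum. An eigenvalue counts as zero when it is below
#' `tol * max(1, lambda_max)` — a scale-aware cutoff that survives unit
#' changes.
#'
#' @param L symmetric matrix (a [combinatorial_laplacian()] result).
#' @param tol relative zero tolerance (default `1e-8`).
#' @return a `laplacian_spectrum`: list with `eigenvalues`,
#'   `zero_multiplicity`, `betti` (equal to `zero_multiplicity`) and
#'   `nonharmonic`.
#' @export
laplacian_spectrum <- function(L, tol = 1e-8) {
  if (nrow(L) == 0) {
    return(structure(list(eigenvalues = numeric(0), zero_multiplicity = 0L,
                          betti = 0L, nonharmonic = numeric(0)),
                     class = "laplacian_spectrum"))
  }
  if (!isSymmetric(unname(L), tol = 1e-8)) stop("Laplacian must be symmetric")
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  cutoff <- tol * max(1, max(ev))
  if (min(ev) < -cutoff)
    stop("Laplacian is not positive semidefinite (min eigenvalue ", min(ev), ")")
  nz <- sum(ev < cutoff)
  structure(list(eigenvalues = ev, zero_multiplicity = nz, betti = nz,
                 nonharmonic = ev[ev >= cutoff]),
            class = "laplacian_spectrum")
}

#' @export
print.laplacian_spectrum <- function(x, ...) {
  cat("laplacian_spectrum: order", length(x$eigenvalues),
      " betti =", x$betti, "\n")
  invisible(x)
}

#' Betti numbers along a filtration grid
#'
#' For each grid scale `t`, the k-th Betti number of the snapshot complex
#' `K_t`, read off as the zero-eigenvalue multiplicity of `L_k(K_t)`.
#'
#' @param filtration a `filtration`.
#' @param k homology dimension.
#' @param grid ascending numeric scales.
#' @return integer vector of Betti numbers, one per grid scale.
#' @export
betti_curve <- function(filtration, k, grid) {
  if (is.unsorted(grid)) stop("grid must be ascending")
  vapply(grid, function(t) {
    laplacian_spectrum(combinatorial_laplacian(snapshot(filtration, t), k))$betti
  }, 0L)
}

# statistics of one spectrum: betti + (min, max, mean, sd, sum, count) of
# the nonharmonic part; an empty nonharmonic set yields zeros with count 0
#' @noRd
.spectral_stats <- function(spec) {
  nh <- spec$nonharmonic
  if (length(nh) == 0) {
    c(betti = spec$betti, min = 0, max = 0, mean = 0, sd = 0, sum = 0, count = 0)
  } else {
    c(betti = spec$betti, min = min(nh), max = max(nh), mean = mean(nh),
      sd = if (length(nh) > 1) sd(nh) else 0, sum = sum(nh),
      count = length(nh))
  }
}

#' Feature configuration for persistent-Laplacian descriptors
#'
#' The featurization pairs site/binding atom subsets with element groups:
#' dimension-0 features come from Vietoris-Rips filtrations on the modified
#' cross-set distance `D_mod` for each element pair (same-subset pairs
#' excluded), while dimension-1/2 features come from Alpha filtrations on
#' the raw coordinates of single subsets with a joint element group.
#'
#' @param r selection radius (Angstrom) for neighborhood and binding-site
#'   subsets; default 10.
#' @param element_pairs list of 2-vectors of element symbols for the
#'   dimension-0 `D_mod` blocks; default the six unordered pairs over
#'   `{C, N, O}` (C-C capturing hydrophobic and N-O hydrophilic contacts).
#' @param alpha_elements element group for the Alpha (dims 1-2) blocks.
#' @param vr_grid filtration grid for dimension 0 (edge-length scale, A).
#' @param alpha_grid filtration grid for dimensions 1-2 (radius scale, A).
#' @param alpha_dims homology dimensions computed on Alpha filtrations.
#' @param pair_sets which subset pairs feed the `D_mod` blocks; each entry
#'   is `c("site", "neighborhood")` or `c("p1_binding", "p2_binding")`.
#' @param alpha_sets which single subsets feed the Alpha blocks.
#' @param max_order largest Laplacian order diagonalized densely; larger
#'   complexes contribute a zero block flagged in the layout.
#' @return a `pl_feature_config` list.
#' @export
pl_feature_config <- function(r = 10,
                              element_pairs = list(c("C", "C"), c("C", "N"),
                                                   c("C", "O"), c("N", "N"),
                                                   c("N", "O"), c("O", "O")),
                              alpha_elements = c("C", "N", "O"),
                              vr_grid = seq(0, 12, by = 0.25),
                              alpha_grid = seq(0, 10, by = 0.25),
                              alpha_dims = c(1L, 2L),
                              pair_sets = list(c("site", "neighborhood"),
                                               c("p1_binding", "p2_binding")),
                              alpha_sets = c("site", "neighborhood",
                                             "p1_binding", "p2_binding"),
                              max_order = 2000L) {
  structure(list(r = r, element_pairs = element_pairs,
                 alpha_elements = alpha_elements, vr_grid = vr_grid,
                 alpha_grid = alpha_grid, alpha_dims = as.integer(alpha_dims),
                 pair_sets = pair_sets, alpha_sets = alpha_sets,
                 max_order = as.integer(max_order)),
            class = "pl_feature_config")
}

#' Compact feature configuration
#'
#' A reduced descriptor set (coarser grids, fewer element pairs, dims 0-1)
#' used by the synthetic-data generator and anywhere a fast, low-dimensional
#' featurization is preferred over the full menu.
#'
#' @return a `pl_feature_config`.
#' @export
pl_feature_config_compact <- function() {
  pl_feature_config(
    r = 8,
    element_pairs = list(c("C", "C"), c("N", "O")),
    vr_grid = seq(0, 8, by = 2),
    alpha_grid = seq(1, 6, by = 2.5),
    alpha_dims = 1L,
    alpha_sets = c("site", "neighborhood"))
}

#' @noRd
.resolve_subset <- function(structure, mutation, name, r, elements) {
  switch(name,
    site = mutation_site_atoms(structure, mutation, elements),
    neighborhood = neighborhood_atoms(structure, mutation, r, elements),
    p1_binding = binding_site_atoms(structure, "p1", r, elements),
    p2_binding = binding_site_atoms(structure, "p2", r, elements),
    stop("unknown subset name: ", name))
}

# spectrum statistics over a grid for one filtration and dimension,
# honoring the dense-order cap
#' @noRd
.grid_stats <- function(filtration, k, grid, max_order) {
  out <- matrix(0, length(grid), 7)
  colnames(out) <- c("betti", "min", "max", "mean", "sd", "sum", "count")
  for (gi in seq_along(grid)) {
    cplx <- snapshot(filtration, grid[gi])
    cells <- cplx$dims[[as.character(k)]]
    n <- if (is.null(cells)) 0L else nrow(cells)
    if (n > max_order) next   # zero block, flagged via layout
    spec <- laplacian_spectrum(combinatorial_laplacian(cplx, k))
    out[gi, ] <- .spectral_stats(spec)
  }
  out
}

#' Persistent-Laplacian spectral features for one mutation
#'
#' Assembles the full descriptor vector for one mutation on one complex:
#' for every configured subset pair and element pair, dimension-0 harmonic
#' (Betti) and nonharmonic statistics of the Vietoris-Rips filtration on
#' the modified distance `D_mod` over the filtration grid; for every
#' configured subset, dimension-1/2 statistics of the Alpha filtration on
#' raw coordinates. Empty subsets contribute zero blocks (flagged in the
#' layout); the vector is deterministic for fixed input and configuration
#' and invariant to atom input order.
#'
#' @param structure a `complex_structure`.
#' @param mutation a `mutation_spec`.
#' @param config a [pl_feature_config()].
#' @return named numeric vector with attribute `layout`, a data frame
#'   describing every block (kind, subsets, elements, dimension, grid
#'   length, atom counts, empty flag).
#' @export
spectral_features <- function(structure, mutation,
                              config = pl_feature_config()) {
  stopifnot(inherits(config, "pl_feature_config"))
  stat_names <- c("betti", "min", "max", "mean", "sd", "sum", "count")
  vecs <- list(); layout <- list()

  # dimension-0 blocks: VR on D_mod for each subset pair x element pair
  for (pair in config$pair_sets) {
    for (ep in config$element_pairs) {
      sa <- .resolve_subset(structure, mutation, pair[1], config$r, ep[1])
      sb <- .resolve_subset(structure, mutation, pair[2], config$r, ep[2])
      empty <- nrow(sa$atoms) == 0 || nrow(sb$atoms) == 0
      if (empty) {
        stats <- matrix(0, length(config$vr_grid), 7)
        colnames(stats) <- stat_names
      } else {
        dm <- dmod_matrix(sa, sb)
        filt <- build_vr_filtration(dm, max_scale = max(config$vr_grid),
                                    max_dim = 1)
        stats <- .grid_stats(filt, 0L, config$vr_grid, config$max_order)
      }
      tag <- paste0("vr0_", pair[1], ".", pair[2], "_",
                    tolower(ep[1]), tolower(ep[2]))
      v <- as.numeric(t(stats))
      names(v) <- paste0(tag, "_t", rep(seq_along(config$vr_grid), each = 7),
                         "_", rep(stat_names, length(config$vr_grid)))
      vecs[[tag]] <- v
      layout[[tag]] <- data.frame(
        block = tag, kind = "vr_dmod", dim = 0L,
        subsets = paste(pair, collapse = "+"),
        elements = paste(ep, collapse = ""),
        grid_len = length(config$vr_grid),
        n_atoms = nrow(sa$atoms) + nrow(sb$atoms), empty = empty)
    }
  }

  # dimension-1/2 blocks: Alpha on raw coordinates per subset
  for (sname in config$alpha_sets) {
    ss <- .resolve_subset(structure, mutation, sname, config$r,
                          config$alpha_elements)
    pts <- .subset_coords(ss)
    can_build <- nrow(pts) >= 2
    filt <- if (can_build) build_alpha_filtration(pts) else NULL
    for (k in config$alpha_dims) {
      if (is.null(filt)) {
        stats <- matrix(0, length(config$alpha_grid), 7)
        colnames(stats) <- stat_names
      } else {
        stats <- .grid_stats(filt, k, config$alpha_grid, config$max_order)
      }
      tag <- paste0("alpha", k, "_", sname)
      v <- as.numeric(t(stats))
      names(v) <- paste0(tag, "_t", rep(seq_along(config$alpha_grid), each = 7),
                         "_", rep(stat_names, length(config$alpha_grid)))
      vecs[[tag]] <- v
      layout[[tag]] <- data.frame(
        block = tag, kind = "alpha", dim = k,
        subsets = sname,
        elements = paste(config$alpha_elements, collapse = ""),
        grid_len = length(config$alpha_grid),
        n_atoms = nrow(pts), empty = !can_build)
    }
  }

  out <- do.call(c, unname(vecs))
  attr(out, "layout") <- do.call(rbind, c(layout, make.row.names = FALSE))
  out
}
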