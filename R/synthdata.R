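# Synthetic-data generator: toy two-chain complexes with controlled
# flexibility, perturbed "predicted" copies, geometric point clouds with
# known topology, and ddG tables with planted linear signal. Everything is
# deterministic under its seed, so the whole pipeline is testable with no
# downloads.

# evaluate expr with a local RNG state
#' @noRd
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic complex configuration
#'
#' Study conditions for the toy complex generator: two chains of
#' `n_residues` each, separated across the interface by `gap` Angstrom, a
#' flexible segment (`flex_span`, residue indices applied to both chains)
#' whose B-factors are `flex_multiplier` times the `b_baseline`, and small
#' coordinate noise of `noise_sd` Angstrom keeping atoms in general
#' position.
#'
#' @param n_residues residues per chain (default 50, so a complex carries
#'   100 residues as in the flexibility-recovery experiments).
#' @param gap inter-chain interface separation, Angstrom (default 5, within
#'   contact distance of the default 10 A selection radius).
#' @param flex_span integer range of flexible residues per chain; the
#'   default (`NULL`) takes a central segment covering 30% of each chain,
#'   e.g. residues 16-30 of a 50-residue chain. Use `integer(0)` for a
#'   fully rigid complex.
#' @param flex_multiplier B-factor multiplier over the flexible segment.
#' @param b_baseline baseline isotropic B-factor, Angstrom^2.
#' @param noise_sd coordinate jitter, Angstrom.
#' @param seed RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_residues = 50, gap = 5, flex_span = NULL,
                         flex_multiplier = 5, b_baseline = 20,
                         noise_sd = 0.05, seed = 1) {
  stopifnot(n_residues >= 2, gap >= 0, flex_multiplier >= 0,
            b_baseline >= 0, noise_sd >= 0)
  if (is.null(flex_span)) {
    len <- max(1L, round(0.3 * n_residues))
    start <- max(1L, floor((n_residues - len) / 2) + 1L)
    flex_span <- seq(start, length.out = len)
  }
  flex_span <- as.integer(flex_span)
  if (length(flex_span) && (min(flex_span) < 1 || max(flex_span) > n_residues))
    stop("flex_span must lie within 1..n_residues")
  structure(list(n_residues = n_residues, gap = gap, flex_span = flex_span,
                 flex_multiplier = flex_multiplier, b_baseline = b_baseline,
                 noise_sd = noise_sd, seed = seed),
            class = "synth_config")
}

# idealised residue: heavy-atom offsets (A) from the CA position
#' @noRd
.RES_TEMPLATE <- rbind(
  N  = c(-1.46,  0.50,  0.30),
  CA = c( 0.00,  0.00,  0.00),
  C  = c( 1.25,  0.60, -0.30),
  O  = c( 1.60,  1.75, -0.35),
  CB = c(-0.10, -1.05,  1.05))

#' Generate a toy two-chain complex
#'
#' Two poly-alanine chains on idealized backbone geometry (3.8 A CA
#' spacing with a gentle deterministic wiggle), heavy atoms N/CA/C/O/CB
#' with correct element labels, the interface within contact distance, and
#' B-factors equal to the baseline except multiplied over the flexible
#' segment of each chain.
#'
#' @param config a [synth_config()].
#' @param id complex identifier (default `"SYN"`).
#' @return a `complex_structure` with partner split `A:B`.
#' @export
make_toy_complex <- function(config = synth_config(), id = "SYN") {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    rows <- list()
    for (ch in c("A", "B")) {
      ysign <- if (ch == "A") -1 else 1
      ybase <- ysign * (config$gap / 2 + 1.05)  # CB tips meet across the gap
      xoff <- if (ch == "A") 0 else 1.9         # stagger the chains
      for (i in seq_len(config$n_residues)) {
        ca <- c(xoff + 3.8 * (i - 1),
                ybase + ysign * 0.6 * sin(1.7 * i),
                0.7 * cos(1.3 * i + ifelse(ch == "A", 0, 1)))
        tmpl <- .RES_TEMPLATE
        tmpl[, 2] <- tmpl[, 2] * ysign          # side chains face the partner
        xyz <- sweep(tmpl, 2, ca, "+") +
          matrix(rnorm(15, sd = config$noise_sd), 5, 3)
        b <- config$b_baseline *
          if (i %in% config$flex_span) config$flex_multiplier else 1
        rows[[length(rows) + 1]] <- data.frame(
          chain = ch, resno = i, icode = "", resid = "ALA",
          elety = rownames(.RES_TEMPLATE),
          element = substr(rownames(.RES_TEMPLATE), 1, 1),
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
          b = b, occ = 1, stringsAsFactors = FALSE)
      }
    }
    new_complex_structure(id, do.call(rbind, rows), list(p1 = "A", p2 = "B"))
  })
}

# random proper rotation (QR of a Gaussian matrix, det forced to +1)
#' @noRd
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Perturb a structure into a synthetic "prediction"
#'
#' Creates the comparison partner for structure-evaluation experiments.
#' `rigid` mode applies only a random rotation and translation, so
#' per-residue RMSD after superposition is numerically zero. `flexible`
#' mode additionally displaces each residue rigidly by a Gaussian vector
#' whose standard deviation is proportional to the residue's B-factor
#' (`sd = amplitude * B / b_ref`) — the mechanism that makes flexible
#' segments misalign, as high-B regions do in real predictions.
#'
#' @param structure a `complex_structure`.
#' @param mode `"rigid"` or `"flexible"`.
#' @param amplitude displacement scale, Angstrom (sd at `B = b_ref`).
#' @param seed RNG seed.
#' @param b_ref reference B-factor at which the displacement sd equals
#'   `amplitude` (default the structure's mean B-factor).
#' @return a perturbed `complex_structure` (id suffixed `"_pred"`).
#' @export
perturb_structure <- function(structure, mode = c("rigid", "flexible"),
                              amplitude = 0.5, seed = 1, b_ref = NULL) {
  mode <- match.arg(mode)
  if (amplitude < 0) stop("amplitude must be >= 0")
  .with_seed(seed, {
    a <- structure$atoms
    if (mode == "flexible" && amplitude > 0) {
      if (is.null(b_ref)) b_ref <- mean(a$b)
      key <- .residue_key(a$chain, a$resno, a$icode)
      for (k in unique(key)) {
        sel <- key == k
        sd_k <- amplitude * a$b[sel][1] / b_ref
        shift <- rnorm(3, sd = sd_k)
        a$x[sel] <- a$x[sel] + shift[1]
        a$y[sel] <- a$y[sel] + shift[2]
        a$z[sel] <- a$z[sel] + shift[3]
      }
    }
    R <- .random_rotation()
    tr <- runif(3, -10, 10)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R) +
      matrix(tr, nrow(a), 3, byrow = TRUE)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    new_complex_structure(paste0(structure$id, "_pred"), a,
                          structure$partner_split,
                          confidence = structure$confidence)
  })
}

#' Point clouds with known topology
#'
#' Geometric fixtures whose Betti signatures are known at stated scales:
#' `two_clusters` (two tight blobs 10 A apart: one component per blob at
#' small scales), `circle` (radius 5 A in the xy-plane: a single loop at
#' intermediate Alpha scales), `sphere` (radius 5 A: a single cavity), and
#' `tetrahedron` (the exact 4-point regular tetrahedron of edge 1).
#'
#' @param shape one of `"two_clusters"`, `"circle"`, `"sphere"`,
#'   `"tetrahedron"`.
#' @param n number of points (ignored for `tetrahedron`).
#' @param noise_sd Gaussian noise added to every coordinate, Angstrom.
#' @param seed RNG seed.
#' @return an `n x 3` coordinate matrix.
#' @export
make_point_cloud <- function(shape = c("two_clusters", "circle", "sphere",
                                       "tetrahedron"),
                             n = 30, noise_sd = 0, seed = 1) {
  shape <- match.arg(shape)
  .with_seed(seed, {
    pts <- switch(shape,
      two_clusters = {
        stopifnot(n >= 2)
        n1 <- floor(n / 2)
        rbind(matrix(rnorm(3 * n1, sd = 0.3), ncol = 3),
              matrix(rnorm(3 * (n - n1), sd = 0.3), ncol = 3) +
                matrix(c(10, 0, 0), n - n1, 3, byrow = TRUE))
      },
      circle = {
        stopifnot(n >= 3)
        th <- 2 * pi * (seq_len(n) - 1) / n
        cbind(5 * cos(th), 5 * sin(th), 0.02 * sin(7 * th))
      },
      sphere = {
        stopifnot(n >= 4)
        5 * .sphere_points(n)
      },
      tetrahedron = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                          c(-1, -1, 1)) / sqrt(8))
    if (noise_sd > 0) pts <- pts + matrix(rnorm(length(pts), sd = noise_sd),
                                          nrow(pts), 3)
    pts
  })
}

#' Synthetic ddG table with planted linear signal
#'
#' Generates a cohort of toy complexes, draws random single mutations on
#' them, computes their persistent-Laplacian spectral features, and builds
#' ddG values as a sparse linear combination of selected feature columns
#' plus Gaussian noise scaled so that the signal explains a target fraction
#' `r2` of the variance. Ground-truth coefficients are returned so
#' cross-validation recovery can be asserted.
#'
#' @param n_complexes number of toy complexes in the cohort.
#' @param muts_per_complex mutations drawn per complex.
#' @param n_signal number of feature columns carrying signal.
#' @param r2 target fraction of ddG variance explained by the signal
#'   (`0 <= r2 < 1`; `r2 = 0` gives pure noise).
#' @param seed RNG seed.
#' @param config feature configuration (default the compact menu, see
#'   [pl_feature_config_compact()]).
#' @param ddg_sd marginal standard deviation of the generated ddG,
#'   kcal/mol.
#' @return list with `records` (SKEMPI-style data frame: `complex`,
#'   `mutation`, `chain`, `resno`, `icode`, `wt`, `mut`, `ddg`), `features`
#'   (row per record), `structures` (named list of `complex_structure`),
#'   `truth` (signal column names and coefficients), and `config`.
#' @export
make_ddg_table <- function(n_complexes = 20, muts_per_complex = 25,
                           n_signal = 3, r2 = 0.8, seed = 1,
                           config = pl_feature_config_compact(),
                           ddg_sd = 1.5) {
  stopifnot(r2 >= 0, r2 < 1, n_signal >= 1)
  .with_seed(seed, {
    ids <- sprintf("SYN%03d", seq_len(n_complexes))
    structures <- list()
    recs <- list(); feats <- list()
    for (ci in seq_len(n_complexes)) {
      nres <- sample(12:18, 1)
      cfg <- synth_config(n_residues = nres, gap = 4 + runif(1, 0, 2),
                          flex_span = integer(0), noise_sd = 0.15,
                          seed = sample.int(2^31 - 2, 1))
      st <- make_toy_complex(cfg, id = ids[ci])
      structures[[ids[ci]]] <- st
      pos <- sample(rep(seq_len(nres), ceiling(muts_per_complex / nres) + 1),
                    muts_per_complex)
      chain <- ifelse(seq_along(pos) %% 2 == 0, "A", "B")
      for (mi in seq_len(muts_per_complex)) {
        mut_aa <- sample(setdiff(names(.AA3), "A"), 1)
        mstring <- paste0("A", chain[mi], pos[mi], mut_aa)
        mu <- parse_mutation(mstring, complex_id = ids[ci])
        fv <- spectral_features(st, mu, config)
        recs[[length(recs) + 1]] <- data.frame(
          complex = ids[ci], mutation = mstring, chain = chain[mi],
          resno = pos[mi], icode = "", wt = "A", mut = mut_aa,
          stringsAsFactors = FALSE)
        feats[[length(feats) + 1]] <- fv
      }
    }
    records <- do.call(rbind, recs)
    X <- do.call(rbind, feats)
    rownames(X) <- NULL

    # plant sparse linear signal on high-variance feature columns
    v <- apply(X, 2, var)
    usable <- which(v > 1e-12)
    ord <- usable[order(v[usable], decreasing = TRUE)]
    idx <- ord[unique(pmax(1, round(seq(1, min(length(ord), 25),
                                        length.out = n_signal))))]
    beta <- c(1, -0.8, 0.6, 0.9, -0.5)[seq_along(idx)]
    signal <- as.numeric(scale(X[, idx, drop = FALSE]) %*% beta)
    if (r2 > 0) {
      signal <- signal / sd(signal) * ddg_sd * sqrt(r2)
      noise <- rnorm(nrow(X), sd = ddg_sd * sqrt(1 - r2))
      records$ddg <- signal + noise
    } else {
      records$ddg <- rnorm(nrow(X), sd = ddg_sd)
    }
    list(records = records, features = X, structures = structures,
         truth = list(columns = colnames(X)[idx], beta = beta,
                      r2_target = r2),
         config = config)
  })
}

#' Write synthetic fixtures to disk
#'
#' Emits a toy complex as a PDB file, a perturbed prediction, a synthetic
#' AF3-style confidence JSON, and a SKEMPI-style mutation CSV, rooting a
#' fully file-based run of the pipeline.
#'
#' @param dir output directory (created if needed).
#' @param config a [synth_config()].
#' @param iptm,ptm confidence scores written to the JSON.
#' @return invisible list of written paths.
#' @export
write_synth_fixtures <- function(dir, config = synth_config(n_residues = 12),
                                 iptm = 0.85, ptm = 0.9) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- make_toy_complex(config, id = "SYN")
  pred <- perturb_structure(st, "flexible", amplitude = 0.4,
                            seed = config$seed + 1)
  p1 <- file.path(dir, "SYN_ref.pdb"); write_structure_pdb(st, p1)
  p2 <- file.path(dir, "SYN_pred.pdb"); write_structure_pdb(pred, p2)
  p3 <- file.path(dir, "SYN_confidence.json")
  jsonlite::write_json(list(iptm = iptm, ptm = ptm), p3, auto_unbox = TRUE)
  p4 <- file.path(dir, "SYN_mutations.csv")
  muts <- data.frame(complex = "SYN",
                     mutation = paste0("AA", c(2, 5, 8), "G"),
                     ddg = c(0.5, -1.2, 2.0))
  write.csv(muts, p4, row.names = FALSE)
  invisible(list(ref = p1, pred = p2, confidence = p3, mutations = p4))
}
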