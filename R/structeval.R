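# Predicted-vs-reference structure comparison: Kabsch superposition,
# chain/residue correspondence via global sequence alignment, per-residue
# backbone RMSD, Shrake-Rupley relative accessible surface area, and the
# five-region interface classification.

#' Kabsch superposition
#'
#' Least-squares optimal rigid-body superposition of paired coordinate
#' sets: SVD of the cross-covariance with the determinant correction that
#' guarantees a proper rotation (det = +1).
#'
#' @param ref_coords,mov_coords `n x 3` matrices of paired coordinates,
#'   `n >= 3`, not all collinear.
#' @return list with `rotation` (3x3), `translation` (length-3), and `rmsd`
#'   (Angstrom) after applying `mov %*% t(R) + t` to the moving set.
#' @export
kabsch_superpose <- function(ref_coords, mov_coords) {
  ref_coords <- as.matrix(ref_coords); mov_coords <- as.matrix(mov_coords)
  n <- nrow(ref_coords)
  if (n != nrow(mov_coords)) stop("coordinate sets must be paired (equal length)")
  if (n < 3) stop("need at least 3 paired points for superposition")
  cr <- colMeans(ref_coords); cm <- colMeans(mov_coords)
  A <- sweep(ref_coords, 2, cr); Bm <- sweep(mov_coords, 2, cm)
  sv <- svd(crossprod(Bm, A))      # 3x3 cross-covariance
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate input: points are (near-)collinear, rotation underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Bm %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)), rmsd = rmsd)
}

#' @noRd
.chain_sequence <- function(structure, chain) {
  a <- structure$atoms
  res <- unique(a[a$chain == chain, c("resno", "icode", "resid")])
  res <- res[order(res$resno, res$icode), , drop = FALSE]
  aa <- .AA1[res$resid]
  keep <- !is.na(aa)
  list(seq = paste(aa[keep], collapse = ""),
       resno = res$resno[keep], icode = res$icode[keep])
}

#' Chain and residue correspondence between two structures
#'
#' Pairs chains by global sequence alignment (Needleman-Wunsch via
#' Biostrings), greedily assigning the chain pairs with the highest
#' percent identity, then maps residues through the aligned positions.
#' Needed because structure-prediction servers renumber and rename chains.
#'
#' @param ref,pred `complex_structure` objects.
#' @param min_identity smallest acceptable identity (fraction) for the best
#'   chain pairing; below it the files are presumed mispaired.
#' @return a `chain_map` object: list with `chains` (data frame ref/pred
#'   chain pairs and identity), `residues` (data frame `ref_chain`,
#'   `ref_resno`, `ref_icode`, `pred_chain`, `pred_resno`, `pred_icode`),
#'   and counts `n_unmapped_ref`, `n_unmapped_pred`.
#' @export
chain_map <- function(ref, pred, min_identity = 0.3) {
  rc <- unique(ref$atoms$chain); pc <- unique(pred$atoms$chain)
  rseq <- lapply(rc, function(ch) .chain_sequence(ref, ch))
  pseq <- lapply(pc, function(ch) .chain_sequence(pred, ch))
  names(rseq) <- rc; names(pseq) <- pc

  aln <- list(); idm <- matrix(0, length(rc), length(pc), dimnames = list(rc, pc))
  for (i in rc) for (j in pc) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(rseq[[i]]$seq), Biostrings::AAString(pseq[[j]]$seq),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    aln[[paste(i, j)]] <- al
    idm[i, j] <- Biostrings::pid(al) / 100
  }
  # greedy assignment by identity
  pairs <- NULL; m <- idm
  while (nrow(m) > 0 && ncol(m) > 0 && max(m) > -Inf) {
    best <- which(m == max(m), arr.ind = TRUE)[1, , drop = FALSE]
    pairs <- rbind(pairs, data.frame(ref_chain = rownames(m)[best[1]],
                                     pred_chain = colnames(m)[best[2]],
                                     identity = m[best], stringsAsFactors = FALSE))
    m <- m[-best[1], -best[2], drop = FALSE]
  }
  if (max(pairs$identity) < min_identity)
    stop("best chain pairing has identity ", round(max(pairs$identity), 3),
         " < ", min_identity, "; reference and prediction are likely mispaired")
  pairs <- pairs[pairs$identity >= min_identity, , drop = FALSE]

  res_map <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$ref_chain[k]; j <- pairs$pred_chain[k]
    al <- aln[[paste(i, j)]]
    ap <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    ri <- 0L; pi <- 0L
    rows <- list()
    for (pos in seq_along(ap)) {
      if (ap[pos] != "-") ri <- ri + 1L
      if (as_[pos] != "-") pi <- pi + 1L
      if (ap[pos] != "-" && as_[pos] != "-") {
        rows[[length(rows) + 1]] <- data.frame(
          ref_chain = i, ref_resno = rseq[[i]]$resno[ri],
          ref_icode = rseq[[i]]$icode[ri],
          pred_chain = j, pred_resno = pseq[[j]]$resno[pi],
          pred_icode = pseq[[j]]$icode[pi], stringsAsFactors = FALSE)
      }
    }
    res_map[[k]] <- do.call(rbind, rows)
  }
  residues <- do.call(rbind, res_map)
  n_ref <- sum(vapply(rseq, function(s) length(s$resno), 0L))
  n_pred <- sum(vapply(pseq, function(s) length(s$resno), 0L))
  structure(list(chains = pairs, residues = residues,
                 n_unmapped_ref = n_ref - nrow(residues),
                 n_unmapped_pred = n_pred - nrow(residues)),
            class = "chain_map")
}

#' @export
print.chain_map <- function(x, ...) {
  cat("chain_map:", nrow(x$residues), "mapped residues;",
      x$n_unmapped_ref, "unmapped (ref),", x$n_unmapped_pred, "unmapped (pred)\n")
  print(x$chains, row.names = FALSE)
  invisible(x)
}

#' @noRd
.backbone <- c("N", "CA", "C", "O")

#' Per-residue backbone RMSD report
#'
#' One global Kabsch superposition on all mapped backbone atoms (N, CA, C,
#' O where present in both structures); the per-residue RMSD is the RMS
#' deviation of each residue's backbone atoms under that single global
#' transform — no per-residue refitting — so flexible regions stand out
#' against the rigid global frame. Reference B-factors (backbone mean) are
#' carried along for flexibility/accuracy concordance analyses.
#'
#' @param ref,pred `complex_structure` objects.
#' @param mapping optional [chain_map()] result (computed if omitted).
#' @return an `alignment_report`: list with `complex_id`, `global_rmsd`
#'   (Angstrom), `per_residue` (data frame `chain`, `resno`, `icode`,
#'   `resid`, `rmsd`, `bfactor`), `n_mapped`, `n_unmapped_ref`,
#'   `n_unmapped_pred`, and the `confidence` scores of `pred` when present.
#' @export
per_residue_rmsd <- function(ref, pred, mapping = NULL) {
  if (is.null(mapping)) mapping <- chain_map(ref, pred)
  res <- mapping$residues
  if (is.null(res) || nrow(res) == 0) stop("empty residue mapping")

  ra <- ref$atoms; pa <- pred$atoms
  ra_key <- .residue_key(ra$chain, ra$resno, ra$icode)
  pa_key <- .residue_key(pa$chain, pa$resno, pa$icode)
  ref_rows <- list(); mov_rows <- list(); owner <- list()
  skipped <- 0L
  for (k in seq_len(nrow(res))) {
    rk <- .residue_key(res$ref_chain[k], res$ref_resno[k], res$ref_icode[k])
    pk <- .residue_key(res$pred_chain[k], res$pred_resno[k], res$pred_icode[k])
    rres <- ra[ra_key == rk & ra$elety %in% .backbone, , drop = FALSE]
    pres <- pa[pa_key == pk & pa$elety %in% .backbone, , drop = FALSE]
    common <- intersect(rres$elety, pres$elety)
    if (length(common) == 0) { skipped <- skipped + 1L; next }
    rres <- rres[match(common, rres$elety), , drop = FALSE]
    pres <- pres[match(common, pres$elety), , drop = FALSE]
    ref_rows[[length(ref_rows) + 1]] <- rres
    mov_rows[[length(mov_rows) + 1]] <- pres
    owner[[length(owner) + 1]] <- rep(k, length(common))
  }
  if (length(ref_rows) == 0) stop("no common backbone atoms between structures")
  R <- do.call(rbind, ref_rows); M <- do.call(rbind, mov_rows)
  own <- unlist(owner)
  fit <- kabsch_superpose(as.matrix(R[, c("x", "y", "z")]),
                          as.matrix(M[, c("x", "y", "z")]))
  moved <- as.matrix(M[, c("x", "y", "z")]) %*% t(fit$rotation) +
    matrix(fit$translation, nrow(M), 3, byrow = TRUE)
  dev2 <- rowSums((moved - as.matrix(R[, c("x", "y", "z")]))^2)

  per <- do.call(rbind, lapply(unique(own), function(k) {
    sel <- own == k
    data.frame(chain = res$ref_chain[k], resno = res$ref_resno[k],
               icode = res$ref_icode[k],
               resid = R$resid[sel][1],
               rmsd = sqrt(mean(dev2[sel])),
               bfactor = mean(R$b[sel]), stringsAsFactors = FALSE)
  }))
  structure(list(complex_id = ref$id,
                 global_rmsd = sqrt(mean(dev2)),
                 per_residue = per,
                 n_mapped = length(unique(own)),
                 n_unmapped_ref = mapping$n_unmapped_ref + skipped,
                 n_unmapped_pred = mapping$n_unmapped_pred + skipped,
                 confidence = pred$confidence),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat("alignment_report '", x$complex_id, "': global backbone RMSD ",
      round(x$global_rmsd, 3), " A over ", x$n_mapped, " residues (",
      x$n_unmapped_ref, "/", x$n_unmapped_pred, " unmapped ref/pred)\n",
      sep = "")
  invisible(x)
}

# evenly distributed unit sphere points (golden spiral)
#' @noRd
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley relative accessible surface area
#'
#' Per-atom accessible surface area by the Shrake-Rupley sphere-point
#' method (probe radius 1.4 A, 960 test points per atom, standard van der
#' Waals radii), summed per residue and divided by the residue's
#' theoretical maximum ASA, giving the relative ASA (rASA). Values can
#' slightly exceed 1 for terminal residues.
#'
#' @param structure a `complex_structure`.
#' @param chains chain IDs to include as the molecule (default all);
#'   atoms of other chains are ignored entirely (used for monomer rASA).
#' @param n_points sphere test points per atom.
#' @param probe probe radius, Angstrom.
#' @return data frame with `chain`, `resno`, `icode`, `resid`, `asa`
#'   (Angstrom^2) and `rasa` per residue.
#' @export
shrake_rupley_rasa <- function(structure, chains = NULL, n_points = 960,
                               probe = 1.4) {
  a <- structure$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  a <- a[a$element != "H", , drop = FALSE]
  if (nrow(a) == 0) stop("no heavy atoms selected")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- .vdw_radius(a$element) + probe
  sp <- .sphere_points(n_points)
  n <- nrow(a)
  maxr <- max(rad)
  asa <- numeric(n)
  # neighbor lists via cutoff on pair distances
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rad[i] + rad[nb])^2]
    pts <- sp * rad[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(buried)) break
        dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        buried <- buried | dj2 < rad[j]^2
      }
      acc <- sum(!buried)
    }
    asa[i] <- 4 * pi * rad[i]^2 * acc / n_points
  }
  key <- .residue_key(a$chain, a$resno, a$icode)
  agg <- rowsum(asa, key)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    icode = a$icode[first], resid = a$resid[first],
                    stringsAsFactors = FALSE)
  out$asa <- agg[match(key[first], rownames(agg)), 1]
  mx <- .MAX_ASA[out$resid]
  mx[is.na(mx)] <- mean(.MAX_ASA)
  out$rasa <- out$asa / mx
  out
}

#' Classify residues into the five rASA structural regions
#'
#' Residues of the two partner sides are labelled by comparing the relative
#' accessible surface area computed on the side in isolation (monomer) and
#' in the full complex, against the 25% exposure cutoff. Non-interface
#' residues (burial change below `delta`): `interior` when the complex
#' rASA is below the cutoff, else `surface`. Interface residues (burial
#' change at least `delta`): `support` when already buried as a monomer,
#' `core` when exposed as a monomer but buried in the complex, `rim` when
#' still exposed in the complex.
#'
#' @param structure a `complex_structure` with a partner split.
#' @param cutoff rASA exposure cutoff (default 0.25).
#' @param delta smallest monomer-to-complex rASA drop counting as interface
#'   burial (default 0.001 — any measurable burial, guarded against
#'   numerical noise).
#' @param ... passed to [shrake_rupley_rasa()].
#' @return data frame with `chain`, `resno`, `icode`, `resid`,
#'   `rasa_monomer`, `rasa_complex` and `region` (one of `interior`,
#'   `surface`, `support`, `rim`, `core`).
#' @export
classify_regions <- function(structure, cutoff = 0.25, delta = 0.001, ...) {
  ps <- structure$partner_split
  cx <- shrake_rupley_rasa(structure, chains = c(ps$p1, ps$p2), ...)
  mono <- rbind(shrake_rupley_rasa(structure, chains = ps$p1, ...),
                shrake_rupley_rasa(structure, chains = ps$p2, ...))
  key_cx <- .residue_key(cx$chain, cx$resno, cx$icode)
  key_mono <- .residue_key(mono$chain, mono$resno, mono$icode)
  m <- match(key_cx, key_mono)
  out <- cx[, c("chain", "resno", "icode", "resid")]
  out$rasa_monomer <- mono$rasa[m]
  out$rasa_complex <- cx$rasa
  out$region <- classify_region_label(out$rasa_monomer, out$rasa_complex,
                                      cutoff = cutoff, delta = delta)
  out
}

#' @rdname classify_regions
#' @param rasa_monomer,rasa_complex rASA fractions of a residue in its side
#'   alone and in the full complex.
#' @export
classify_region_label <- function(rasa_monomer, rasa_complex, cutoff = 0.25,
                                  delta = 0.001) {
  interface <- (rasa_monomer - rasa_complex) >= delta
  ifelse(!interface,
         ifelse(rasa_complex < cutoff, "interior", "surface"),
         ifelse(rasa_monomer < cutoff, "support",
                ifelse(rasa_complex < cutoff, "core", "rim")))
}

#' Cohort evaluation summary
#'
#' Aggregates alignment reports (and their attached confidence scores) into
#' the cohort statistics used to judge a set of predicted complexes: mean
#' and median superposition RMSD, ipTM and pTM, the fractions above/below
#' the ipTM 0.8 / 0.6 and pTM 0.5 bands, top-n rankings by RMSD (worst
#' first) and ipTM (lowest first), the pooled per-residue (B-factor, RMSD)
#' table, and optional per-region boxplot statistics.
#'
#' @param reports list of `alignment_report` objects.
#' @param regions optional named list (by complex id) of [classify_regions()]
#'   tables; when given, per-region RMSD min/median/max are reported.
#' @param top_n length of the rankings (default 40).
#' @return an `evaluation_summary` list.
#' @export
evaluation_summary <- function(reports, regions = NULL, top_n = 40) {
  if (length(reports) == 0) stop("need at least one report")
  rmsd <- vapply(reports, `[[`, 0, "global_rmsd")
  id <- vapply(reports, `[[`, "", "complex_id")
  iptm <- vapply(reports, function(r)
    if (is.null(r$confidence)) NA_real_ else r$confidence$iptm, 0)
  ptm <- vapply(reports, function(r)
    if (is.null(r$confidence)) NA_real_ else r$confidence$ptm, 0)

  per_res <- do.call(rbind, lapply(reports, function(r)
    cbind(complex_id = r$complex_id, r$per_residue)))

  region_stats <- NULL
  if (!is.null(regions)) {
    per_res$region <- NA_character_
    for (cid in names(regions)) {
      reg <- regions[[cid]]
      sel <- per_res$complex_id == cid
      m <- match(.residue_key(per_res$chain[sel], per_res$resno[sel],
                              per_res$icode[sel]),
                 .residue_key(reg$chain, reg$resno, reg$icode))
      per_res$region[sel] <- reg$region[m]
    }
    ok <- !is.na(per_res$region)
    region_stats <- do.call(rbind, lapply(
      split(per_res$rmsd[ok], per_res$region[ok]), function(v)
        data.frame(n = length(v), min = min(v), median = median(v),
                   max = max(v))))
    region_stats <- cbind(region = rownames(region_stats), region_stats)
    rownames(region_stats) <- NULL
  }

  structure(list(
    n = length(reports),
    mean_rmsd = mean(rmsd), median_rmsd = median(rmsd),
    mean_iptm = mean(iptm, na.rm = TRUE), median_iptm = median(iptm, na.rm = TRUE),
    mean_ptm = mean(ptm, na.rm = TRUE), median_ptm = median(ptm, na.rm = TRUE),
    frac_iptm_high = mean(iptm >= 0.8, na.rm = TRUE),
    frac_iptm_low = mean(iptm < 0.6, na.rm = TRUE),
    frac_ptm_ge_0.5 = mean(ptm >= 0.5, na.rm = TRUE),
    ranking_rmsd = data.frame(complex_id = id, rmsd = rmsd)[
      order(-rmsd), ][seq_len(min(top_n, length(id))), ],
    ranking_iptm = data.frame(complex_id = id, iptm = iptm)[
      order(iptm), ][seq_len(min(top_n, length(id))), ],
    per_residue = per_res,
    region_stats = region_stats),
    class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("evaluation_summary over", x$n, "complexes\n")
  cat(sprintf("  mean RMSD %.3f A (median %.3f)\n", x$mean_rmsd, x$median_rmsd))
  if (is.finite(x$mean_iptm))
    cat(sprintf("  mean ipTM %.3f, mean pTM %.3f; %.1f%% ipTM >= 0.8, %.1f%% ipTM < 0.6, %.1f%% pTM >= 0.5\n",
                x$mean_iptm, x$mean_ptm, 100 * x$frac_iptm_high,
                100 * x$frac_iptm_low, 100 * x$frac_ptm_ge_0.5))
  invisible(x)
}
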