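# Element/site-specific atom subsets and the modified distance matrix that
# feed the topological featurization.

#' Parse a SKEMPI-style mutation string
#'
#' Mutation strings follow the SKEMPI 2.0 convention `"EA38G"`: wild-type
#' amino acid (1-letter), chain ID (second character), residue position
#' (with optional insertion code suffix), mutant amino acid.
#'
#' @param x mutation string, e.g. `"EA38G"` or `"YC100aF"`.
#' @param complex_id optional complex identifier carried along.
#' @param ddg optional measured ddG (kcal/mol).
#' @return a `mutation_spec` object: list with `complex_id`, `chain`,
#'   `resno`, `icode`, `wt`, `mut`, `ddg`.
#' @export
parse_mutation <- function(x, complex_id = NA_character_, ddg = NA_real_) {
  m <- regmatches(x, regexec("^([A-Y])(.)([0-9]+)([a-z]?)([A-Y])$", x))[[1]]
  if (length(m) == 0)
    stop("cannot parse mutation string '", x,
         "' (expected e.g. 'EA38G': wt, chain, position, mut)")
  wt <- m[2]; mut <- m[6]
  if (wt == mut) stop("wild-type and mutant residues are identical in '", x, "'")
  structure(list(complex_id = complex_id, chain = m[3],
                 resno = as.integer(m[4]), icode = m[5],
                 wt = wt, mut = mut, ddg = ddg),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("mutation ", x$wt, x$chain, x$resno, x$icode, x$mut,
      if (!is.na(x$ddg)) paste0("  (ddG = ", x$ddg, " kcal/mol)"), "\n", sep = "")
  invisible(x)
}

#' Read a SKEMPI-style mutation table
#'
#' Expects a CSV with columns `complex`, `mutation` (SKEMPI string, see
#' [parse_mutation()]) and `ddg` (kcal/mol).
#'
#' @param path path to the CSV file.
#' @return data frame with columns `complex`, `mutation`, `chain`, `resno`,
#'   `icode`, `wt`, `mut`, `ddg`.
#' @export
read_mutation_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("complex", "mutation", "ddg")
  if (!all(need %in% names(tab)))
    stop("mutation table must have columns ", paste(need, collapse = ", "))
  parsed <- lapply(seq_len(nrow(tab)), function(i)
    parse_mutation(tab$mutation[i], tab$complex[i], tab$ddg[i]))
  data.frame(complex = tab$complex, mutation = tab$mutation,
             chain = vapply(parsed, `[[`, "", "chain"),
             resno = vapply(parsed, `[[`, 0L, "resno"),
             icode = vapply(parsed, `[[`, "", "icode"),
             wt = vapply(parsed, `[[`, "", "wt"),
             mut = vapply(parsed, `[[`, "", "mut"),
             ddg = tab$ddg, stringsAsFactors = FALSE)
}

#' @noRd
.new_atom_subset <- function(label, elements, atoms) {
  structure(list(label = label, elements = elements, atoms = atoms),
            class = "atom_subset")
}

#' @export
print.atom_subset <- function(x, ...) {
  cat("atom_subset '", x$label, "' ({",
      paste(x$elements, collapse = ","), "}): ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' @noRd
.subset_coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

# locate the mutated residue and check the recorded wild type against it
#' @noRd
.resolve_mutation_residue <- function(structure, mutation) {
  a <- structure$atoms
  sel <- a$chain == mutation$chain & a$resno == mutation$resno &
    a$icode == (if (is.null(mutation$icode)) "" else mutation$icode)
  if (!any(sel))
    stop("mutation residue ", mutation$chain, mutation$resno, mutation$icode,
         " not found in structure '", structure$id, "'")
  res <- a[sel, , drop = FALSE]
  found <- unique(res$resid)
  if (length(found) != 1)
    stop("mutation position resolves to multiple residue names: ",
         paste(found, collapse = ", "))
  expected <- .AA3[mutation$wt]
  if (is.na(expected) || found != expected)
    stop("wild-type mismatch at ", mutation$chain, mutation$resno,
         ": table says ", mutation$wt, " (", expected, ") but structure has ",
         found)
  sel
}

#' Atoms of the mutation site
#'
#' All atoms of the mutated residue, filtered by element group. Featurization
#' uses wild-type geometry only; the mutant side chain is never rebuilt.
#'
#' @param structure a `complex_structure`.
#' @param mutation a `mutation_spec` (see [parse_mutation()]).
#' @param elements element symbols to keep (default the heavy-atom group
#'   `{C, N, O}`).
#' @return an `atom_subset` with label `"site"`.
#' @export
mutation_site_atoms <- function(structure, mutation, elements = c("C", "N", "O")) {
  sel <- .resolve_mutation_residue(structure, mutation)
  atoms <- structure$atoms[sel & structure$atoms$element %in% elements, , drop = FALSE]
  .new_atom_subset("site", elements, atoms)
}

#' Atoms in the mutation neighborhood
#'
#' Atoms within distance `r` of any mutation-site atom, excluding the
#' mutated residue's own atoms, filtered by element group. An empty result
#' is valid (flagged by zero rows), e.g. for an exposed terminal residue
#' with a small radius.
#'
#' @inheritParams mutation_site_atoms
#' @param r neighborhood radius in Angstrom (default 10).
#' @return an `atom_subset` with label `"neighborhood"`.
#' @export
neighborhood_atoms <- function(structure, mutation, r = 10,
                               elements = c("C", "N", "O")) {
  if (!is.numeric(r) || r <= 0) stop("radius r must be positive")
  sel <- .resolve_mutation_residue(structure, mutation)
  site <- as.matrix(structure$atoms[sel, c("x", "y", "z")])
  rest <- structure$atoms[!sel, , drop = FALSE]
  rest <- rest[rest$element %in% elements, , drop = FALSE]
  if (nrow(rest) > 0) {
    d2 <- .min_cross_dist2(as.matrix(rest[, c("x", "y", "z")]), site)
    rest <- rest[d2 <= r^2, , drop = FALSE]
  }
  .new_atom_subset("neighborhood", elements, rest)
}

#' Binding-site atoms of one partner
#'
#' Atoms of the named side (protein 1 or protein 2 of the partner split)
#' lying within distance `r` of any atom of the opposite side, filtered by
#' element group.
#'
#' @inheritParams neighborhood_atoms
#' @param side `"p1"` or `"p2"`.
#' @return an `atom_subset` with label `"p1_binding"` or `"p2_binding"`.
#' @export
binding_site_atoms <- function(structure, side = c("p1", "p2"), r = 10,
                               elements = c("C", "N", "O")) {
  side <- match.arg(side)
  if (!is.numeric(r) || r <= 0) stop("radius r must be positive")
  ps <- structure$partner_split
  own_chains <- ps[[side]]
  other_chains <- ps[[setdiff(c("p1", "p2"), side)]]
  a <- structure$atoms
  own <- a[a$chain %in% own_chains, , drop = FALSE]
  other <- a[a$chain %in% other_chains, , drop = FALSE]
  if (nrow(own) == 0) stop("side '", side, "' has no atoms")
  if (nrow(other) == 0) stop("opposite side of '", side, "' has no atoms")
  own <- own[own$element %in% elements, , drop = FALSE]
  if (nrow(own) > 0) {
    d2 <- .min_cross_dist2(as.matrix(own[, c("x", "y", "z")]),
                           as.matrix(other[, c("x", "y", "z")]))
    own <- own[d2 <= r^2, , drop = FALSE]
  }
  .new_atom_subset(paste0(side, "_binding"), elements, own)
}

# squared distance from each row of a to the nearest row of b
#' @noRd
.min_cross_dist2 <- function(a, b) {
  if (nrow(b) == 0) return(rep(Inf, nrow(a)))
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b, in one BLAS call
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  pmax(apply(d2, 1, min), 0)
}

#' Modified pair-distance matrix with same-subset exclusion
#'
#' Builds the modified distance `D_mod` over the union of two atom subsets:
#' the entry for a pair drawn from different subsets is their Euclidean
#' distance, while pairs from the same subset (including the diagonal) are
#' excluded — set beyond every filtration scale — so that only cross-set
#' interactions can ever form simplices. Exclusions are encoded as `Inf`;
#' the Vietoris-Rips builder never forms edges on non-finite entries.
#'
#' @param set_a,set_b `atom_subset` objects from the same structure. If the
#'   same subset is passed twice the matrix is fully excluded.
#' @return a `pair_distance_matrix`: list with the symmetric numeric matrix
#'   `values` (`Inf` marks exclusion), the membership vector `subset`
#'   (`"a"`/`"b"` per row), and the two subset labels.
#' @export
dmod_matrix <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "atom_subset"), inherits(set_b, "atom_subset"))
  if (identical(set_a, set_b)) {
    # one subset against itself: every pair shares the subset, all excluded
    ca <- .subset_coords(set_a)
    n <- nrow(ca)
    return(structure(list(values = matrix(Inf, n, n),
                          subset = rep("a", n),
                          labels = c(set_a$label, set_b$label),
                          points = ca),
                     class = "pair_distance_matrix"))
  }
  ca <- .subset_coords(set_a); cb <- .subset_coords(set_b)
  na <- nrow(ca); nb <- nrow(cb)
  pts <- rbind(ca, cb)
  n <- na + nb
  values <- matrix(Inf, n, n)
  if (na > 0 && nb > 0) {
    a2 <- rowSums(ca^2); b2 <- rowSums(cb^2)
    cross2 <- pmax(outer(a2, b2, "+") - 2 * tcrossprod(ca, cb), 0)
    cross <- sqrt(cross2)
    values[seq_len(na), na + seq_len(nb)] <- cross
    values[na + seq_len(nb), seq_len(na)] <- t(cross)
  }
  structure(list(values = values,
                 subset = rep(c("a", "b"), c(na, nb)),
                 labels = c(set_a$label, set_b$label),
                 points = pts),
            class = "pair_distance_matrix")
}

#' @export
print.pair_distance_matrix <- function(x, ...) {
  cat("pair_distance_matrix (", x$labels[1], " x ", x$labels[2], "): ",
      nrow(x$values), " atoms, ",
      sum(is.finite(x$values[upper.tri(x$values)])), " finite pairs\n", sep = "")
  invisible(x)
}
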