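# Structure input/output: PDB / mmCIF readers (bio3d backend), a PDB writer
# for fixtures, and AF3-style confidence metadata parsing.

#' Read a protein-protein complex structure
#'
#' Parses a PDB or mmCIF file into the package's complex representation:
#' a flat atom table plus a two-side partner partition designating the two
#' interacting proteins. Only `ATOM` records of the first model are kept;
#' heteroatoms and waters are dropped; alternate locations are resolved to
#' the highest-occupancy conformer. Residue numbering follows the
#' author-assigned scheme in the file (no renumbering), because mutation
#' tables reference author numbering.
#'
#' @param path path to a structure file.
#' @param partners the partner split: either a string `"A:B"` (chain IDs of
#'   protein 1 and protein 2 separated by `:`, several chains per side
#'   allowed, e.g. `"AB:C"`) or a list with elements `p1` and `p2` of chain
#'   IDs.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param id complex identifier; defaults to the file name without extension.
#' @return an object of class `complex_structure`: a list with elements
#'   `id`, `atoms` (data frame with columns `chain`, `resno`, `icode`,
#'   `resid`, `elety`, `element`, `x`, `y`, `z`, `b`, `occ`), `partner_split`
#'   (list `p1`, `p2` of chain IDs) and `confidence` (`NULL` until attached
#'   via [parse_confidence()]).
#' @seealso [write_structure_pdb()], [parse_confidence()]
#' @export
read_structure <- function(path, partners, format = c("auto", "pdb", "mmcif"),
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                         verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  atoms <- data.frame(
    chain   = as.character(at$chain),
    resno   = as.integer(at$resno),
    icode   = ifelse(is.na(at$insert) | at$insert == "", "", as.character(at$insert)),
    resid   = as.character(at$resid),
    elety   = as.character(at$elety),
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             substr(gsub("[0-9']", "", at$elety), 1, 1),
                             at$elesy)),
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b),
    occ = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    stringsAsFactors = FALSE)
  atoms <- .resolve_altloc(atoms)
  new_complex_structure(
    id = if (is.null(id)) tools::file_path_sans_ext(basename(path)) else id,
    atoms = atoms,
    partner_split = .parse_partners(partners, unique(atoms$chain)))
}

#' @noRd
.parse_partners <- function(partners, available) {
  if (is.character(partners) && length(partners) == 1) {
    sides <- strsplit(partners, ":", fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("partner string must look like 'A:B'")
    partners <- list(p1 = strsplit(sides[1], "")[[1]],
                     p2 = strsplit(sides[2], "")[[1]])
  }
  if (!is.list(partners) || !all(c("p1", "p2") %in% names(partners)))
    stop("partners must be 'A:B' or list(p1 = ..., p2 = ...)")
  p1 <- as.character(partners$p1); p2 <- as.character(partners$p2)
  if (length(p1) == 0 || length(p2) == 0) stop("both partner sides must be non-empty")
  if (length(intersect(p1, p2)) > 0) stop("partner sides must be disjoint")
  missing <- setdiff(c(p1, p2), available)
  if (length(missing) > 0)
    stop("partner chain(s) ", paste(missing, collapse = ", "),
         " not present in structure; available chains: ",
         paste(available, collapse = ", "))
  list(p1 = p1, p2 = p2)
}

# keep, per (chain, resno, icode, atom name), the highest-occupancy conformer
#' @noRd
.resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety)
  if (!anyDuplicated(key)) { atoms$altloc <- NULL; return(atoms) }
  ord <- order(key, -atoms$occ)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resno, atoms$icode), , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  atoms
}

#' Construct a complex_structure object
#'
#' Low-level constructor used by the readers and the synthetic generator;
#' validates the atom table and the partner split.
#'
#' @param id complex identifier.
#' @param atoms atom data frame (see [read_structure()] for columns).
#' @param partner_split list with chain-ID vectors `p1` and `p2`.
#' @param confidence optional `confidence_scores` object.
#' @return a `complex_structure` object.
#' @export
new_complex_structure <- function(id, atoms, partner_split, confidence = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("chain", "resno", "icode", "resid", "elety", "element",
            "x", "y", "z", "b", "occ")
  if (!all(need %in% names(atoms)))
    stop("atom table missing column(s): ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(atoms$element == "")) stop("empty element symbols in atom table")
  if (any(atoms$b < 0)) stop("negative B-factors in atom table")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancy outside [0,1]")
  partner_split <- .parse_partners(partner_split, unique(atoms$chain))
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, partner_split = partner_split,
                 confidence = confidence),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "icode")]))
  cat("complex_structure '", x$id, "': ",
      length(unique(x$atoms$chain)), " chains, ",
      nres, " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  cat("  partners: P1 = {", paste(x$partner_split$p1, collapse = ","),
      "}, P2 = {", paste(x$partner_split$p2, collapse = ","), "}\n", sep = "")
  if (!is.null(x$confidence))
    cat("  confidence: ipTM =", x$confidence$iptm, " pTM =", x$confidence$ptm, "\n")
  invisible(x)
}

#' Write a complex structure as a PDB file
#'
#' Fixture-grade PDB writer (delegates to bio3d). Coordinates keep the
#' conventional 3-decimal precision of the format.
#'
#' @param structure a `complex_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno,
                   chain = a$chain, resid = a$resid, elety = a$elety,
                   insert = ifelse(a$icode == "", "", a$icode),
                   o = a$occ, b = a$b, elesy = a$element)
  invisible(path)
}

# ---------------------------------------------------------------------------
# AF3-style confidence metadata

#' Parse AF3-style confidence metadata
#'
#' Reads a JSON summary carrying the predicted interface TM-score (ipTM) and
#' predicted TM-score (pTM) of a predicted complex. Two dialects are
#' accepted: a flat summary with `iptm` / `ptm` fields, and a per-chain-pair
#' matrix (`chain_pair_iptm`), which is reduced to the mean of the
#' off-diagonal (cross-partner) entries. A missing field yields an absent
#' score (`NA`), never zero.
#'
#' @param path path to a JSON confidence file.
#' @return a `confidence_scores` object: list with numeric `iptm` and `ptm`
#'   (either may be `NA` when absent).
#' @export
parse_confidence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- tryCatch(jsonlite::fromJSON(path),
                 error = function(e) stop("malformed confidence file '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  pick <- function(keys) {
    for (k in keys) if (!is.null(js[[k]])) return(as.numeric(js[[k]])[1])
    NA_real_
  }
  iptm <- pick(c("iptm", "ipTM"))
  ptm <- pick(c("ptm", "pTM"))
  if (is.na(iptm) && !is.null(js$chain_pair_iptm)) {
    m <- as.matrix(js$chain_pair_iptm)
    if (nrow(m) >= 2) iptm <- mean(m[row(m) != col(m)], na.rm = TRUE)
  }
  new_confidence_scores(iptm, ptm)
}

#' @rdname parse_confidence
#' @param iptm,ptm scores in `[0, 1]`, or `NA` when absent.
#' @export
new_confidence_scores <- function(iptm = NA_real_, ptm = NA_real_) {
  for (v in list(iptm = iptm, ptm = ptm)) {
    if (!is.na(v) && (v < 0 || v > 1))
      stop("confidence scores must lie in [0, 1]; got ", v)
  }
  structure(list(iptm = iptm, ptm = ptm), class = "confidence_scores")
}

#' Classify a predicted complex by its ipTM score
#'
#' AF3's interface confidence bands: an ipTM above 0.8 marks a highly
#' confident interface prediction, below 0.6 a likely-incorrect one, and
#' anything between 0.6 and 0.8 may be either.
#'
#' @param scores a `confidence_scores` object (ipTM must be present).
#' @return one of `"high_confidence"`, `"ambiguous"`, `"likely_incorrect"`.
#' @export
classify_confidence <- function(scores) {
  iptm <- if (inherits(scores, "confidence_scores")) scores$iptm else as.numeric(scores)
  if (is.na(iptm)) stop("ipTM score absent; cannot classify")
  if (iptm > 0.8) "high_confidence"
  else if (iptm < 0.6) "likely_incorrect"
  else "ambiguous"
}
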