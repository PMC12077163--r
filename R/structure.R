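# Minimal structure utility for dimer-interface checks: read a complex
# (PDB/mmCIF), measure polar heavy-atom distances between residues of two
# chains, and list cross-chain contacts. Enough to verify a reported
# interface hydrogen bond from a coordinate file; no modeling.

#' Read a macromolecular complex
#'
#' Parses a PDB or mmCIF coordinate file (via bio3d) into a flat atom
#' table. Only the first model is used; waters and hydrogens are excluded
#' by default; alternate locations are resolved to the highest-occupancy
#' copy of each atom.
#'
#' @param path Coordinate file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @param keep_waters,keep_hydrogens Keep waters / hydrogens?
#' @return Object of class `structure_complex`: list with `atoms`, a
#'   `data.frame` of `chain`, `resno`, `resid`, `atom` (atom name),
#'   `element`, `x`, `y`, `z`, `occupancy`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_waters = FALSE, keep_hydrogens = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
      "mmcif"
    } else {
      "pdb"
    }
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE),
    error = function(e) {
      stop("read_structure(): cannot parse '", path, "' as ", format, ": ",
           conditionMessage(e))
    })
  at <- parsed$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- bio3d::atom2ele(at$elety)
  } else {
    blank <- is.na(elem) | elem == ""
    if (any(blank)) elem[blank] <- bio3d::atom2ele(at$elety[blank])
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      atom = at$elety, element = toupper(trimws(elem)),
                      x = at$x, y = at$y, z = at$z,
                      occupancy = if (is.null(at$o)) 1 else at$o,
                      alt = if (is.null(at$alt)) NA_character_ else at$alt,
                      stringsAsFactors = FALSE)
  if (!keep_waters) {
    atoms <- atoms[!atoms$resid %in% c("HOH", "WAT", "DOD", "H2O"), ]
  }
  if (!keep_hydrogens) atoms <- atoms[!atoms$element %in% c("H", "D"), ]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("read_structure(): non-finite coordinates in '", path, "'")
  }
  # altloc: keep the highest-occupancy copy of each (chain, residue, atom)
  if (any(!is.na(atoms$alt) & atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$atom)
    atoms <- atoms[order(key, -atoms$occupancy), ]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$resid,
                                     atoms$atom)), ]
  }
  atoms$alt <- NULL
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_complex")
}

#' @export
print.structure_complex <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat(sprintf("<structure_complex> %d atoms; chains: %s\n", nrow(x$atoms),
              paste(sprintf("%s (%d)", names(ch), ch), collapse = ", ")))
  invisible(x)
}

#' Write a complex as a minimal PDB file
#'
#' Emits standard fixed-width ATOM records (serial, atom name, residue,
#' chain, coordinates, occupancy, element) — sufficient to round-trip the
#' atom table through [read_structure()].
#'
#' @param sc A `structure_complex`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(sc, path) {
  a <- sc$atoms
  name <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom),
                 sprintf("%-4s", a$atom))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name, a$resid, a$chain, a$resno,
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# atoms of one residue; lookup error names the chain and residue
residue_atoms <- function(sc, chain, resno, elements = NULL) {
  at <- sc$atoms[sc$atoms$chain == chain & sc$atoms$resno == resno, ,
                 drop = FALSE]
  if (nrow(at) == 0L) {
    stop("residue ", resno, " not found in chain ", chain)
  }
  if (!is.null(elements)) at <- at[at$element %in% elements, , drop = FALSE]
  at
}

# all pairwise distances between two atom tables
cross_distances <- function(a, b) {
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Minimum polar heavy-atom distance between two residues
#'
#' Shortest Euclidean distance over pairs of polar heavy atoms (N or O,
#' backbone included — glycine has no side chain) drawn one from each
#' residue. This is the operational stand-in for a hydrogen bond used for
#' single-number interface checks: no hydrogen placement, no angle
#' criterion. Reported rounded to one decimal, with the raw value attached
#' as attribute `"raw"`.
#'
#' @param sc A `structure_complex`.
#' @param chainA,resA First residue (chain id, residue number).
#' @param chainB,resB Second residue.
#' @return Distance in Angstrom, rounded to one decimal; `attr(, "raw")`
#'   holds the unrounded value.
#' @export
min_polar_distance <- function(sc, chainA, resA, chainB, resB) {
  a <- residue_atoms(sc, chainA, resA, elements = c("N", "O"))
  b <- residue_atoms(sc, chainB, resB, elements = c("N", "O"))
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("min_polar_distance(): no polar heavy atoms in ",
         if (nrow(a) == 0L) paste0(chainA, ":", resA)
         else paste0(chainB, ":", resB))
  }
  d <- min(cross_distances(a, b))
  structure(round(d, 1), raw = d)
}

#' Cross-chain residue contacts under a distance cutoff
#'
#' All residue pairs, one residue from each chain, whose minimum
#' heavy-atom distance (any element) is at most `cutoff`, sorted by
#' distance.
#'
#' @param sc A `structure_complex`.
#' @param chainA,chainB Chain identifiers.
#' @param cutoff Distance cutoff in Angstrom (> 0, or 0 for an empty list).
#' @return `data.frame` with `resno_a`, `resid_a`, `resno_b`, `resid_b`,
#'   `distance`, sorted ascending.
#' @export
interface_contacts <- function(sc, chainA, chainB, cutoff) {
  stopifnot(cutoff >= 0)
  a <- sc$atoms[sc$atoms$chain == chainA, , drop = FALSE]
  b <- sc$atoms[sc$atoms$chain == chainB, , drop = FALSE]
  if (nrow(a) == 0L) stop("interface_contacts(): chain ", chainA, " absent")
  if (nrow(b) == 0L) stop("interface_contacts(): chain ", chainB, " absent")
  d <- cross_distances(a, b)
  ka <- paste(a$resno, a$resid)
  kb <- paste(b$resno, b$resid)
  pairs <- expand.grid(ia = unique(ka), ib = unique(kb),
                       stringsAsFactors = FALSE)
  dist <- mapply(function(ia, ib) min(d[ka == ia, kb == ib]),
                 pairs$ia, pairs$ib)
  keep <- dist <= cutoff
  if (!any(keep)) {
    return(data.frame(resno_a = integer(), resid_a = character(),
                      resno_b = integer(), resid_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  split_key <- function(k) {
    parts <- strsplit(k, " ")
    list(resno = as.integer(vapply(parts, `[`, "", 1)),
         resid = vapply(parts, `[`, "", 2))
  }
  sa <- split_key(pairs$ia[keep]); sb <- split_key(pairs$ib[keep])
  out <- data.frame(resno_a = sa$resno, resid_a = sa$resid,
                    resno_b = sb$resno, resid_b = sb$resid,
                    distance = dist[keep], stringsAsFactors = FALSE)
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  out
}
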