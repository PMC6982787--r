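# Extended-connectivity count fingerprints (ECFC, diameter 6 = radius 3).
# Circular substructure identifiers are grown by iterative neighborhood
# hashing from per-atom invariants; every atom emits one identifier per
# radius 0..3, identifiers are counted (not OR-ed) and folded into a fixed
# width by modulo reduction, so folding conserves the total count.

.HASH_MOD <- 2147483647  # 2^31 - 1 (prime); products stay exact in doubles

.rollHash <- function(values) {
  h <- 7
  for (v in values) h <- (h * 31 + (v %% .HASH_MOD) + 1) %% .HASH_MOD
  h
}

.ELEMENT_ORDER <- names(.ATOMIC_MASS)

#' Raw circular identifiers of a molecule
#'
#' One identifier per atom and radius 0..3 (diameter 6). The radius-0
#' invariant hashes element, heavy-atom degree, hydrogen count, formal
#' charge and aromaticity; each iteration re-hashes an atom's identifier
#' with the sorted (bond order, identifier) pairs of its neighbors, so the
#' result is independent of input atom order.
#'
#' @param mol a [Molecule-class].
#' @param radius maximum radius (default 3).
#' @return integer-valued numeric vector of length `(radius + 1) * nAtoms`.
#' @export
ecfcIdentifiers <- function(mol, radius = 3L) {
  stopifnot(is(mol, "Molecule"))
  n <- nAtoms(mol)
  deg <- atomDegrees(mol)
  elnum <- match(mol@element, .ELEMENT_ORDER)
  elnum[is.na(elnum)] <- length(.ELEMENT_ORDER) + 1L
  ids <- vapply(seq_len(n), function(a)
    .rollHash(c(elnum[a], deg[a], mol@nH[a], mol@charge[a] + 8,
                as.integer(mol@aromatic[a]))), numeric(1))
  b <- mol@bonds
  neighbors <- lapply(seq_len(n), function(a) {
    if (nrow(b) == 0) return(cbind(atom = integer(0), order = integer(0)))
    sel1 <- b[, 1] == a; sel2 <- b[, 2] == a
    cbind(atom = c(b[sel2, 1], b[sel1, 2]),
          order = c(b[sel2, 3], b[sel1, 3]))
  })
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(a) {
      nbr <- neighbors[[a]]
      if (nrow(nbr) == 0) return(.rollHash(c(r, ids[a])))
      o <- order(ids[nbr[, "atom"]], nbr[, "order"])
      pairs <- rbind(nbr[o, "order"], ids[nbr[o, "atom"]])
      .rollHash(c(r, ids[a], as.numeric(pairs)))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  all_ids
}

#' Folded circular count fingerprint (ECFC6)
#'
#' @param mol a [Molecule-class].
#' @param nBits folded width, 1024 or 2048.
#' @return integer vector of length `nBits` with attribute `diameter = 6`;
#'   entries are substructure counts, and `sum(fp) == 4 * nAtoms(mol)`.
#' @examples
#' fp <- ecfcFingerprint(standardizeMolecule("c1ccccc1O"))
#' sum(fp)  # 4 identifiers per heavy atom
#' @export
ecfcFingerprint <- function(mol, nBits = c(2048L, 1024L)) {
  nBits <- as.integer(nBits[1])
  if (!nBits %in% c(1024L, 2048L))
    stop("nBits must be 1024 or 2048")
  ids <- ecfcIdentifiers(mol)
  slot <- (ids %% nBits) + 1
  counts <- integer(nBits)
  tab <- table(slot)
  counts[as.integer(names(tab))] <- as.integer(tab)
  structure(counts, diameter = 6L)
}

#' Fingerprint matrix for a list of molecules
#'
#' @param mols list of [Molecule-class] objects.
#' @param nBits folded width, 1024 or 2048.
#' @return integer matrix, molecules x `nBits`, rownames = compound ids.
#' @export
fingerprintMatrix <- function(mols, nBits = 2048L) {
  out <- t(vapply(mols, function(m) as.integer(ecfcFingerprint(m, nBits)),
                  integer(as.integer(nBits[1]))))
  rownames(out) <- unname(vapply(mols, function(m) m@id, ""))
  out
}

#' Write fingerprints as sparse index:count text
#'
#' One line per molecule: compound id followed by whitespace-separated
#' `index:count` pairs (1-based indices of nonzero slots).
#'
#' @param fps matrix from [fingerprintMatrix()].
#' @param file output path.
#' @export
writeFingerprints <- function(fps, file) {
  lines <- vapply(seq_len(nrow(fps)), function(i) {
    nz <- which(fps[i, ] > 0)
    paste(rownames(fps)[i],
          paste0(nz, ":", fps[i, nz], collapse = " "))
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read fingerprints written by [writeFingerprints()]
#'
#' @param file input path.
#' @param nBits folded width of the stored fingerprints.
#' @return integer matrix, molecules x `nBits`.
#' @export
readFingerprints <- function(file, nBits = 2048L) {
  lines <- readLines(file)
  out <- matrix(0L, length(lines), nBits)
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    ids[i] <- tok[1]
    if (length(tok) > 1) {
      kv <- strsplit(tok[-1], ":", fixed = TRUE)
      idx <- as.integer(vapply(kv, `[`, "", 1))
      out[i, idx] <- as.integer(vapply(kv, `[`, "", 2))
    }
  }
  rownames(out) <- ids
  out
}
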