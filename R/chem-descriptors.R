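#' Cheap graph descriptors of a standardized molecule
#'
#' Counting descriptors computable in closed form from the heavy-atom graph.
#' These drive the latent ground-truth endpoints of the synthetic-data
#' generator and serve as the reference feature set for the oracle linear
#' model that upper-bounds achievable performance on synthetic studies.
#'
#' @param mol a [Molecule-class].
#' @return named numeric vector: `nAtoms`, `nC` (carbons), `nPolar` (N + O),
#'   `nRings` (cycle rank of the bond graph), `hbd` (N/O bearing at least
#'   one hydrogen), `hba` (N + O), `rotB` (acyclic single bonds between
#'   non-terminal atoms), `nAromatic`, `mw`.
#' @examples
#' molDescriptors(standardizeMolecule("CC(=O)Nc1ccc(O)cc1"))
#' @export
molDescriptors <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  el <- mol@element
  deg <- atomDegrees(mol)
  b <- mol@bonds
  n <- nAtoms(mol)
  ncomp <- if (n == 1) 1L else max(.fragmentMembership(n, b))
  n_rings <- nrow(b) - n + ncomp
  rotb <- 0L
  if (nrow(b) > 0) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, t(b[, 1:2, drop = FALSE]))
    bridge_ids <- igraph::bridges(g)
    is_bridge <- seq_len(nrow(b)) %in% bridge_ids
    rotb <- sum(is_bridge & b[, 3] == 1L & deg[b[, 1]] > 1L &
                  deg[b[, 2]] > 1L)
  }
  polar <- el %in% c("N", "O")
  c(nAtoms = n,
    nC = sum(el == "C"),
    nPolar = sum(polar),
    nRings = n_rings,
    hbd = sum(polar & mol@nH >= 1L),
    hba = sum(polar),
    rotB = rotb,
    nAromatic = sum(mol@aromatic),
    mw = mol@mw)
}

#' Descriptor table for a list of molecules
#'
#' @param mols list of [Molecule-class] objects.
#' @return data.frame, one row per molecule, with an `id` column.
#' @export
molDescriptorTable <- function(mols) {
  d <- t(vapply(mols, molDescriptors, numeric(9)))
  data.frame(id = vapply(mols, function(m) m@id, ""), d,
             row.names = NULL, stringsAsFactors = FALSE)
}
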