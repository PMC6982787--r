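# 75-dimensional atomic input features for the graph convolutional network,
# following the featurization convention of the Duvenaud-style reference
# implementation: concatenated one-hot/binary blocks.

.FEATURE_ELEMENTS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb"
)  # 43 symbols; slot 44 is "other"

.HYBRIDIZATIONS <- c("SP", "SP2", "SP3", "SP3D", "SP3D2")

.oneHot <- function(value, levels) {
  m <- matrix(0, length(value), length(levels))
  idx <- match(value, levels)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Atomic feature matrix
#'
#' Builds the 75-wide initial node features: element one-hot over a fixed
#' 43-symbol list plus an "other" slot (44), heavy-atom degree one-hot 0-10
#' (11), implicit-hydrogen (implicit valence) one-hot 0-6 (7), formal charge
#' scalar (1), radical-electron count scalar (1), hybridization one-hot over
#' SP/SP2/SP3/SP3D/SP3D2 (5), aromaticity flag (1), and total hydrogen count
#' one-hot 0-4 (5).
#'
#' @param mol a [Molecule-class].
#' @return numeric matrix `nAtoms x 75`.
#' @examples
#' dim(atomFeatures(standardizeMolecule("c1ccccc1")))
#' @export
atomFeatures <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  n <- nAtoms(mol)
  deg <- atomDegrees(mol)
  elem <- .oneHot(mol@element, .FEATURE_ELEMENTS)
  other <- as.numeric(rowSums(elem) == 0)
  feats <- cbind(
    elem, other,                                   # 44
    .oneHot(deg, 0:10),                            # 11
    .oneHot(mol@nH, 0:6),                          # 7
    mol@charge,                                    # 1 (scalar)
    rep(0, n),                                     # 1 radical electrons
    .oneHot(mol@hybridization, .HYBRIDIZATIONS),   # 5
    as.numeric(mol@aromatic),                      # 1
    .oneHot(pmin(mol@nH, 99L), 0:4)                # 5 total H (all implicit)
  )
  dimnames(feats) <- NULL
  stopifnot(ncol(feats) == 75L)
  feats
}

#' Convert a molecule to its featurized graph
#'
#' One node per heavy atom, one undirected edge per bond; bond types are not
#' distinguished (single, double and aromatic bonds all contribute the same
#' unit entry to the adjacency matrix).
#'
#' @param mol a [Molecule-class].
#' @return a [MolecularGraph-class].
#' @examples
#' g <- molToGraph(standardizeMolecule("CCO"))
#' g@degrees
#' @export
molToGraph <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  n <- nAtoms(mol)
  b <- mol@bonds
  A <- Matrix::sparseMatrix(
    i = c(b[, 1], b[, 2]), j = c(b[, 2], b[, 1]), x = 1,
    dims = c(n, n))
  new("MolecularGraph", nodeFeatures = atomFeatures(mol), adjacency = A,
      degrees = as.integer(Matrix::rowSums(A)))
}

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph:", nrow(object@nodeFeatures), "atoms,",
      sum(object@degrees) / 2, "edges, feature width",
      ncol(object@nodeFeatures), "\n")
})
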