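#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

setOldClass(c("graphConvConfig", "list"))
setOldClass(c("denseNetConfig", "list"))
setOldClass(c("syntheticConfig", "list"))
setOldClass(c("experimentConfig", "list"))

#' Standardized small molecule
#'
#' Heavy-atom representation of a standardized structure: elements, kekulized
#' bonds, formal charges, aromaticity and hybridization flags (perceived by
#' OpenBabel), implicit hydrogen counts and the molecular weight. Produced by
#' [standardizeMolecules()]; hydrogens are implicit throughout.
#'
#' @slot id compound identifier carried through from the input.
#' @slot smiles canonical SMILES of the standardized structure.
#' @slot element character vector of element symbols, one per heavy atom.
#' @slot charge integer vector of formal charges remaining after
#'   neutralization.
#' @slot aromatic logical vector, atom-level aromaticity.
#' @slot hybridization character vector in `SP`, `SP2`, `SP3`, `SP3D`,
#'   `SP3D2`.
#' @slot bonds integer matrix with columns `i`, `j`, `order` (kekulized
#'   orders; aromatic rings appear as alternating 1/2).
#' @slot nH integer vector of implicit hydrogen counts.
#' @slot mw molecular weight in g/mol, implicit hydrogens included.
#' @exportClass Molecule
setClass("Molecule",
  representation(
    id = "character", smiles = "character", element = "character",
    charge = "integer", aromatic = "logical", hybridization = "character",
    bonds = "matrix", nH = "integer", mw = "numeric"
  )
)

setValidity("Molecule", function(object) {
  n <- length(object@element)
  if (n < 1L) return("molecule has no heavy atoms")
  if (length(object@charge) != n || length(object@aromatic) != n ||
      length(object@hybridization) != n || length(object@nH) != n)
    return("per-atom slots disagree in length")
  b <- object@bonds
  if (nrow(b) > 0 && (any(b[, 1:2] < 1) || any(b[, 1:2] > n)))
    return("bond indices out of range")
  TRUE
})

#' Molecular graph with atomic input features
#'
#' The graph fed to the convolutional network: one node per heavy atom with a
#' 75-dimensional binary feature vector, and a symmetric, zero-diagonal
#' adjacency matrix. Bond types are deliberately not distinguished.
#'
#' @slot nodeFeatures numeric matrix, `n_atoms x 75`, entries in `{0, 1}`
#'   except the two scalar columns (formal charge, radical electrons).
#' @slot adjacency symmetric sparse adjacency matrix with zero diagonal.
#' @slot degrees integer vector of heavy-atom degrees (adjacency row sums).
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(nodeFeatures = "matrix", adjacency = "Matrix",
                 degrees = "integer")
)

setValidity("MolecularGraph", function(object) {
  n <- nrow(object@nodeFeatures)
  if (ncol(object@nodeFeatures) != 75L)
    return("node feature width must be 75")
  A <- object@adjacency
  if (nrow(A) != n || ncol(A) != n) return("adjacency dimension mismatch")
  if (any(Matrix::diag(A) != 0)) return("adjacency diagonal must be zero")
  if (!Matrix::isSymmetric(A)) return("adjacency must be symmetric")
  if (!identical(as.integer(Matrix::rowSums(A)), object@degrees))
    return("degrees inconsistent with adjacency")
  TRUE
})

#' Endpoint (task) specification set
#'
#' The per-endpoint configuration of a modeling study: short assay code,
#' the value transformation applied during preprocessing, and whether the
#' endpoint is a helper task (trained jointly to support related endpoints
#' but excluded from headline performance averages).
#'
#' @slot code short unique endpoint codes (e.g. `"LOD"`, `"LOP"`).
#' @slot transform one of `"none"`, `"log10"`, `"log10_molar"` per endpoint.
#'   `log10_molar` converts mg/L to mol/L using the molecular weight before
#'   taking log10; `log10` takes log10 of the reported value; `none` passes
#'   values through (e.g. melting point in degrees Celsius).
#' @slot helper logical, helper-task flag per endpoint.
#' @slot displayName human-readable assay names.
#' @exportClass EndpointSet
setClass("EndpointSet",
  representation(code = "character", transform = "character",
                 helper = "logical", displayName = "character")
)

setValidity("EndpointSet", function(object) {
  if (anyDuplicated(object@code)) return("endpoint codes must be unique")
  if (!all(object@transform %in% c("none", "log10", "log10_molar")))
    return("transform must be none, log10 or log10_molar")
  n <- length(object@code)
  if (length(object@transform) != n || length(object@helper) != n ||
      length(object@displayName) != n)
    return("slots disagree in length")
  TRUE
})

#' Compounds x tasks assay matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the sparse
#' multi-endpoint training matrix: rows are unique standardized compounds,
#' columns are endpoints. Assays:
#' \describe{
#'   \item{`values`}{measurements on the transformed model scale (`NA` where
#'     unlabeled).}
#'   \item{`mask`}{logical; `TRUE` where a label exists.}
#'   \item{`dates`}{numeric days (as in `as.numeric(Date)`); optional,
#'     latest replicate date per cell.}
#' }
#' Column metadata mirrors the [EndpointSet]; row metadata carries compound
#' id, canonical SMILES and molecular weight. After [standardizeTasks()] the
#' per-task scaling parameters live in `metadata(x)$scalers` and the
#' standardized values in assay `z`.
#'
#' @exportClass AssayMatrix
setClass("AssayMatrix", contains = "SummarizedExperiment")

setValidity("AssayMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("values", "mask") %in% an))
    return("assays 'values' and 'mask' are required")
  m <- SummarizedExperiment::assay(object, "mask")
  v <- SummarizedExperiment::assay(object, "values")
  if (!is.logical(m)) return("mask must be logical")
  if (any(is.na(v[m]))) return("values must be defined wherever mask is TRUE")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("code", "transform", "helper") %in% colnames(cd)))
    return("colData must carry code, transform and helper")
  TRUE
})

#' Fold assignment for model validation
#'
#' Produced by [clusterSplit()], [randomSplitMatched()] or [timeSplit()].
#' For cluster and matched-random strategies, `fold` assigns each compound to
#' a cross-validation fold (`-1` marks the held-out test fold). For time
#' splits the assignment is per compound-x-task cell (`cellTest`): in the
#' taskwise variant a compound may be training in one task and test in
#' another; the strict variant removes such compounds from all training sets.
#'
#' @slot strategy one of `"cluster"`, `"random"`, `"time_taskwise"`,
#'   `"time_strict"`.
#' @slot fold named integer vector (compound keys), `-1` = test set; `NA`
#'   for pure time splits.
#' @slot cellTest logical matrix (compounds x tasks) for time strategies;
#'   `NA` where the cell is unlabeled. 0-row matrix otherwise.
#' @slot K number of clusters/folds requested.
#' @slot cutoff cutoff `Date` for time splits (`NA` otherwise).
#' @slot seed integer seed that produced the plan (`NA` if none).
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(strategy = "character", fold = "integer",
                 cellTest = "matrix", K = "integer", cutoff = "Date",
                 seed = "integer")
)

setValidity("SplitPlan", function(object) {
  if (!object@strategy %in%
      c("cluster", "random", "time_taskwise", "time_strict"))
    return("unknown strategy")
  if (object@strategy %in% c("cluster", "random")) {
    if (is.null(names(object@fold)) || anyDuplicated(names(object@fold)))
      return("fold must be named by unique compound keys")
    if (any(is.na(object@fold))) return("fold assignments must be complete")
  }
  TRUE
})

#' Virtual parent of the regression models
#'
#' Common parent of [GraphConvModel-class] and [DenseNetModel-class]; both
#' respond to [predictTasks()] and [fitModel()].
#' @exportClass ADMETModel
setClass("ADMETModel", representation("VIRTUAL",
  config = "list", params = "list", taskCodes = "character",
  scalers = "list", history = "data.frame"))

#' Graph convolutional regression network
#'
#' Duvenaud-style graph convolutional network: two graph convolution steps
#' (128 units each, rectifier activations), a per-atom dense layer (256
#' units), a mean/max readout with tanh producing a 512-dimensional molecule
#' embedding, and one linear output unit per task. Construct with
#' [graphConvModel()] and train with [fitModel()].
#'
#' @exportClass GraphConvModel
setClass("GraphConvModel", contains = "ADMETModel")

#' Fully connected fingerprint network
#'
#' Pyramidal fully connected network over folded circular count
#' fingerprints: four rectifier hidden layers (2000/1000/500/100 by default)
#' with decreasing dropout, He-initialized weights, output bias initialized
#' at -1, and the count-mimicking input-noise scheme followed by tanh.
#' Construct with [denseNetModel()] and train with [fitModel()].
#'
#' @exportClass DenseNetModel
setClass("DenseNetModel", contains = "ADMETModel")
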