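#' Predict task values for new structures
#'
#' @param object a fitted [ADMETModel-class].
#' @param newdata input structures: a list of [Molecule-class] objects (or,
#'   for the dense model, a fingerprint count matrix).
#' @param ... further arguments: `scale = c("model", "standardized",
#'   "assay")` selects the output scale; `mw` supplies molecular weights
#'   when `scale = "assay"` and a `log10_molar` endpoint is present.
#' @return numeric matrix, compounds x tasks.
#' @export
setGeneric("predictTasks", function(object, newdata, ...)
  standardGeneric("predictTasks"))

#' Train a model on an assay matrix
#'
#' @param object an untrained [ADMETModel-class].
#' @param am an [AssayMatrix-class] (standardized targets are fitted
#'   internally on the training portion).
#' @param ... training arguments: `train` (compound keys or logical), `mols`
#'   / `fps` featurized inputs, `seed`, `verbose`.
#' @return the fitted model with training history attached.
#' @export
setGeneric("fitModel", function(object, am, ...) standardGeneric("fitModel"))

#' @rdname taskCodes
#' @export
setGeneric("taskCodes", function(x) standardGeneric("taskCodes"))

#' @rdname taskSizes
#' @export
setGeneric("taskSizes", function(x) standardGeneric("taskSizes"))

#' @rdname isHelper
#' @export
setGeneric("isHelper", function(x) standardGeneric("isHelper"))

#' @rdname assayValues
#' @export
setGeneric("assayValues", function(x) standardGeneric("assayValues"))

#' @rdname assayValues
#' @export
setGeneric("assayMask", function(x) standardGeneric("assayMask"))

#' @rdname assayValues
#' @export
setGeneric("assayDates", function(x) standardGeneric("assayDates"))

#' @rdname compoundKeys
#' @export
setGeneric("compoundKeys", function(x) standardGeneric("compoundKeys"))

#' @rdname scalers
#' @export
setGeneric("scalers", function(x) standardGeneric("scalers"))
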