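#' Accessors for AssayMatrix
#'
#' @param x an [AssayMatrix-class].
#' @return `assayValues`: numeric matrix of model-scale values;
#'   `assayMask`: logical labeled-cell matrix; `assayDates`: numeric date
#'   matrix (days, as `as.numeric(Date)`).
#' @name assayValues
NULL

#' @rdname assayValues
setMethod("assayValues", "AssayMatrix", function(x)
  SummarizedExperiment::assay(x, "values"))

#' @rdname assayValues
setMethod("assayMask", "AssayMatrix", function(x)
  SummarizedExperiment::assay(x, "mask"))

#' @rdname assayValues
setMethod("assayDates", "AssayMatrix", function(x) {
  if ("dates" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "dates") else NULL
})

#' Task codes of an object
#'
#' @param x an [AssayMatrix-class], [EndpointSet-class] or model.
#' @return character vector of endpoint codes.
#' @name taskCodes
NULL

#' @rdname taskCodes
setMethod("taskCodes", "AssayMatrix", function(x) colnames(x))

#' Labeled-compound count per task
#'
#' @param x an [AssayMatrix-class].
#' @return named integer vector of mask column sums.
#' @name taskSizes
NULL

#' @rdname taskSizes
setMethod("taskSizes", "AssayMatrix", function(x) colSums(assayMask(x)))

#' Helper-task flags
#'
#' @param x an [AssayMatrix-class] or [EndpointSet-class].
#' @return named logical vector.
#' @name isHelper
NULL

#' @rdname isHelper
setMethod("isHelper", "AssayMatrix", function(x)
  stats::setNames(SummarizedExperiment::colData(x)$helper, colnames(x)))

#' Compound keys (row identifiers)
#'
#' One key per unique standardized structure.
#'
#' @param x an [AssayMatrix-class].
#' @return character vector.
#' @name compoundKeys
NULL

#' @rdname compoundKeys
setMethod("compoundKeys", "AssayMatrix", function(x) rownames(x))

#' Fitted per-task scalers
#'
#' @param x an [AssayMatrix-class] after [standardizeTasks()], or a fitted
#'   model.
#' @return data.frame with columns `code`, `mean`, `sd` (or `NULL`).
#' @name scalers
NULL

#' @rdname scalers
setMethod("scalers", "AssayMatrix", function(x)
  S4Vectors::metadata(x)$scalers)

setMethod("show", "AssayMatrix", function(object) {
  cat("AssayMatrix:", nrow(object), "compounds x", ncol(object), "tasks\n")
  ts <- taskSizes(object)
  cat("  labeled cells:", sum(ts), "(",
      round(100 * sum(ts) / prod(dim(object)), 1), "% dense )\n")
  cat("  task sizes:", paste(names(ts), ts, sep = "=", collapse = " "), "\n")
  if (!is.null(scalers(object))) cat("  per-task scalers fitted\n")
  dr <- S4Vectors::metadata(object)$dropped
  if (!is.null(dr) && sum(dr) > 0)
    cat("  dropped records:", paste(names(dr), dr, sep = "=",
                                    collapse = " "), "\n")
})
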