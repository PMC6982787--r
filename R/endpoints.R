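#' Construct an endpoint specification set
#'
#' @param code character vector of unique endpoint codes.
#' @param transform per-endpoint transform: `"none"`, `"log10"` or
#'   `"log10_molar"` (mg/L converted to mol/L before log10).
#' @param helper logical; helper tasks contribute to joint training but are
#'   excluded from headline metric averages.
#' @param displayName human-readable names (defaults to `code`).
#' @return an [EndpointSet-class].
#' @examples
#' endpointSet(c("LOD", "LOP"), c("none", "log10_molar"))
#' @export
endpointSet <- function(code, transform = "none", helper = FALSE,
                        displayName = code) {
  n <- length(code)
  new("EndpointSet", code = as.character(code),
      transform = rep_len(as.character(transform), n),
      helper = rep_len(as.logical(helper), n),
      displayName = rep_len(as.character(displayName), n))
}

#' Default ten-endpoint study design
#'
#' The physico-chemical endpoint panel modeled by this package: logD at
#' neutral and acidic pH (reported on log scale, no transform), membrane
#' affinity and human serum albumin binding (log10 of the reported value),
#' melting point (degrees Celsius, untransformed), and five aqueous
#' solubility assays reported in mg/L and transformed to log10 mol/L. The
#' nephelometric, DMSO-not-fully-dissolved and unannotated solubility
#' assays are helper tasks.
#'
#' @return an [EndpointSet-class] with ten endpoints.
#' @export
defaultEndpoints <- function() {
  endpointSet(
    code = c("LOD", "LOA", "LOM", "LOH", "LMP",
             "LOO", "LOP", "LON", "LOX", "LOQ"),
    transform = c("none", "none", "log10", "log10", "none",
                  rep("log10_molar", 5)),
    helper = c(rep(FALSE, 7), TRUE, TRUE, TRUE),
    displayName = c("LogD (pH7.5)", "LogD (pH2.3)", "Membrane affinity",
                    "Human serum albumin binding", "Melting point",
                    "Solubility (DMSO)", "Solubility (powder)",
                    "Solubility (nephelometry)",
                    "Solubility (DMSO not fully dissolved)",
                    "Solubility (no assay annotation)"))
}

#' @describeIn EndpointSet-class endpoint codes.
#' @param x an `EndpointSet`.
setMethod("taskCodes", "EndpointSet", function(x) x@code)

#' @describeIn EndpointSet-class helper-task flags, named by code.
setMethod("isHelper", "EndpointSet", function(x)
  stats::setNames(x@helper, x@code))

#' @describeIn EndpointSet-class number of endpoints.
setMethod("length", "EndpointSet", function(x) length(x@code))

#' @describeIn EndpointSet-class subset by index or code.
#' @param i index or code.
#' @param j,drop,... ignored.
setMethod("[", "EndpointSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@code)
  endpointSet(x@code[i], x@transform[i], x@helper[i], x@displayName[i])
})

setMethod("show", "EndpointSet", function(object) {
  cat("EndpointSet with", length(object), "endpoints\n")
  print(as.data.frame(object))
})

#' @describeIn EndpointSet-class coerce to data.frame.
#' @export
setMethod("as.data.frame", "EndpointSet", function(x, ...) {
  data.frame(code = x@code, transform = x@transform, helper = x@helper,
             displayName = x@displayName, stringsAsFactors = FALSE)
})

#' Read or write an endpoint configuration in YAML
#'
#' The YAML mirrors the study-design table: a sequence of mappings with
#' `code`, `transform`, `helper` and optional `name` keys.
#'
#' @param file path to a YAML file.
#' @return [readEndpointConfig()] returns an [EndpointSet-class].
#' @export
readEndpointConfig <- function(file) {
  y <- yaml::read_yaml(file)
  eps <- if (!is.null(y$endpoints)) y$endpoints else y
  endpointSet(
    code = vapply(eps, function(e) e$code, ""),
    transform = vapply(eps, function(e)
      if (is.null(e$transform)) "none" else e$transform, ""),
    helper = vapply(eps, function(e) isTRUE(e$helper), TRUE),
    displayName = vapply(eps, function(e)
      if (is.null(e$name)) e$code else e$name, ""))
}

#' @rdname readEndpointConfig
#' @param endpoints an [EndpointSet-class] to serialize.
#' @export
writeEndpointConfig <- function(endpoints, file) {
  df <- as.data.frame(endpoints)
  y <- list(endpoints = lapply(seq_len(nrow(df)), function(i)
    list(code = df$code[i], transform = df$transform[i],
         helper = df$helper[i], name = df$displayName[i])))
  yaml::write_yaml(y, file)
  invisible(file)
}
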