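# Assay preprocessing: qualifier adjustment, replicate aggregation, unit/log
# transforms, and assembly of the sparse compounds x tasks training matrix.

#' Adjust a measurement for its inequality qualifier
#'
#' Censored measurements carry a `<` or `>` qualifier. The value is replaced
#' by half the reported value for `<` and double the reported value for `>`;
#' exact measurements pass through. The adjustment is a per-measurement
#' property and is always applied before replicate averaging.
#'
#' @param value numeric vector of reported assay values.
#' @param qualifier character vector: `"eq"`/`"="`/`""`, `"lt"`/`"<"`, or
#'   `"gt"`/`">"` (recycled).
#' @return adjusted numeric vector.
#' @examples
#' applyQualifier(10, "<")  # 5
#' applyQualifier(10, ">")  # 20
#' @export
applyQualifier <- function(value, qualifier = "eq") {
  if (any(!is.finite(value))) stop("assay values must be finite")
  q <- .normalizeQualifier(rep_len(qualifier, length(value)))
  value * unname(c(eq = 1, lt = 0.5, gt = 2)[q])
}

.normalizeQualifier <- function(q) {
  q <- as.character(q)
  q[is.na(q) | q %in% c("", "=", "==", "eq")] <- "eq"
  q[q %in% c("<", "lt", "<=")] <- "lt"
  q[q %in% c(">", "gt", ">=")] <- "gt"
  bad <- !q %in% c("eq", "lt", "gt")
  if (any(bad)) stop("unknown qualifier: ", paste(unique(q[bad]), collapse = ", "))
  q
}

#' Aggregate replicate measurements of one compound and endpoint
#'
#' The final experimental value is the arithmetic mean of the
#' qualifier-adjusted replicate measurements, taken on the raw assay scale
#' (before any log transform).
#'
#' @param values numeric vector of replicate values (same compound and
#'   endpoint).
#' @param qualifiers qualifiers per replicate (see [applyQualifier()]).
#' @return a single numeric value.
#' @examples
#' aggregateReplicates(c(10, 6), c("<", "eq"))  # (5 + 6) / 2
#' @export
aggregateReplicates <- function(values, qualifiers = "eq") {
  if (length(values) == 0) stop("no measurements to aggregate")
  mean(applyQualifier(values, qualifiers))
}

#' Transform an aggregated value to the model scale
#'
#' `none` passes the value through (melting point, logD); `log10` takes the
#' base-10 logarithm of the reported value (membrane affinity, serum albumin
#' binding); `log10_molar` converts a solubility in mg/L to mol/L using the
#' molecular weight, then takes log10.
#'
#' @param value aggregated assay value (raw scale).
#' @param transform `"none"`, `"log10"` or `"log10_molar"`.
#' @param molWeight molecular weight in g/mol (required for `log10_molar`).
#' @return value on the model (transformed) scale.
#' @examples
#' toModelScale(180, "log10_molar", molWeight = 180)  # -3
#' @export
toModelScale <- function(value, transform, molWeight = NA_real_) {
  transform <- match.arg(transform, c("none", "log10", "log10_molar"))
  switch(transform,
    none = value,
    log10 = {
      if (any(value <= 0)) stop("log10 transform requires positive values")
      log10(value)
    },
    log10_molar = {
      if (any(value <= 0)) stop("log10 transform requires positive values")
      if (any(!is.finite(molWeight)) || any(molWeight <= 0))
        stop("log10_molar requires a positive molecular weight")
      log10(value / 1000 / molWeight)
    })
}

#' Invert standardization and the endpoint transform
#'
#' Exact inverse of the model-scale pipeline: undo per-task standardization
#' (if a `(mean, sd)` scaler is given), then undo the endpoint transform, so
#' predictions can be reported in assay units.
#'
#' @param value value on the model scale (standardized if `scaler` given).
#' @param transform as in [toModelScale()].
#' @param scaler optional numeric `c(mean, sd)` fitted by
#'   [standardizeTasks()].
#' @param molWeight molecular weight (g/mol) for `log10_molar`.
#' @return value in assay units.
#' @examples
#' invertModelScale(-3, "log10_molar", molWeight = 180)  # 180 mg/L
#' @export
invertModelScale <- function(value, transform, scaler = NULL,
                             molWeight = NA_real_) {
  transform <- match.arg(transform, c("none", "log10", "log10_molar"))
  if (!is.null(scaler)) value <- value * scaler[2] + scaler[1]
  switch(transform,
    none = value,
    log10 = 10^value,
    log10_molar = 10^value * 1000 * molWeight)
}

#' Read a delimited assay table
#'
#' Expects columns `compound_id`, `smiles`, `endpoint`, `value`, and
#' optionally `qualifier` and `date`. The separator is sniffed from the
#' header (tab or comma).
#'
#' @param file path to a CSV/TSV file.
#' @return a records data.frame with normalized qualifiers and `Date` dates.
#' @export
readAssayTable <- function(file) {
  first <- readLines(file, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  .normalizeRecords(df)
}

.normalizeRecords <- function(df) {
  need <- c("compound_id", "smiles", "endpoint", "value")
  if (!all(need %in% colnames(df)))
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  df$value <- as.numeric(df$value)
  df$qualifier <- if ("qualifier" %in% colnames(df))
    .normalizeQualifier(df$qualifier) else "eq"
  df$date <- if ("date" %in% colnames(df)) as.Date(df$date) else
    as.Date(NA)
  df[c("compound_id", "smiles", "endpoint", "value", "qualifier", "date")]
}

#' @rdname readAssayTable
#' @param records a records data.frame.
#' @param sep field separator (default tab).
#' @export
writeAssayTable <- function(records, file, sep = "\t") {
  utils::write.table(records, file, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read assay records from an SDF file
#'
#' Maps SDF data fields to the assay-record columns; the structure itself
#' supplies the SMILES via canonicalization.
#'
#' @param file path to an SDF file.
#' @param fields named character vector mapping record columns
#'   (`compound_id`, `endpoint`, `value`, `qualifier`, `date`) to SDF data
#'   field names.
#' @return a records data.frame as from [readAssayTable()].
#' @export
readAssaySDF <- function(file,
                         fields = c(compound_id = "compound_id",
                                    endpoint = "endpoint", value = "value",
                                    qualifier = "qualifier", date = "date")) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(file, skipErrors = TRUE))
  smi <- as.character(ChemmineR::sdf2smiles(sdfset))
  rows <- lapply(seq_along(sdfset), function(i) {
    db <- ChemmineR::datablock(sdfset[[i]])
    get <- function(key) if (key %in% names(db)) db[[key]] else NA
    data.frame(
      compound_id = as.character(get(fields["compound_id"])),
      smiles = smi[i],
      endpoint = as.character(get(fields["endpoint"])),
      value = as.numeric(get(fields["value"])),
      qualifier = as.character(get(fields["qualifier"])),
      date = as.character(get(fields["date"])),
      stringsAsFactors = FALSE)
  })
  .normalizeRecords(do.call(rbind, rows))
}

#' Build the compounds x tasks assay matrix
#'
#' Full preprocessing pipeline: standardize every structure with
#' [standardizeMolecules()], deduplicate compounds at the level of the
#' canonical standardized structure, adjust each raw measurement for its
#' qualifier, average replicates on the raw scale, apply the endpoint
#' transform, and assemble the sparse label matrix with its mask and
#' per-cell dates (latest replicate date). Records whose qualifier-adjusted
#' value is non-positive under a log transform are dropped and counted, as
#' are records with unparseable structures; counts are kept in
#' `metadata(x)$dropped`.
#'
#' @param records a records data.frame (see [readAssayTable()]).
#' @param endpoints an [EndpointSet-class]; every record's endpoint must be
#'   listed.
#' @param mols optional pre-standardized named list of [Molecule-class]
#'   (names = compound ids) to skip re-standardization.
#' @return an [AssayMatrix-class]. Values are on the transformed model
#'   scale; call [standardizeTasks()] to fit per-task scalers.
#' @export
buildAssayMatrix <- function(records, endpoints, mols = NULL) {
  records <- .normalizeRecords(records)
  unknown <- setdiff(unique(records$endpoint), taskCodes(endpoints))
  if (length(unknown))
    stop("endpoints not in specification: ", paste(unknown, collapse = ", "))

  dropped <- c(structure = 0L, nonpositive = 0L)
  if (is.null(mols)) {
    first <- !duplicated(records$compound_id)
    std <- standardizeMolecules(records$smiles[first],
                                ids = records$compound_id[first])
    mols <- std$molecules
    dropped["structure"] <- nrow(std$failures)
  }
  keep <- records$compound_id %in% names(mols)
  records <- records[keep, , drop = FALSE]
  if (!nrow(records)) stop("no records with parseable structures")

  # structure-level deduplication: canonical SMILES defines compound identity
  can <- vapply(mols, function(m) m@smiles, "")
  first_of_struct <- !duplicated(can)
  struct_rep <- stats::setNames(names(mols)[first_of_struct][
    match(can, can[first_of_struct])], names(mols))
  records$key <- struct_rep[records$compound_id]

  row_keys <- unique(records$key)
  codes <- taskCodes(endpoints)
  epdf <- as.data.frame(endpoints)
  nR <- length(row_keys); nT <- length(codes)
  values <- matrix(NA_real_, nR, nT, dimnames = list(row_keys, codes))
  mask <- matrix(FALSE, nR, nT, dimnames = list(row_keys, codes))
  dates <- matrix(NA_real_, nR, nT, dimnames = list(row_keys, codes))
  mw <- vapply(mols[row_keys], molWeight, numeric(1))

  adj <- applyQualifier(records$value, records$qualifier)
  tr_of <- stats::setNames(epdf$transform, epdf$code)
  is_log <- tr_of[records$endpoint] != "none"
  bad <- is_log & adj <= 0
  dropped["nonpositive"] <- sum(bad)
  records <- records[!bad, , drop = FALSE]
  adj <- adj[!bad]

  grp <- interaction(match(records$key, row_keys),
                     match(records$endpoint, codes), drop = TRUE)
  means <- tapply(adj, grp, mean)
  late <- tapply(as.numeric(records$date), grp, function(d)
    if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE))
  ij <- do.call(rbind, strsplit(names(means), ".", fixed = TRUE))
  ii <- as.integer(ij[, 1]); jj <- as.integer(ij[, 2])
  raw <- as.numeric(means)
  modval <- numeric(length(raw))
  for (k in seq_along(raw))
    modval[k] <- toModelScale(raw[k], tr_of[codes[jj[k]]], mw[ii[k]])
  values[cbind(ii, jj)] <- modval
  mask[cbind(ii, jj)] <- TRUE
  dates[cbind(ii, jj)] <- as.numeric(late)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values, mask = mask, dates = dates),
    rowData = S4Vectors::DataFrame(id = row_keys,
                                   smiles = unname(can[row_keys]),
                                   mw = unname(mw), row.names = row_keys),
    colData = S4Vectors::DataFrame(epdf, row.names = epdf$code))
  am <- methods::new("AssayMatrix", se)
  S4Vectors::metadata(am)$dropped <- dropped
  S4Vectors::metadata(am)$scalers <- NULL
  am
}

#' Fit per-task standardization scalers
#'
#' Scales each endpoint to zero mean and unit standard deviation over the
#' labeled cells of the training portion (all compounds if `train` is
#' `NULL`), stores the `(mean, sd)` pairs in `metadata(x)$scalers`, and adds
#' a `z` assay with the standardized values. Fitting on the training fold
#' only and reusing the scalers for validation/test avoids information
#' leakage.
#'
#' @param x an [AssayMatrix-class].
#' @param train optional compound keys or logical vector selecting the
#'   training rows used to fit the scalers.
#' @return the [AssayMatrix-class] with scalers and a `z` assay.
#' @export
standardizeTasks <- function(x, train = NULL) {
  stopifnot(is(x, "AssayMatrix"))
  v <- assayValues(x); m <- assayMask(x)
  sel <- if (is.null(train)) rep(TRUE, nrow(x)) else
    if (is.logical(train)) train else rownames(x) %in% train
  helper <- SummarizedExperiment::colData(x)$helper
  mu <- sdv <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) {
    vals <- v[sel & m[, j], j]
    if (!length(vals)) {
      # an empty helper task never enters a minibatch loss; identity
      # scaling keeps it harmless. Empty modeled tasks are an error.
      if (!isTRUE(helper[j]))
        stop("task ", colnames(v)[j], " has no labeled training compound")
      mu[j] <- 0; sdv[j] <- 1
      next
    }
    mu[j] <- mean(vals)
    sdv[j] <- if (length(vals) > 1) stats::sd(vals) else 1
    if (sdv[j] == 0) sdv[j] <- 1
  }
  z <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  z[!m] <- NA_real_
  SummarizedExperiment::assay(x, "z", withDimnames = FALSE) <- z
  S4Vectors::metadata(x)$scalers <- data.frame(
    code = colnames(v), mean = mu, sd = sdv, stringsAsFactors = FALSE)
  x
}
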