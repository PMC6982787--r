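# The general solubility equation (Yalkowsky) and the model-consistency
# audit built on it.

#' General solubility equation
#'
#' `logSw = -0.01 * (LMP - 25) - logKow + 0.5`, where `logSw` is the base-10
#' logarithm of aqueous solubility in mol/L, `LMP` the melting point in
#' degrees Celsius and `Kow` the octanol-water partition coefficient.
#' Compounds melting at the 25 degree reference temperature with logKow = 0
#' have a predicted solubility of 10^0.5 mol/L.
#'
#' @param LMP melting point in degrees Celsius.
#' @param logKow base-10 log of the partition coefficient.
#' @return predicted log10 aqueous solubility (mol/L).
#' @examples
#' gseLogS(25, 0)   # 0.5
#' gseLogS(125, 0)  # -0.5
#' @export
gseLogS <- function(LMP, logKow) {
  stopifnot(is.numeric(LMP), is.numeric(logKow))
  -0.01 * (LMP - 25) - logKow + 0.5
}

#' GSE consistency audit of model predictions
#'
#' Checks whether a model's predictions jointly respect the general
#' solubility equation without having been trained under that constraint.
#' Given per-compound predictions for melting point, logD (standing in for
#' logKow, as is usual at physiological pH) and aqueous solubility (log10
#' mol/L), computes:
#' \describe{
#'   \item{`predicted`}{Pearson correlation between the GSE solubility
#'     derived from predicted LMP and logD, and the predicted solubility.}
#'   \item{`measured`}{the same correlation on measured values, when
#'     supplied.}
#'   \item{`logd_only`}{correlation between `-`predicted logD and predicted
#'     solubility -- the ablation that shows how much of the consistency is
#'     mere logD/solubility anticorrelation.}
#' }
#'
#' @param predLMP,predLogD,predLogS numeric vectors of predictions for a
#'   common compound set (>= 3 compounds).
#' @param measLMP,measLogD,measLogS optional measured values on the same
#'   compounds.
#' @return named numeric vector with elements `predicted`, `logd_only` and
#'   (when measurements are supplied) `measured`.
#' @export
gseConsistency <- function(predLMP, predLogD, predLogS,
                           measLMP = NULL, measLogD = NULL,
                           measLogS = NULL) {
  n <- length(predLogS)
  if (n < 3) stop("need at least 3 compounds for the consistency audit")
  stopifnot(length(predLMP) == n, length(predLogD) == n)
  out <- c(predicted = pearsonR(gseLogS(predLMP, predLogD), predLogS),
           logd_only = pearsonR(-predLogD, predLogS))
  if (!is.null(measLMP) && !is.null(measLogD) && !is.null(measLogS)) {
    out <- c(out,
             measured = pearsonR(gseLogS(measLMP, measLogD), measLogS))
  }
  out
}
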