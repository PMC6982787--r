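# Masked multitask mean-squared-error loss. Missing labels are ignored;
# tasks absent from a minibatch drop out of the average entirely.

#' Masked multitask MSE
#'
#' Per-task mean squared error over labeled cells only, combined across the
#' tasks present in the batch. With `weighting = "simple"` each present task
#' receives weight `1/N` (`N` = number of tasks with at least one labeled
#' cell in the batch). With `weighting = "balanced"` task weights are
#' proportional to the inverse of the task sizes, normalized to sum to one
#' over present tasks, so smaller tasks are upweighted. By default balanced
#' weights use the global training-set task sizes (`taskSizes`); set
#' `perBatch = TRUE` to use the labeled-cell counts of the minibatch
#' instead.
#'
#' @param pred,target numeric matrices, batch x tasks (targets on the
#'   standardized scale during training).
#' @param mask logical matrix; `TRUE` where a label exists.
#' @param weighting `"simple"` or `"balanced"`.
#' @param taskSizes named or positional integer vector of global
#'   training-set sizes per task (required for balanced weighting unless
#'   `perBatch`).
#' @param perBatch logical; balanced weights from minibatch counts.
#' @return scalar loss.
#' @examples
#' p <- matrix(c(2, 0), 1); t <- matrix(c(0, 0), 1)
#' m <- matrix(TRUE, 1, 2)
#' maskedMultitaskMSE(p, t, m)  # (4 + 0) / 2
#' @export
maskedMultitaskMSE <- function(pred, target, mask,
                               weighting = c("simple", "balanced"),
                               taskSizes = NULL, perBatch = FALSE) {
  .maskedLossGrad(pred, target, mask, match.arg(weighting), taskSizes,
                  perBatch, want_grad = FALSE)$loss
}

# Loss plus gradient wrt predictions (exactly zero at unmasked cells).
.maskedLossGrad <- function(pred, target, mask, weighting = "simple",
                            taskSizes = NULL, perBatch = FALSE,
                            want_grad = TRUE) {
  stopifnot(identical(dim(pred), dim(target)),
            identical(dim(pred), dim(mask)))
  if (!any(mask)) stop("empty mask: no labeled cell in batch")
  m_t <- colSums(mask)
  present <- m_t > 0
  err <- (pred - target)
  err[!mask] <- 0
  sq <- colSums(err^2)
  L_t <- ifelse(present, sq / pmax(m_t, 1), 0)
  if (weighting == "simple") {
    w <- ifelse(present, 1 / sum(present), 0)
  } else {
    sizes <- if (perBatch) m_t else {
      if (is.null(taskSizes))
        stop("balanced weighting requires taskSizes (or perBatch = TRUE)")
      if (!is.null(names(taskSizes)) && !is.null(colnames(pred)))
        taskSizes <- taskSizes[colnames(pred)]
      as.numeric(taskSizes)
    }
    if (any(sizes[present] <= 0)) stop("task sizes must be positive")
    w <- numeric(length(m_t))
    w[present] <- (1 / sizes[present]) / sum(1 / sizes[present])
  }
  loss <- sum(w * L_t)
  grad <- NULL
  if (want_grad) {
    scale <- ifelse(present, 2 * w / pmax(m_t, 1), 0)
    grad <- sweep(err, 2, scale, "*")
  }
  list(loss = loss, grad = grad, weights = w, taskLoss = L_t)
}
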