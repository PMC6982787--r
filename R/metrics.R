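# Regression performance measures. r2 is the coefficient of determination
# (1 - SS_res/SS_tot), which is negative for models worse than the mean
# predictor -- deliberately NOT the squared correlation.

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` of predictions against observations; may be
#' negative when the model predicts worse than the observed mean.
#'
#' @param pred,obs numeric vectors of equal length (>= 2); `obs` must not be
#'   constant.
#' @return a scalar.
#' @examples
#' r2(c(0, 0, 0), obs = c(0, 1, 2))  # -1.5
#' @export
r2 <- function(pred, obs) {
  .checkPair(pred, obs)
  if (stats::sd(obs) == 0) stop("r2 undefined for constant observations")
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Spearman rank correlation
#'
#' Standard Spearman's rho with average ranks for ties.
#'
#' @inheritParams r2
#' @return a scalar in `[-1, 1]`.
#' @export
spearmanRho <- function(pred, obs) {
  .checkPair(pred, obs)
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    stop("correlation undefined for constant vectors")
  stats::cor(pred, obs, method = "spearman")
}

#' Pearson correlation
#'
#' @inheritParams r2
#' @return a scalar in `[-1, 1]`.
#' @export
pearsonR <- function(pred, obs) {
  .checkPair(pred, obs)
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    stop("correlation undefined for constant vectors")
  stats::cor(pred, obs, method = "pearson")
}

#' Root mean squared error
#'
#' @inheritParams r2
#' @return a non-negative scalar.
#' @export
rmse <- function(pred, obs) {
  .checkPair(pred, obs)
  sqrt(mean((pred - obs)^2))
}

.checkPair <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(obs) < 2) stop("need at least 2 observations")
  if (any(!is.finite(pred)) || any(!is.finite(obs)))
    stop("non-finite values in pred/obs")
}

#' Per-task metrics of a prediction matrix
#'
#' @param pred,obs numeric matrices (compounds x tasks) on a common scale.
#' @param mask logical matrix selecting the labeled cells to evaluate.
#' @return data.frame with one row per task: `code`, `n`, `r2`,
#'   `spearman`, `pearson`, `rmse` (`NA` for tasks with fewer than 2
#'   labeled cells).
#' @export
taskMetrics <- function(pred, obs, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(obs)
  codes <- colnames(obs)
  out <- lapply(seq_len(ncol(obs)), function(j) {
    sel <- mask[, j] & !is.na(obs[, j])
    n <- sum(sel)
    if (n < 2 || stats::sd(obs[sel, j]) == 0)
      return(data.frame(code = codes[j], n = n, r2 = NA_real_,
                        spearman = NA_real_, pearson = NA_real_,
                        rmse = NA_real_))
    data.frame(code = codes[j], n = n,
               r2 = r2(pred[sel, j], obs[sel, j]),
               spearman = spearmanRho(pred[sel, j], obs[sel, j]),
               pearson = pearsonR(pred[sel, j], obs[sel, j]),
               rmse = rmse(pred[sel, j], obs[sel, j]))
  })
  do.call(rbind, out)
}

#' Fold-averaged metrics report
#'
#' Averages per-fold, per-task metrics (no pooling of predictions across
#' folds) and attaches fold standard deviations.
#'
#' @param folds list of per-fold data.frames from [taskMetrics()], with a
#'   `fold` column added by the caller or added here from list names.
#' @return list with `perFold` (stacked data.frame) and `average`
#'   (data.frame of fold means and standard deviations per task).
#' @export
metricsReport <- function(folds) {
  if (is.null(names(folds))) names(folds) <- seq_along(folds)
  per <- do.call(rbind, lapply(names(folds), function(f)
    cbind(fold = f, folds[[f]])))
  metrics <- c("r2", "spearman", "pearson", "rmse")
  avg <- do.call(rbind, lapply(split(per, per$code), function(d) {
    row <- data.frame(code = d$code[1], nFolds = sum(!is.na(d$r2)))
    for (m in metrics) {
      row[[m]] <- mean(d[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- stats::sd(d[[m]], na.rm = TRUE)
    }
    row
  }))
  rownames(avg) <- NULL
  list(perFold = per, average = avg)
}
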