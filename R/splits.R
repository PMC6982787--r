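# Validation splits: leave-cluster-out (k-means on count fingerprints with
# task-coverage merging), matched random splits of identical fold sizes,
# and taskwise / strict time splits.

#' Leave-cluster-out split
#'
#' Clusters compounds with the k-means algorithm (`K = 10` by default,
#' Euclidean distance on folded count fingerprints). Clusters that do not
#' contain labeled compounds of every task are merged into the nearest
#' larger cluster (centroid distance) until every fold covers every task.
#' One fold is then designated the external test set (`-1`); the remaining
#' folds form the cross-validation folds.
#'
#' @param fps fingerprint count matrix (rownames = compound keys of `am`).
#' @param am an [AssayMatrix-class].
#' @param K number of clusters (default 10).
#' @param seed integer seed; the split is deterministic given
#'   (fingerprints, K, seed).
#' @param testFold index of the merged fold to hold out as test set;
#'   `NULL` picks the fold whose size is closest to the average.
#' @return a [SplitPlan-class].
#' @export
clusterSplit <- function(fps, am, K = 10L, seed = 1L, testFold = NULL) {
  stopifnot(is(am, "AssayMatrix"), nrow(fps) == nrow(am))
  if (is.null(rownames(fps))) rownames(fps) <- rownames(am)
  stopifnot(all(rownames(fps) == rownames(am)))
  mask <- assayMask(am)
  if (any(colSums(mask) < 2))
    stop("infeasible coverage: task(s) with fewer than 2 compounds: ",
         paste(colnames(mask)[colSums(mask) < 2], collapse = ", "))
  if (nrow(fps) < K) stop("need at least K compounds")
  km <- .withSeed(seed, stats::kmeans(fps, centers = K, iter.max = 50,
                                      nstart = 1))
  memb <- km$cluster
  memb <- .mergeForCoverage(memb, fps, mask)
  # renumber by decreasing size for a stable fold labeling
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  memb <- relab[as.character(memb)]
  nf <- max(memb)
  if (nf < 2) stop("clustering collapsed to a single fold")
  if (is.null(testFold)) {
    fs <- tabulate(memb, nf)
    testFold <- which.min(abs(fs - mean(fs)))
  }
  fold <- ifelse(memb == testFold, -1L, memb)
  # compact CV fold numbers to 1..nf-1
  cv <- sort(unique(fold[fold != -1L]))
  fold[fold != -1L] <- match(fold[fold != -1L], cv)
  new("SplitPlan", strategy = "cluster",
      fold = stats::setNames(as.integer(fold), rownames(am)),
      cellTest = matrix(logical(0), 0, 0), K = as.integer(K),
      cutoff = as.Date(NA), seed = as.integer(seed))
}

# Merge clusters lacking full task coverage into the nearest larger
# cluster, repeating until all clusters cover all tasks.
.mergeForCoverage <- function(memb, fps, mask) {
  repeat {
    cl <- sort(unique(memb))
    if (length(cl) == 1) {
      if (all(colSums(mask) > 0)) return(memb)
      stop("a task has no labeled compound at all")
    }
    cover <- vapply(cl, function(c)
      all(colSums(mask[memb == c, , drop = FALSE]) > 0), logical(1))
    if (all(cover)) return(memb)
    sizes <- vapply(cl, function(c) sum(memb == c), integer(1))
    bad <- cl[!cover]
    victim <- bad[which.min(sizes[match(bad, cl)])]
    centroids <- do.call(rbind, lapply(cl, function(c)
      colMeans(fps[memb == c, , drop = FALSE])))
    vi <- match(victim, cl)
    dists <- sqrt(rowSums(sweep(centroids, 2, centroids[vi, ], "-")^2))
    larger <- sizes > sizes[vi]
    cand <- if (any(larger)) which(larger) else setdiff(seq_along(cl), vi)
    target <- cl[cand[which.min(dists[cand])]]
    memb[memb == victim] <- target
  }
}

#' Random split matched to a cluster plan
#'
#' Permutes compounds into folds with exactly the fold sizes of an existing
#' cluster plan, then repairs the assignment by swapping compounds between
#' folds until every fold (including the test fold) again contains labeled
#' compounds of every task.
#'
#' @param plan a cluster [SplitPlan-class].
#' @param am the [AssayMatrix-class] the plan was built on.
#' @param seed integer seed.
#' @return a [SplitPlan-class] with `strategy = "random"`.
#' @export
randomSplitMatched <- function(plan, am, seed = 1L) {
  stopifnot(is(plan, "SplitPlan"), plan@strategy == "cluster")
  fold0 <- plan@fold[rownames(am)]
  mask <- assayMask(am)
  fold <- .withSeed(seed, {
    f <- stats::setNames(sample(fold0), names(fold0))
    .repairCoverage(f, mask)
  })
  new("SplitPlan", strategy = "random", fold = fold,
      cellTest = matrix(logical(0), 0, 0), K = plan@K,
      cutoff = as.Date(NA), seed = as.integer(seed))
}

# Swap compounds between folds until every fold covers every task.
.repairCoverage <- function(fold, mask) {
  ids <- names(fold)
  for (iter in seq_len(1000)) {
    counts <- rowsum(mask + 0, fold)  # folds x tasks labeled counts
    miss <- which(counts == 0, arr.ind = TRUE)
    if (nrow(miss) == 0) return(fold)
    f <- rownames(counts)[miss[1, 1]]
    tsk <- colnames(counts)[miss[1, 2]]
    # donor compound: has the task, lives in a fold keeping >=2 of it,
    # and every task it carries stays covered after it leaves
    donors <- ids[mask[, tsk] & fold != as.integer(f)]
    ok_d <- vapply(donors, function(c) {
      fd <- as.character(fold[c])
      all(counts[fd, mask[c, ]] >= 2)
    }, logical(1))
    if (!any(ok_d)) stop("coverage repair infeasible for task ", tsk)
    donor <- donors[which(ok_d)[1]]
    # counterpart from the deficient fold whose departure keeps coverage
    here <- ids[fold == as.integer(f)]
    ok_h <- vapply(here, function(c)
      all(counts[f, mask[c, ]] >= 2) || !any(mask[c, ]), logical(1))
    if (!any(ok_h)) stop("coverage repair infeasible in fold ", f)
    cpt <- here[which(ok_h)[1]]
    fdonor <- fold[donor]
    fold[donor] <- fold[cpt]
    fold[cpt] <- fdonor
  }
  stop("coverage repair did not converge")
}

#' Taskwise or strict time split
#'
#' Fixes a cutoff date and, for each task independently, assigns labeled
#' cells with later dates to the test set and earlier cells to the
#' training set (taskwise split: a compound may be training in one task
#' and test in another). The strict variant additionally removes, from
#' every training set, any compound occurring in the test set of any task
#' (those training cells become excluded, coded `NA`). Tasks without any
#' dates are split randomly at the overall test fraction of the dated
#' tasks.
#'
#' @param am an [AssayMatrix-class] with a `dates` assay.
#' @param cutoff cutoff `Date`; cells dated strictly after it are test.
#' @param strict logical; apply the strict compound-level filter.
#' @param seed seed for the random assignment of dateless tasks.
#' @return a [SplitPlan-class] with a per-cell `cellTest` matrix
#'   (`TRUE` test, `FALSE` train, `NA` unlabeled/excluded).
#' @export
timeSplit <- function(am, cutoff, strict = FALSE, seed = 1L) {
  stopifnot(is(am, "AssayMatrix"))
  dates <- assayDates(am)
  if (is.null(dates)) stop("assay matrix has no dates")
  mask <- assayMask(am)
  cutoff <- as.Date(cutoff)
  cn <- as.numeric(cutoff)
  cell <- matrix(NA, nrow(mask), ncol(mask),
                 dimnames = dimnames(mask))
  dated_tasks <- colSums(!is.na(dates) & mask) > 0
  for (j in which(dated_tasks)) {
    sel <- mask[, j] & !is.na(dates[, j])
    cell[sel, j] <- dates[sel, j] > cn
    # labeled but undated cells in a dated task: keep in training
    cell[mask[, j] & is.na(dates[, j]), j] <- FALSE
  }
  dated_cells <- !is.na(dates) & mask
  if (!any(dated_cells)) stop("no dated cells to split on")
  frac_test <- sum(dates[dated_cells] > cn) / sum(dated_cells)
  if (frac_test == 0) stop("cutoff after all measurement dates: empty test")
  if (frac_test == 1)
    stop("cutoff before all measurement dates: empty training set")
  if (any(!dated_tasks)) {
    cell[, !dated_tasks] <- .withSeed(seed, {
      rnd <- matrix(stats::runif(nrow(mask) * sum(!dated_tasks)) < frac_test,
                    nrow(mask))
      out <- matrix(NA, nrow(mask), sum(!dated_tasks))
      out[mask[, !dated_tasks, drop = FALSE]] <-
        rnd[mask[, !dated_tasks, drop = FALSE]]
      out
    })
  }
  strategy <- "time_taskwise"
  if (strict) {
    strategy <- "time_strict"
    in_test <- rowSums(cell, na.rm = TRUE) > 0
    sub <- cell[in_test, , drop = FALSE]
    sub[!is.na(sub) & !sub] <- NA   # excluded from all training sets
    cell[in_test, ] <- sub
  }
  new("SplitPlan", strategy = strategy,
      fold = stats::setNames(rep(NA_integer_, nrow(am)), rownames(am)),
      cellTest = cell, K = NA_integer_, cutoff = cutoff,
      seed = as.integer(seed))
}

#' Training and evaluation selections of a split plan
#'
#' Resolves a [SplitPlan-class] into a logical training-cell matrix and an
#' evaluation-cell matrix for one evaluation unit: a CV `fold` number for
#' cluster/random plans (or `fold = -1` for the external test set), ignored
#' for time plans.
#'
#' @param plan a [SplitPlan-class].
#' @param am the matching [AssayMatrix-class].
#' @param fold evaluation fold for cluster/random plans.
#' @return list with logical `trainCells` and `evalCells` matrices and the
#'   logical row selector `trainRows`.
#' @export
splitSelection <- function(plan, am, fold = -1L) {
  mask <- assayMask(am)
  if (plan@strategy %in% c("cluster", "random")) {
    f <- plan@fold[rownames(am)]
    evalRows <- f == fold
    trainRows <- f != fold & f != -1L
    if (fold == -1L) trainRows <- f != -1L
    train <- mask & trainRows
    ev <- mask & evalRows
    list(trainCells = train, evalCells = ev, trainRows = trainRows)
  } else {
    ct <- plan@cellTest
    train <- !is.na(ct) & !ct & mask
    ev <- !is.na(ct) & ct & mask
    list(trainCells = train, evalCells = ev,
         trainRows = rowSums(train) > 0)
  }
}

#' Serialize or restore a split plan
#'
#' Plans are stored as plain text: comment headers carrying the strategy,
#' K, cutoff and seed, then a two-column (compound, fold) table for
#' compound-level plans or a three-column (compound, endpoint, set) table
#' for time plans.
#'
#' @param plan a [SplitPlan-class].
#' @param file path.
#' @return `readSplitPlan` returns the restored [SplitPlan-class].
#' @export
writeSplitPlan <- function(plan, file) {
  hdr <- c(paste0("# strategy: ", plan@strategy),
           paste0("# K: ", plan@K),
           paste0("# cutoff: ", format(plan@cutoff)),
           paste0("# seed: ", plan@seed))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (plan@strategy %in% c("cluster", "random")) {
    writeLines(paste(names(plan@fold), plan@fold, sep = "\t"), con)
  } else {
    ct <- plan@cellTest
    idx <- which(!is.na(ct), arr.ind = TRUE)
    writeLines(paste(rownames(ct)[idx[, 1]], colnames(ct)[idx[, 2]],
                     ifelse(ct[idx], "test", "train"), sep = "\t"), con)
  }
  invisible(file)
}

#' @rdname writeSplitPlan
#' @param am the [AssayMatrix-class] the plan refers to (needed to restore
#'   the cell grid of time plans).
#' @export
readSplitPlan <- function(file, am = NULL) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  geth <- function(key) sub(paste0("# ", key, ": "), "",
                            grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  strategy <- geth("strategy")
  K <- suppressWarnings(as.integer(geth("K")))
  cutoff_s <- geth("cutoff")
  cutoff <- if (!length(cutoff_s) || cutoff_s %in% c("NA", ""))
    as.Date(NA) else as.Date(cutoff_s)
  seed <- suppressWarnings(as.integer(geth("seed")))
  if (strategy %in% c("cluster", "random")) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    fold <- stats::setNames(
      as.integer(vapply(parts, `[`, "", 2)),
      vapply(parts, `[`, "", 1))
    cell <- matrix(logical(0), 0, 0)
  } else {
    if (is.null(am)) stop("restoring a time plan requires the AssayMatrix")
    parts <- strsplit(body, "\t", fixed = TRUE)
    cell <- matrix(NA, nrow(am), ncol(am), dimnames = dimnames(assayMask(am)))
    cell[cbind(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))] <-
      vapply(parts, `[`, "", 3) == "test"
    fold <- stats::setNames(rep(NA_integer_, nrow(am)), rownames(am))
  }
  new("SplitPlan", strategy = strategy, fold = fold, cellTest = cell,
      K = if (length(K)) K else NA_integer_,
      cutoff = if (length(cutoff)) cutoff else as.Date(NA),
      seed = if (length(seed)) seed else NA_integer_)
}

setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan (", object@strategy, ")\n", sep = "")
  if (object@strategy %in% c("cluster", "random")) {
    tb <- table(object@fold)
    cat("  folds:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  } else {
    cat("  cutoff:", format(object@cutoff), "; train cells:",
        sum(!object@cellTest, na.rm = TRUE), "; test cells:",
        sum(object@cellTest, na.rm = TRUE), "\n")
  }
})
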