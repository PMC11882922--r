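#' First-level percept contrast
#'
#' Per-voxel least-squares regression of the per-trial volumes on the
#' two percept indicator regressors ("felt as one", "felt as two"). For
#' this dummy design the coefficient estimates are the condition means,
#' so the contrast `beta_two - beta_one` equals the difference of
#' condition-mean volumes exactly — computing it this way *is* solving
#' the regression.
#'
#' @param volumes a [ScalpVolumes-class] with one column per trial.
#' @param percepts character vector ("one"/"two") per trial (defaults
#'   to the `percept` column of the volume metadata).
#' @return a [ScalpVolumes-class] with a single contrast column;
#'   attribute `"nPerCondition"` carries the trial counts.
#' @export
firstLevel <- function(volumes, percepts = volumes@meta$percept) {
  stopifnot(is(volumes, "ScalpVolumes"))
  if (is.null(percepts) || length(percepts) != ncol(volumes@data))
    stop("need one percept per trial volume")
  nOne <- sum(percepts == "one"); nTwo <- sum(percepts == "two")
  if (nOne == 0 || nTwo == 0)
    stop(sprintf("each condition needs >= 1 trial (one: %d, two: %d)",
                 nOne, nTwo))
  ctr <- rowMeans(volumes@data[, percepts == "two", drop = FALSE]) -
         rowMeans(volumes@data[, percepts == "one", drop = FALSE])
  out <- new("ScalpVolumes", gridX = volumes@gridX, gridY = volumes@gridY,
             mask = volumes@mask, times = volumes@times,
             data = matrix(ctr, ncol = 1), meta = data.frame())
  attr(out@data, "nPerCondition") <- c(one = nOne, two = nTwo)
  out
}

#' Combine per-subject contrast volumes
#'
#' @param contrastList list of single-column [ScalpVolumes-class]
#'   objects sharing a mask.
#' @param meta optional per-subject data.frame.
#' @return a [ScalpVolumes-class] with one column per subject.
#' @export
bindContrasts <- function(contrastList, meta = data.frame()) {
  ref <- contrastList[[1]]
  for (v in contrastList)
    if (!identical(v@mask, ref@mask)) stop("masks differ across subjects")
  new("ScalpVolumes", gridX = ref@gridX, gridY = ref@gridY,
      mask = ref@mask, times = ref@times,
      data = do.call(cbind, lapply(contrastList, function(v) v@data)),
      meta = as.data.frame(meta))
}

# per-voxel group t for the intercept with optional mean-centered
# nuisance covariates; Y is nsubj x nvox
groupTStat <- function(Y, covariates = NULL) {
  n <- nrow(Y)
  m <- colMeans(Y)
  ss <- colSums(Y^2)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    C <- sweep(C, 2, colMeans(C))
    keep <- apply(C, 2, function(v) sd(v) > 1e-12)
    if (!all(keep)) {
      warning("constant covariate dropped; simple t-test used for that term")
      C <- C[, keep, drop = FALSE]
    }
    if (ncol(C) > 0) {
      Q <- qr.Q(qr(C))
      B <- crossprod(Q, Y)
      rss <- ss - n * m^2 - colSums(B^2)
      df <- n - 1 - ncol(C)
    } else {
      rss <- ss - n * m^2
      df <- n - 1
    }
  } else {
    rss <- ss - n * m^2
    df <- n - 1
  }
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / n)
  list(t = m / pmax(se, .Machine$double.xmin), df = df)
}

#' Second-level (group) t-map
#'
#' Per voxel, fits `y = b0 + b1 (covariate - mean) + e` across subjects
#' and returns the one-tailed t statistic for `b0 > 0` with `n - 2`
#' degrees of freedom (or a one-sample t with `n - 1` df without a
#' covariate). Because the covariate is mean-centered, `b0` is the
#' group-mean contrast; the t-map is invariant to adding a constant to
#' the covariate.
#'
#' @param volumes a [ScalpVolumes-class], one column per subject.
#' @param covariate numeric vector (e.g. each subject's discrimination
#'   threshold), a matrix of covariates, or NULL.
#' @return list `t` (statistic per voxel), `df`.
#' @export
secondLevel <- function(volumes, covariate = NULL) {
  stopifnot(is(volumes, "ScalpVolumes"))
  n <- ncol(volumes@data)
  if (n < 3) stop("need >= 3 subjects")
  if (!is.null(covariate) && !all(is.finite(as.matrix(covariate))))
    stop("covariate must be finite")
  groupTStat(t(volumes@data), covariate)
}

# connected components (6-connectivity: x, y and time neighbours) of
# supra-threshold voxels; rows index masked voxels time-major
connectedClusters <- function(rows, maskIdx, nMask, nTime, nx, ny) {
  if (length(rows) == 0)
    return(list(labels = integer(0), sizes = integer(0)))
  ncell <- nx * ny
  mcell <- ((rows - 1L) %% nMask) + 1L
  tix <- ((rows - 1L) %/% nMask) + 1L
  cell <- maskIdx[mcell]                    # 1..nx*ny, x fastest
  gx <- ((cell - 1L) %% nx) + 1L
  gy <- ((cell - 1L) %/% nx) + 1L
  key <- cell + ncell * (tix - 1L)
  ord <- order(key)
  key <- key[ord]
  edges <- function(offset, ok) {
    j <- match(key + offset, key)
    good <- which(!is.na(j) & ok)
    cbind(good, j[good])
  }
  e <- rbind(edges(1L, gx[ord] < nx),
             edges(nx, gy[ord] < ny),
             edges(ncell, tix[ord] < nTime))
  parent <- seq_along(key)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(e) > 0) {
    for (k in seq_len(nrow(e))) {
      ra <- findRoot(e[k, 1]); rb <- findRoot(e[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  lab <- vapply(seq_along(key), findRoot, integer(1))
  lab <- match(lab, unique(lab))
  labels <- integer(length(rows))
  labels[ord] <- lab
  list(labels = labels, sizes = tabulate(lab))
}

#' Find supra-threshold clusters in a t-map
#'
#' Marks voxels with one-tailed p below `clusterAlpha` (the
#' cluster-defining threshold) and groups them into face-connected
#' components (6-connectivity over the 32 x 32 grid and time). Cluster
#' extent, time span and peak are reported; family-wise-corrected
#' p-values come from [clusterFwe()].
#'
#' @param tstat t statistic per voxel (aligned with `volumes` rows).
#' @param df degrees of freedom.
#' @param volumes a [ScalpVolumes-class] supplying mask/grid/times.
#' @param clusterAlpha cluster-defining threshold (default 0.001).
#' @param tail `"one"` (positive direction) or `"two"`.
#' @return data.frame, one row per cluster (possibly empty), columns
#'   `cluster_id, k_voxels, time_min_ms, time_max_ms, t_peak,
#'   peak_time_ms, peak_grid_x, peak_grid_y`; attribute `"voxels"`
#'   holds the per-cluster row indices.
#' @export
findClusters <- function(tstat, df, volumes, clusterAlpha = 0.001,
                         tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (df < 1) stop("df must be >= 1")
  tcrit <- qt(1 - clusterAlpha, df)
  stat <- if (tail == "two") abs(tstat) else tstat
  rows <- which(stat > tcrit)
  nMask <- sum(volumes@mask); nTime <- length(volumes@times)
  nx <- length(volumes@gridX); ny <- length(volumes@gridY)
  maskIdx <- which(volumes@mask)
  comp <- connectedClusters(rows, maskIdx, nMask, nTime, nx, ny)
  if (length(rows) == 0) {
    out <- data.frame(cluster_id = integer(0), k_voxels = integer(0),
                      time_min_ms = numeric(0), time_max_ms = numeric(0),
                      t_peak = numeric(0), peak_time_ms = numeric(0),
                      peak_grid_x = numeric(0), peak_grid_y = numeric(0))
    attr(out, "voxels") <- list()
    return(out)
  }
  mcell <- ((rows - 1L) %% nMask) + 1L
  tix <- ((rows - 1L) %/% nMask) + 1L
  cell <- maskIdx[mcell]
  gx <- ((cell - 1L) %% nx) + 1L
  gy <- ((cell - 1L) %/% nx) + 1L
  tms <- volumes@times[tix] * 1000
  ids <- sort(unique(comp$labels))
  recs <- lapply(ids, function(cl) {
    sel <- comp$labels == cl
    pk <- which(sel)[which.max(stat[rows[sel]])]
    data.frame(cluster_id = cl, k_voxels = sum(sel),
               time_min_ms = min(tms[sel]), time_max_ms = max(tms[sel]),
               t_peak = tstat[rows[pk]], peak_time_ms = tms[pk],
               peak_grid_x = volumes@gridX[gx[pk]],
               peak_grid_y = volumes@gridY[gy[pk]])
  })
  out <- do.call(rbind, recs)
  out <- out[order(-out$k_voxels), , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  attr(out, "voxels") <- lapply(ids[order(-vapply(ids, function(cl)
    sum(comp$labels == cl), integer(1)))], function(cl) rows[comp$labels == cl])
  out
}

#' Cluster-level family-wise error control by sign-flip permutation
#'
#' Builds the null distribution of the maximum cluster extent (and
#' maximum peak t) by randomly sign-flipping the covariate-residualized
#' subject contrasts, recomputing the group t-map and clustering at the
#' cluster-defining threshold each time. Corrected p-values follow the
#' permutation convention `p = (1 + #{null >= observed}) / (1 + nPerm)`.
#'
#' @param volumes a [ScalpVolumes-class], one contrast column per
#'   subject.
#' @param covariate optional nuisance covariate(s) as in
#'   [secondLevel()].
#' @param nPerm number of sign-flip permutations (default 1000; fewer
#'   than 100 warns, fewer than 20 is an error).
#' @param clusterAlpha cluster-defining threshold.
#' @param tail `"one"` or `"two"`.
#' @param chunk permutations per block (memory control).
#' @return list with `clusters` (the [findClusters()] table plus
#'   `p_fwe_cluster` and `p_fwe_peak`), `t`, `df`, `nullMaxExtent`,
#'   `nullMaxT`.
#' @export
clusterFwe <- function(volumes, covariate = NULL, nPerm = 1000L,
                       clusterAlpha = 0.001, tail = c("one", "two"),
                       chunk = 50L) {
  tail <- match.arg(tail)
  stopifnot(is(volumes, "ScalpVolumes"))
  n <- ncol(volumes@data)
  if (n < 8) stop("need >= 8 subjects for meaningful sign-flipping")
  if (nPerm < 20) stop("nPerm must be >= 20")
  if (nPerm < 100) warning("nPerm < 100 gives a very coarse p-value floor")
  Y <- t(volumes@data)                      # subjects x voxels
  obs <- groupTStat(Y, covariate)
  clusters <- findClusters(obs$t, obs$df, volumes, clusterAlpha, tail)
  # reduced-model residuals (nuisance only) for the permutation null
  C <- NULL
  if (!is.null(covariate)) {
    C <- as.matrix(covariate)
    C <- sweep(C, 2, colMeans(C))
    C <- C[, apply(C, 2, function(v) sd(v) > 1e-12), drop = FALSE]
    if (ncol(C) == 0) C <- NULL
  }
  R <- if (is.null(C)) Y else Y - C %*% qr.solve(C, Y)
  ss2 <- colSums(R^2)
  Q <- if (is.null(C)) NULL else qr.Q(qr(C))
  df <- obs$df
  tcrit <- qt(1 - clusterAlpha, df)
  nMask <- sum(volumes@mask); nTime <- length(volumes@times)
  nx <- length(volumes@gridX); ny <- length(volumes@gridY)
  maskIdx <- which(volumes@mask)
  nullMaxExtent <- numeric(nPerm)
  nullMaxT <- numeric(nPerm)
  done <- 0L
  # t^2 = df * A^2 / (n*ss2 - A^2 - n*sum_j B_j^2) for sign-flipped sums
  # A; working on the squared scale avoids per-voxel sqrt/divisions
  RQ <- if (is.null(Q)) list() else
    lapply(seq_len(ncol(Q)), function(j) Q[, j] * R)
  nss2C <- matrix(n * ss2, chunk, length(ss2), byrow = TRUE)
  gcrit <- tcrit^2 / df
  while (done < nPerm) {
    p <- min(chunk, nPerm - done)
    S <- matrix(sample(c(-1, 1), p * n, replace = TRUE), p, n)
    A <- S %*% R
    A2 <- A * A
    D <- (if (p == chunk) nss2C else nss2C[seq_len(p), , drop = FALSE]) - A2
    for (Rq in RQ) {
      Bj <- S %*% Rq
      D <- D - n * (Bj * Bj)
    }
    if (min(D) <= 0) D[D <= 0] <- .Machine$double.xmin
    G <- A2 / D                            # t^2 / df, unsigned
    if (tail == "one") G[A <= 0] <- 0
    for (i in seq_len(p)) {
      gi <- G[i, ]
      rows <- which(gi > gcrit)
      comp <- connectedClusters(rows, maskIdx, nMask, nTime, nx, ny)
      nullMaxExtent[done + i] <-
        if (length(comp$sizes)) max(comp$sizes) else 0
      nullMaxT[done + i] <- sqrt(df * max(gi, 0))
    }
    done <- done + p
  }
  if (nrow(clusters) > 0) {
    clusters$p_fwe_cluster <- vapply(clusters$k_voxels, function(k)
      (1 + sum(nullMaxExtent >= k)) / (1 + nPerm), numeric(1))
    stat <- if (tail == "two") abs(clusters$t_peak) else clusters$t_peak
    clusters$p_fwe_peak <- vapply(stat, function(tp)
      (1 + sum(nullMaxT >= tp)) / (1 + nPerm), numeric(1))
  } else {
    clusters$p_fwe_cluster <- numeric(0)
    clusters$p_fwe_peak <- numeric(0)
  }
  list(clusters = clusters, t = obs$t, df = df,
       nullMaxExtent = nullMaxExtent, nullMaxT = nullMaxT)
}

#' Median-split subgroup analysis
#'
#' Runs the cluster-level analysis independently in the low- and
#' high-threshold subgroups defined by `splitMs` (subjects exactly at
#' the split go to the low group).
#'
#' @param volumes per-subject contrast [ScalpVolumes-class].
#' @param stdts per-subject discrimination thresholds, ms.
#' @param splitMs split point (default 30 ms).
#' @param includeCovariate pass the threshold covariate down to each
#'   subgroup analysis.
#' @param ... forwarded to [clusterFwe()].
#' @return list `low`, `high` (each a [clusterFwe()] result) and
#'   `groups` (assignment vector).
#' @export
medianSplitAnalysis <- function(volumes, stdts, splitMs = 30,
                                includeCovariate = TRUE, ...) {
  grp <- ifelse(stdts <= splitMs, "low", "high")
  if (min(table(factor(grp, c("low", "high")))) < 4)
    stop("each subgroup needs >= 4 subjects")
  sub <- function(g) {
    idx <- which(grp == g)
    v <- new("ScalpVolumes", gridX = volumes@gridX, gridY = volumes@gridY,
             mask = volumes@mask, times = volumes@times,
             data = volumes@data[, idx, drop = FALSE], meta = data.frame())
    clusterFwe(v, covariate = if (includeCovariate) stdts[idx] else NULL, ...)
  }
  list(low = sub("low"), high = sub("high"), groups = grp)
}

#' Run-drift covariate control analysis
#'
#' Augments the group model with a subject-level covariate summarizing
#' the drift of the threshold's ISI level across runs (for example the
#' per-subject mean selected level), alongside the threshold covariate;
#' the inference path is otherwise identical to the main analysis.
#'
#' @param volumes per-subject contrast [ScalpVolumes-class].
#' @param stdts per-subject thresholds.
#' @param runLevelCovariate per-subject run-drift summary (numeric).
#' @param ... forwarded to [clusterFwe()].
#' @export
runCovariateVariant <- function(volumes, stdts, runLevelCovariate, ...) {
  if (length(runLevelCovariate) != ncol(volumes@data))
    stop("run-level covariate must have one value per subject")
  clusterFwe(volumes, covariate = cbind(stdt = stdts,
                                        drift = runLevelCovariate), ...)
}

#' Write a cluster table as TSV
#'
#' @param result a [clusterFwe()] result.
#' @param path output file.
#' @param layout optional [ChannelLayout-class] to name the electrode
#'   nearest each cluster peak.
#' @export
writeClusterTable <- function(result, path, layout = NULL) {
  tab <- result$clusters
  if (!is.null(layout) && nrow(tab) > 0) {
    scalp <- which(layout@type == "eeg")
    tab$nearest_electrode <- vapply(seq_len(nrow(tab)), function(i) {
      d <- (layout@pos2d[scalp, 1] - tab$peak_grid_x[i])^2 +
           (layout@pos2d[scalp, 2] - tab$peak_grid_y[i])^2
      layout@names[scalp[which.min(d)]]
    }, character(1))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
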