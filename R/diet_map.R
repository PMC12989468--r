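# Diet-stability analysis: RMS-scaled Euclidean distances over the 12 diet
# summary variables, Sammon nonlinear mapping of the records, and responder-
# stratified within-participant diet-distance tests.

#' Euclidean distances on RMS-scaled centred diet variables
#'
#' Each variable is centred by its overall mean and scaled by the root mean
#' square of the centred values, then pairwise Euclidean distances are
#' computed. Zero-RMS (constant) variables are dropped with a warning. The
#' scaling makes distances invariant to per-variable affine rescaling of raw
#' units (frequencies vs millilitres).
#'
#' @param records data.frame or matrix of diet variables (rows = records,
#'   e.g. participant-timepoints; non-numeric id columns are ignored).
#' @return a `dist` object over the rows.
#' @export
diet_distances <- function(records) {
  x <- as.matrix(records[vapply(as.data.frame(records), is.numeric,
                                TRUE)])
  if (anyNA(x)) stop("complete records required")
  cx <- sweep(x, 2, colMeans(x))
  rms <- sqrt(colMeans(cx^2))
  if (any(rms == 0)) {
    warning("dropping zero-RMS variable(s): ",
            paste(colnames(x)[rms == 0], collapse = ", "))
    cx <- cx[, rms > 0, drop = FALSE]
    rms <- rms[rms > 0]
  }
  stats::dist(sweep(cx, 2, rms, "/"))
}

#' Sammon stress of a configuration
#'
#' The Sammon objective
#' `E = (1 / sum(delta)) * sum((delta - d)^2 / delta)` over all pairs, where
#' `delta` are the input distances and `d` the distances in the embedding.
#'
#' @param d input distances (`dist` or symmetric matrix).
#' @param coords embedded coordinates, one row per point.
#' @return nonnegative stress value.
#' @export
sammon_stress <- function(d, coords) {
  delta <- as.numeric(stats::as.dist(d))
  dd <- as.numeric(stats::dist(coords))
  sum((delta - dd)^2 / delta) / sum(delta)
}

#' Sammon nonlinear mapping
#'
#' Minimises the Sammon stress by the classic pseudo-Newton iteration with
#' step halving ([MASS::sammon()]), initialised from classical scaling so the
#' result is deterministic. Exact duplicate records (zero off-diagonal
#' distances, common in ordinal survey data) receive a deterministic 1e-9
#' jitter before optimisation. Convergence is declared when a short
#' continuation run improves the stress by less than `tol`.
#'
#' @param d `dist` object or symmetric distance matrix (zero diagonal,
#'   nonnegative).
#' @param dim embedding dimension (2 for the diet ordination).
#' @param max_iter maximum iterations.
#' @param tol relative stress-change convergence tolerance.
#' @return list with `coordinates`, `stress`, `converged`, `max_iter`.
#' @export
sammon_map <- function(d, dim = 2, max_iter = 500, tol = 1e-7) {
  m <- as.matrix(stats::as.dist(d))
  if (any(m < 0)) stop("negative distances")
  off <- m[upper.tri(m)]
  if (any(off == 0)) {
    # deterministic jitter for exact duplicates: division by delta forbids 0
    m[m == 0] <- 1e-9
    diag(m) <- 0
  }
  dd <- stats::as.dist(m)
  fit <- MASS::sammon(dd, k = dim, niter = max_iter, tol = tol,
                      trace = FALSE)
  more <- MASS::sammon(dd, y = fit$points, k = dim, niter = 10, tol = 0,
                       trace = FALSE)
  list(coordinates = fit$points,
       stress = sammon_stress(dd, fit$points),
       converged = (fit$stress - more$stress) < tol * max(fit$stress, 1e-12),
       max_iter = max_iter)
}

#' Within-participant diet shifts stratified by responder class
#'
#' Computes within-participant distances (on the RMS-scaled space over all
#' records) for each timepoint pair and tests, per pair, whether the
#' distances differ across LR / MR / HR via Kruskal-Wallis (+ Dunn post
#' hoc). Degenerate pairs (all distances equal) are reported as
#' non-significant with a warning.
#'
#' @param records data.frame with `participant`, `timepoint`, and the 12
#'   diet variables.
#' @param labels a [stratify()] result (participant -> LR/MR/HR).
#' @return list with `distances` (participant, pair, distance, class) and
#'   `tests` (pair, p, statistic).
#' @export
diet_shift_by_responder <- function(records, labels) {
  num <- vapply(records, is.numeric, TRUE)
  num[names(records) %in% c("participant", "timepoint")] <- FALSE
  dmat <- as.matrix(diet_distances(records[num]))
  key <- paste(records$participant, records$timepoint)
  rownames(dmat) <- colnames(dmat) <- key
  pairs <- list(c("W0", "W4"), c("W4", "W8"), c("W0", "W8"))
  recs <- list()
  for (id in unique(records$participant)) {
    for (p in pairs) {
      k1 <- paste(id, p[1]); k2 <- paste(id, p[2])
      if (k1 %in% key && k2 %in% key) {
        recs[[length(recs) + 1]] <- data.frame(
          participant = id, pair = paste(p, collapse = "-"),
          distance = dmat[k1, k2],
          class = as.character(labels$class[[id]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  dists <- do.call(rbind, recs)
  tests <- lapply(split(dists, dists$pair), function(dp) {
    if (length(unique(dp$distance)) == 1) {
      warning("degenerate diet distances for pair ", dp$pair[1],
              ": reported non-significant")
      return(data.frame(pair = dp$pair[1], statistic = 0, p = 1))
    }
    kd <- kruskal_dunn(dp$distance, dp$class)
    data.frame(pair = dp$pair[1], statistic = kd$statistic, p = kd$p)
  })
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  list(distances = dists, tests = tests)
}
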