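# Nonparametric testing toolkit shared by all analysis stages.
#
# Omnibus tests are delegated to the standard base-R implementations
# (friedman.test, kruskal.test, wilcox.test, cor.test, ks.test, chisq.test);
# the post hoc machinery (Conover all-pairs after Friedman, Dunn's test after
# Kruskal-Wallis) and the rank-based permutation surrogate for the
# group-by-time interaction are implemented here because no installed package
# provides them. Mid-ranks are used for ties throughout, with tie-corrected
# variances.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with respect to the input.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  check_p(p)
  stats::p.adjust(p, method = "BH")
}

#' Holm adjustment
#'
#' Step-down family-wise error rate adjustment.
#'
#' @inheritParams bh_adjust
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  check_p(p)
  stats::p.adjust(p, method = "holm")
}

check_p <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  invisible(p)
}

#' Friedman rank sum test with Conover post hoc comparisons
#'
#' Omnibus Friedman chi-square on within-block ranks (unreplicated blocked
#' design, mid-ranks for ties). When the omnibus p-value is at or below
#' `alpha`, Conover's all-pairs rank-sum t statistics are computed with
#' Benjamini-Hochberg adjustment across pairs, and a compact letter display
#' summarises which conditions are indistinguishable.
#'
#' @param data numeric matrix, blocks (e.g. participants) in rows, conditions
#'   (e.g. timepoints) in columns; complete cases only.
#' @param alpha significance gate for running the post hoc step.
#' @return list with `statistic`, `df`, `p`, `method`, and (when run)
#'   `pairwise` (data.frame: a, b, t, p, adjusted_p) and `letters`.
#' @note The statistic is the tie-corrected Friedman chi-square
#'   (k-1) * sum_j (R_j - n(k+1)/2)^2 / (A1 - C1) with A1 the sum of squared
#'   mid-ranks and C1 = n k (k+1)^2 / 4; it reduces to the classical
#'   12/(nk(k+1)) form when no ties are present. `stats::friedman.test`
#'   omits the tie correction, which matters for heavily tied survey data.
#' @export
friedman_conover <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("incomplete blocks: remove rows with missing cells")
  n <- nrow(data)
  k <- ncol(data)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 conditions")
  r <- t(apply(data, 1, rank))
  R <- colSums(r)
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  if (A1 - C1 <= 0) { # every block fully tied
    return(list(statistic = 0, df = k - 1, p = 1, method = "friedman"))
  }
  T2 <- (k - 1) * sum((R - n * (k + 1) / 2)^2) / (A1 - C1)
  out <- list(statistic = T2, df = k - 1,
              p = stats::pchisq(T2, k - 1, lower.tail = FALSE),
              method = "friedman")
  if (out$p <= alpha) {
    dfree <- (n - 1) * (k - 1)
    sedenom <- sqrt(2 * n * (1 - T2 / (n * (k - 1))) * (A1 - C1) /
                      ((n - 1) * (k - 1)))
    pairs <- utils::combn(k, 2)
    dR <- R[pairs[1, ]] - R[pairs[2, ]]
    if (sedenom == 0) { # perfect within-block concordance
      tval <- sign(dR) * Inf
      tval[dR == 0] <- 0
    } else {
      tval <- dR / sedenom
    }
    pv <- 2 * stats::pt(-abs(tval), dfree)
    adj <- bh_adjust(pv)
    cn <- colnames(data) %||% as.character(seq_len(k))
    out$pairwise <- data.frame(a = cn[pairs[1, ]], b = cn[pairs[2, ]],
                               t = tval, p = pv, adjusted_p = adj,
                               stringsAsFactors = FALSE)
    out$letters <- compact_letters(cn, out$pairwise$a, out$pairwise$b,
                                   out$pairwise$adjusted_p <= alpha)
  }
  out
}

#' Kruskal-Wallis test with Dunn's all-pairs post hoc
#'
#' Tie-corrected Kruskal-Wallis H followed by Dunn z statistics on mean
#' ranks, Benjamini-Hochberg adjusted across pairs.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.
#' @return list with `statistic`, `df`, `p`, `method`, `pairwise`
#'   (a, b, z, p, adjusted_p) and `letters`.
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tiesum <- sum(ties^3 - ties)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(nlevels(groups), 2)
  sigma <- sqrt((N * (N + 1) / 12 - tiesum / (12 * (N - 1))) *
                  (1 / ng[pairs[1, ]] + 1 / ng[pairs[2, ]]))
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / sigma
  pv <- 2 * stats::pnorm(-abs(z))
  adj <- bh_adjust(pv)
  pw <- data.frame(a = lev[pairs[1, ]], b = lev[pairs[2, ]],
                   z = as.numeric(z), p = as.numeric(pv),
                   adjusted_p = as.numeric(adj), stringsAsFactors = FALSE)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, method = "kruskal-dunn", pairwise = pw,
       letters = compact_letters(lev, pw$a, pw$b, pw$adjusted_p <= 0.05))
}

#' Wilcoxon rank sum test with continuity correction
#'
#' Normal approximation with 0.5 continuity correction and tie-corrected
#' variance (the convention for survey-scale data with heavy ties).
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (W), `p`, `method`.
#' @export
wilcoxon_cc <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty input")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = "wilcoxon-cc")
}

#' Pearson product-moment correlation
#'
#' @param a,b numeric vectors of equal length (n >= 3).
#' @return list with `r`, `p` (two-sided, t-distribution), `n`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3) stop("need n >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance input")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (D), `p`, `method`.
#' @export
ks_test2 <- function(x, y) {
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(kt$statistic), p = kt$p.value, method = "ks")
}

#' Chi-squared test on a contingency table
#'
#' @param tab integer matrix of counts.
#' @param correct apply Yates continuity correction (default FALSE: the raw
#'   chi-square statistic is reported).
#' @return list with `statistic`, `df`, `p`, `expected_warning` (TRUE when
#'   any expected cell count is below 5).
#' @export
chi2_test <- function(tab, correct = FALSE) {
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected_warning = any(ct$expected < 5))
}

#' Permutation test for a group-by-time interaction in ranked trajectories
#'
#' Nonparametric surrogate for a split-plot (2 independent groups x 3
#' repeated measures) longitudinal analysis. Observations are globally
#' mid-ranked; each participant's rank trajectory is centred by its own mean
#' (removing participant level), and the statistic is the sum over timepoints
#' of the squared difference in group mean centred ranks. The null is built
#' by permuting group labels across participants; the empirical p-value uses
#' the add-one convention (1 + #perm >= obs) / (1 + n_perm) so it is never
#' exactly zero.
#'
#' @param values numeric observations.
#' @param group 2-level group labels per observation.
#' @param time timepoint labels per observation.
#' @param participant participant ids per observation.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with `statistic`, `p`, `n_perm`, `method`.
#' @export
group_time_interaction_perm <- function(values, group, time, participant,
                                        n_perm = 1000, seed = 1) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly 2 groups required")
  time <- as.factor(time)
  participant <- as.factor(participant)
  r <- rank(values)
  # participant x time matrix of centred ranks; complete cases enforced
  m <- tapply(r, list(participant, time), mean)
  if (anyNA(m)) stop("complete cases required: every participant needs all timepoints")
  m <- m - rowMeans(m)
  pg <- tapply(as.integer(group), participant, function(g) g[1])
  stat_fun <- function(lab) {
    d <- colMeans(m[lab == 1, , drop = FALSE]) -
      colMeans(m[lab == 2, , drop = FALSE])
    sum(d^2)
  }
  obs <- stat_fun(pg)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat_fun(sample(pg)), 0)
  })
  list(statistic = obs, p = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_perm = n_perm, method = "rank-interaction-permutation")
}

#' Compact letter display from pairwise significance
#'
#' Greedy insert-absorb assignment: conditions not significantly different
#' share at least one letter; significantly different conditions share none.
#'
#' @param labels condition labels.
#' @param a,b pairwise comparison endpoints.
#' @param sig logical, TRUE where the pair differs significantly.
#' @return named character vector of letter strings.
#' @export
compact_letters <- function(labels, a, b, sig) {
  k <- length(labels)
  diffmat <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (i in seq_along(a)) {
    diffmat[a[i], b[i]] <- diffmat[b[i], a[i]] <- sig[i]
  }
  groups <- list(labels[1])
  for (lab in labels[-1]) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(diffmat[lab, groups[[gi]]])) {
        groups[[gi]] <- c(groups[[gi]], lab)
        placed <- TRUE
      }
    }
    if (!placed) groups <- c(groups, list(lab))
  }
  # absorb redundant groups
  keep <- rep(TRUE, length(groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i != j && keep[i] && keep[j] &&
          all(groups[[i]] %in% groups[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  groups <- groups[keep]
  out <- stats::setNames(rep("", k), labels)
  for (gi in seq_along(groups)) {
    for (lab in groups[[gi]]) out[lab] <- paste0(out[lab], letters[gi])
  }
  out
}
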