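# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles recompute null distributions by enumeration or direct
# permutation, independent of the package's code paths.

# Exact Friedman null: enumerate all (k!)^n within-block orderings of the
# observed values and count orderings whose tie-corrected statistic reaches
# the observed one. Feasible for n = 4 blocks, k = 3 conditions (1296).
exact_friedman_p <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  stopifnot(k == 3, n <= 5)
  tie_stat <- function(mm) {
    r <- t(apply(mm, 1, rank))
    A1 <- sum(r^2)
    C1 <- n * k * (k + 1)^2 / 4
    if (A1 - C1 <= 0) return(0)
    (k - 1) * sum((colSums(r) - n * (k + 1) / 2)^2) / (A1 - C1)
  }
  obs <- tie_stat(m)
  ords <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  grid <- as.matrix(expand.grid(rep(list(1:6), n)))
  hits <- 0
  for (i in seq_len(nrow(grid))) {
    mm <- t(vapply(seq_len(n), function(b) m[b, ords[grid[i, b], ]],
                   numeric(k)))
    if (tie_stat(mm) >= obs - 1e-9) hits <- hits + 1
  }
  hits / nrow(grid)
}

# Monte Carlo permutation null for the Kruskal-Wallis H (tie-corrected),
# permuting group membership of the pooled ranks.
mc_kruskal_p <- function(vals, grp, B = 20000, seed = 42) {
  r <- rank(vals)
  N <- length(vals)
  ng <- table(grp)
  ties <- table(r)
  tiecorr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H_of <- function(rr) {
    sums <- rowsum(rr, grp)[, 1]
    (12 / (N * (N + 1)) * sum(sums^2 / ng) - 3 * (N + 1)) / tiecorr
  }
  obs <- H_of(r)
  set.seed(seed)
  mean(vapply(seq_len(B), function(b) H_of(sample(r)), 0) >= obs - 1e-9)
}

# tiny complete longitudinal dataset: n participants per group, 3 timepoints
make_longitudinal <- function(n_per_group, slope_g2 = 0, sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  pid <- sprintf("S%02d", seq_len(n))
  grp <- rep(c("A", "B"), each = n_per_group)
  tp <- c("W0", "W4", "W8")
  d <- expand.grid(participant = pid, time = tp, stringsAsFactors = FALSE)
  d$group <- grp[match(d$participant, pid)]
  tnum <- match(d$time, tp) - 1
  d$value <- rnorm(nrow(d), sd = sd) +
    ifelse(d$group == "B", slope_g2 * tnum, 0)
  d
}

# small all-final cohort for simulation-heavy tests
small_cohort_config <- function(n, seed = 1) {
  cohort_config(n_enrolled = n, n_dropout = 0, n_quality_excluded = 0,
                n_validation_excluded = 0, seed = seed)
}
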