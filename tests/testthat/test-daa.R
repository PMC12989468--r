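# small paired table builder: one participant per column pair, counts given
# as ASV x sample matrix with matching metadata
paired_fixture <- function(counts) {
  ids <- unique(sub("-(W0|W4|W8)$", "", colnames(counts)))
  md <- data.frame(
    `sample-id` = colnames(counts),
    participant = sub("-(W0|W4|W8)$", "", colnames(counts)),
    timepoint = sub("^.*-", "", colnames(counts)),
    check.names = FALSE, stringsAsFactors = FALSE)
  list(counts = counts, metadata = md, ids = ids)
}

test_that("paired log2 fold changes follow the pseudocount formula", {
  n_asv <- 12
  base <- matrix(100L, n_asv, 2,
                 dimnames = list(sprintf("A%02d", 1:n_asv),
                                 c("P1-W0", "P1-W8")))
  fx <- paired_fixture(base)
  cfg <- daa_config(contrasts = "W8", prevalence_min = 0)
  fc <- paired_log2fc(fx$counts, fx$metadata, cfg)
  expect_equal(unname(fc$fc$W8["P1", ]), rep(0, n_asv)) # identical samples

  # doubled count at (approximately) equal depth: +1 in the pc << count limit
  m <- base
  m[1, 2] <- 200L
  m[2, 2] <- 0L # keep depth near-equal via a compensating drop
  fc2 <- paired_log2fc(m, fx$metadata, cfg)
  expect_equal(fc2$fc$W8["P1", "A01"], 1, tolerance = 0.01)

  # 0 -> 7 at depth 1000 with pc = 0.5: log2(7.5 / 0.5)
  z <- matrix(0L, n_asv, 2, dimnames = dimnames(base))
  z[3, ] <- c(0L, 7L)
  z[12, ] <- c(1000L, 993L) # filler keeping both depths at 1000
  fcz <- paired_log2fc(z, fx$metadata, cfg)
  expect_equal(fcz$fc$W8["P1", "A03"], log2(7.5 / 0.5), tolerance = 1e-12)

  # participants without W0 are skipped and reported
  m2 <- cbind(base, `P2-W8` = rep(5L, n_asv))
  fx2 <- paired_fixture(m2)
  fc3 <- paired_log2fc(fx2$counts, fx2$metadata, cfg)
  expect_equal(fc3$skipped, "P2")
  expect_equal(rownames(fc3$fc$W8), "P1")

  # prevalence filter removes rare ASVs
  rare <- base
  rare[4, ] <- 0L
  fc4 <- paired_log2fc(rare, fx$metadata,
                       daa_config(contrasts = "W8", prevalence_min = 0.25))
  expect_false("A04" %in% fc4$asvs)
})

test_that("median centring removes common shifts and keeps planted effects", {
  set.seed(33)
  fc <- matrix(rnorm(15 * 200, sd = 0.3), 15, 200,
               dimnames = list(NULL, sprintf("A%03d", 1:200)))
  shifted <- fc + 2.5 # constant compositional shift for every ASV
  expect_equal(bias_correct(shifted), bias_correct(fc), tolerance = 1e-12)
  expect_equal(unname(apply(bias_correct(shifted), 1, median)), rep(0, 15))

  planted <- fc
  planted[, 1] <- planted[, 1] + 2
  cc <- bias_correct(planted)
  expect_equal(mean(cc[, 1]), 2, tolerance = 0.15)

  expect_error(bias_correct(fc[, 1:5]), "at least 10")
})

test_that("the joint p + fold-change rule detects planted effects and not noise", {
  # power: 4-fold planted effect, n = 30, within-subject sd 0.5 log2
  detect <- vapply(1:50, function(i) {
    set.seed(400 + i)
    fc <- matrix(rnorm(30 * 50, 0, 0.5), 30, 50,
                 dimnames = list(NULL, sprintf("A%02d", 1:50)))
    fc[, 1] <- fc[, 1] + 2
    res <- daa_test(list(W8 = bias_correct(fc)), daa_config(contrasts = "W8"))
    res$significant[res$asv == "A01"]
  }, TRUE)
  expect_gte(mean(detect), 0.9)

  # all-zero fold changes: nothing significant
  flat <- matrix(0, 10, 20, dimnames = list(NULL, sprintf("A%02d", 1:20)))
  expect_warning(res0 <- daa_test(list(W8 = flat), daa_config(contrasts = "W8")),
                 "zero-variance")
  expect_false(any(res0$significant))
  expect_true(all(res0$p == 1))

  # Holm within ASV across the two contrasts
  set.seed(44)
  fc2 <- matrix(rnorm(20 * 30, 0, 0.5), 20, 30,
                dimnames = list(NULL, sprintf("A%02d", 1:30)))
  res2 <- daa_test(list(W4 = fc2, W8 = fc2), daa_config())
  expect_true(all(res2$holm_p >= res2$p - 1e-12))
  expect_error(daa_test(list(W8 = fc2[1:3, ])), "at least 5")
})

test_that("fold changes are invariant to scaling a sample's counts", {
  set.seed(55)
  counts <- matrix(rpois(40 * 8, 50) + 1L, 40, 8,
                   dimnames = list(sprintf("A%02d", 1:40),
                                   paste0(rep(paste0("P", 1:4), each = 2),
                                          c("-W0", "-W8"))))
  fx <- paired_fixture(counts)
  cfg <- daa_config(contrasts = "W8", prevalence_min = 0)
  f1 <- bias_correct(paired_log2fc(fx$counts, fx$metadata, cfg)$fc$W8)
  scaled <- fx$counts
  scaled[, "P1-W8"] <- scaled[, "P1-W8"] * 10L
  f2 <- bias_correct(paired_log2fc(scaled, fx$metadata, cfg)$fc$W8)
  # exact up to the pseudocount perturbation, bounded by pc / count scale
  expect_lt(max(abs(f1 - f2)), 0.02)
})

test_that("permutation summary follows the k/N convention with zero-handling", {
  s <- summarize_permutation(27, c(rep(5L, 99), 30L))
  expect_equal(s$empirical_p, 0.01)
  expect_equal(summarize_permutation(3, rep(10L, 50))$empirical_p, 1)
  expect_equal(summarize_permutation(5, rep(0L, 100))$empirical_p, 0)

  cf <- c(A1 = 0, A2 = 0.04, A3 = 0.5)
  s2 <- summarize_permutation(10, rep(0L, 100), chance_freq = cf,
                              hr_asvs = names(cf))
  expect_equal(s2$chance$q_label[1], "< 0.01")
  expect_true(all(diff(s2$chance$q[order(s2$chance$chance_freq)]) >= -1e-12))
  expect_true(all(s2$chance$q >= pmax(s2$chance$chance_freq, 0.01) - 1e-12))
  expect_error(summarize_permutation(1, integer(0)), "at least one")
})

test_that("permutation robustness is seed-reproducible and flags planted effects", {
  coh <- generate_cohort(small_cohort_config(60, seed = 61))
  logs <- generate_training_logs(coh, training_sim_config(seed = 61))
  asv <- generate_asv_tables(coh, logs$true_gain,
                             microbiome_sim_config(n_asv = 120,
                                                   planted_up = 1:8,
                                                   planted_down = 9:14,
                                                   mean_depth = 20000,
                                                   seed = 61))
  gain <- stats::setNames(logs$true_gain, names(logs$true_gain))
  lab <- stratify(gain)
  hr <- names(lab$class)[lab$class == "HR"]
  pool <- names(lab$class)[lab$class != "HR"]
  r1 <- permutation_robustness(asv$counts, asv$metadata, hr, pool,
                               n_subsets = 20, seed = 7)
  r2 <- permutation_robustness(asv$counts, asv$metadata, hr, pool,
                               n_subsets = 20, seed = 7)
  expect_identical(r1$permuted_n_sig, r2$permuted_n_sig)
  expect_identical(r1$empirical_p, r2$empirical_p)
  expect_gt(r1$observed_n_sig, 0)
  expect_lte(r1$empirical_p, 0.05)

  expect_error(permutation_robustness(asv$counts, asv$metadata, hr,
                                      c(pool, hr[1])), "overlaps")
  expect_error(permutation_robustness(asv$counts, asv$metadata, hr,
                                      pool[1:3]), "smaller")
})
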