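test_that("cohort generation conserves the study flow and demographics", {
  coh <- generate_cohort(cohort_config(seed = 1))
  expect_equal(nrow(coh), 205)
  st <- table(coh$status)
  expect_equal(unname(st[["final"]]), 150)
  expect_equal(unname(st[["dropout"]]), 43)
  expect_equal(unname(st[["quality_excluded"]]), 6)
  expect_equal(unname(st[["validation_excluded"]]), 6)
  expect_equal(sum(st), 205) # conservation identity
  expect_true(all(coh$age >= 24 & coh$age <= 61))
  expect_true(all(coh$group %in% c("RRT", "MBRT")))

  # identity case: no exclusions
  coh10 <- generate_cohort(small_cohort_config(10))
  expect_equal(sum(coh10$status == "final"), 10)

  # determinism
  expect_identical(generate_cohort(cohort_config(seed = 33)),
                   generate_cohort(cohort_config(seed = 33)))

  expect_error(cohort_config(n_enrolled = 10, n_dropout = 20),
               "exceed")
  expect_error(cohort_config(n_dropout = -1), "nonnegative")
})

test_that("training logs follow the phase schedule, gains and dropout rules", {
  coh <- generate_cohort(cohort_config(n_enrolled = 30, n_dropout = 5,
                                       n_quality_excluded = 0,
                                       n_validation_excluded = 0, seed = 2))
  cfg <- training_sim_config(seed = 2)
  logs <- generate_training_logs(coh, cfg)

  # a phase-1 regular-program session targets 20 reps x 7 machines x 2 sets
  rrt <- coh$participant[coh$group == "RRT"][1]
  s <- logs$sessions[logs$sessions$participant == rrt, ]
  first_day <- s[s$date == min(s$date), ]
  expect_equal(nrow(first_day), 14)
  expect_equal(unique(first_day$program), "Regular")
  expect_equal(sum(first_day$reps_target), 280)

  # phase-2 weight fraction: negative program at 38% of current max
  wk3 <- s[s$date >= min(s$date) + 14 & s$date < min(s$date) + 28, ]
  expect_equal(unique(wk3$program), "Negative")
  expect_equal(wk3$weight / wk3$max_strength, rep(0.38, nrow(wk3)),
               tolerance = 0.01)

  # deterministic doubling: gain_sd = 0, gain_mean = 100
  cfg2 <- training_sim_config(gain_mean = 100, gain_sd = 0, seed = 3)
  logs2 <- generate_training_logs(coh, cfg2)
  f <- logs2$fitness
  for (id in coh$participant[coh$status == "final"][1:5]) {
    w0 <- f[f$participant == id & f$timepoint == "W0", "max_strength"]
    w8 <- f[f$participant == id & f$timepoint == "W8", "max_strength"]
    expect_equal(w8, 2 * w0, tolerance = 1e-9)
  }

  # dropouts train fewer than 8 weeks and only get a W0 test
  drop <- coh$participant[coh$status == "dropout"]
  for (id in drop) {
    sd_ <- logs$sessions[logs$sessions$participant == id, ]
    expect_lt(as.numeric(max(sd_$date) - min(sd_$date)), 7 * 8)
    expect_equal(unique(logs$fitness$timepoint[
      logs$fitness$participant == id]), "W0")
  }

  # cohort gain distribution honours the configured mean
  big <- generate_cohort(small_cohort_config(150, seed = 4))
  glogs <- generate_training_logs(big, training_sim_config(seed = 4))
  expect_lt(abs(mean(glogs$true_gain) - 24), 4)

  bad <- coh
  bad$group[1] <- "yoga"
  expect_error(generate_training_logs(bad, cfg), "unknown group")
})

test_that("ASV tables have calibrated depths, planted truth and dropout handling", {
  coh <- generate_cohort(cohort_config(n_enrolled = 110, n_dropout = 10,
                                       n_quality_excluded = 0,
                                       n_validation_excluded = 0, seed = 5))
  gain <- stats::setNames(rnorm(110, 24, 16), coh$participant)
  asv <- generate_asv_tables(coh, gain, microbiome_sim_config(seed = 5))
  expect_gte(ncol(asv$counts), 300) # >= 300 samples
  expect_true(all(asv$counts >= 0))
  expect_true(all(asv$counts == round(asv$counts)))
  # realized mean depth within 2% of the 69k target
  expect_lt(abs(mean(colSums(asv$counts)) / 69000 - 1), 0.02)

  # 16 + 11 planted ASVs recorded in the ground truth
  expect_length(asv$truth$planted_up, 16)
  expect_length(asv$truth$planted_down, 11)
  expect_length(intersect(asv$truth$planted_up, asv$truth$planted_down), 0)

  # dropouts contribute only W0 samples
  drop <- coh$participant[coh$status == "dropout"]
  md_drop <- asv$metadata[asv$metadata$participant %in% drop, ]
  expect_true(all(md_drop$timepoint == "W0"))

  # taxonomy covers every ASV with a SILVA-style lineage
  expect_equal(asv$taxonomy$asv, rownames(asv$counts))
  expect_true(all(grepl("^d__Bacteria;p__", asv$taxonomy$lineage)))

  expect_error(microbiome_sim_config(n_asv = 20, planted_up = 1:5,
                                     planted_down = 10:30),
               "outside")
  expect_error(microbiome_sim_config(planted_up = 1:5, planted_down = 3:8),
               "disjoint")
})

test_that("metabolite panel is a 34-compound within-participant null", {
  coh <- generate_cohort(small_cohort_config(30, seed = 6))
  met <- generate_metabolites(coh, seed = 6)
  expect_equal(ncol(met) - 2, 34)
  expect_setequal(unique(met$timepoint), c("W0", "W8"))
  expect_identical(met, generate_metabolites(coh, seed = 6))

  # paired W0/W8 tests reject at about the nominal rate
  compounds <- names(met)[-(1:2)]
  ps <- unlist(lapply(1:40, function(rep) {
    m <- generate_metabolites(coh, seed = 100 + rep)
    w0 <- m[m$timepoint == "W0", compounds]
    w8 <- m[m$timepoint == "W8", compounds]
    vapply(compounds, function(cc) {
      stats::t.test(log(w8[[cc]]) - log(w0[[cc]]))$p.value
    }, 0)
  }))
  fp <- mean(ps <= 0.05)
  expect_gt(fp, 0.02)
  expect_lt(fp, 0.09)
})

test_that("diet records are stable 12-variable profiles", {
  coh <- generate_cohort(small_cohort_config(20, seed = 7))
  diet <- generate_diet(coh, seed = 7)
  expect_equal(ncol(diet) - 2, 12)
  expect_equal(nrow(diet), 20 * 3)
  expect_identical(diet, generate_diet(coh, seed = 7))
  # drinks nonnegative, food frequencies on the 0-7 scale
  expect_true(all(diet$water_tea >= 0))
  expect_true(all(diet$fruit_vegetables >= 0 & diet$fruit_vegetables <= 7))
})
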