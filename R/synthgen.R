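# Synthetic study generator: cohort with realistic attrition, machine-level
# training logs following the two phase-scheduled programs, longitudinal ASV
# count tables with planted responder-linked effects, a null metabolite
# panel, and stable diet records. Everything is seeded and byte-reproducible
# so the full analysis pipeline can be exercised without access to the
# controlled human data it emulates.

MACHINES <- c("Leg press", "Leg curl", "Back trainer", "Abdominal trainer",
              "Chest press", "Seated row", "Lat pull")

# 2-week phases per program, per the published intervention protocol:
# regular resistance training alternates high-rep regular and eccentric-
# overload (negative) blocks; muscle-building runs negative, adaptive,
# isokinetic (2 x 8), adaptive. Percentages are of max strength
# (concentric / eccentric where they differ).
PHASE_SCHEDULE <- list(
  RRT = data.frame(
    phase = 1:4, program = c("Regular", "Negative", "Regular", "Negative"),
    reps = c(20L, 15L, 20L, 15L), pct_conc = c(45, 38, 45, 38),
    pct_ecc = c(45, 58, 45, 58), stringsAsFactors = FALSE),
  MBRT = data.frame(
    phase = 1:4, program = c("Negative", "Adaptive", "Isokinetic", "Adaptive"),
    reps = c(15L, 10L, 16L, 10L), pct_conc = c(38, 68, 73, 68),
    pct_ecc = c(58, 68, 105, 68), stringsAsFactors = FALSE)
)

#' Cohort configuration
#'
#' Defaults reproduce the study flow of the emulated intervention: 205
#' enrolled, 43 protocol dropouts, 6 excluded for data quality and 6 used
#' for workflow validation, leaving a 150-participant final cohort with the
#' published demographics (42.6% male; age 41.7 +/- 11.6 y on [24, 61];
#' BMI 24.5 +/- 3.5 kg/m^2).
#'
#' @param n_enrolled,n_dropout,n_quality_excluded,n_validation_excluded
#'   cohort-flow counts.
#' @param sex_fraction_male proportion of male participants.
#' @param age_mean,age_sd,age_range years (truncated normal).
#' @param bmi_mean,bmi_sd kg/m^2.
#' @param group_split probability of assignment to regular resistance
#'   training (RRT) vs muscle-building (MBRT).
#' @param seed integer seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_enrolled = 205, n_dropout = 43,
                          n_quality_excluded = 6, n_validation_excluded = 6,
                          sex_fraction_male = 0.426,
                          age_mean = 41.7, age_sd = 11.6,
                          age_range = c(24, 61),
                          bmi_mean = 24.5, bmi_sd = 3.5,
                          group_split = 0.5, seed = 1) {
  counts <- c(n_enrolled, n_dropout, n_quality_excluded, n_validation_excluded)
  if (any(counts < 0)) stop("cohort counts must be nonnegative")
  if (sum(counts[-1]) > n_enrolled) stop("exclusions exceed enrollment")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate the participant table
#'
#' Draws demographics and assigns exclusion flags at random: `status` is
#' `final`, `dropout`, `quality_excluded` or `validation_excluded`, with the
#' configured counts (conservation: the four groups partition enrollment).
#'
#' @param config a [cohort_config()].
#' @return data.frame with `participant`, `sex`, `age`, `bmi`, `height`,
#'   `body_weight`, `group`, `status`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  n <- config$n_enrolled
  with_seed(config$seed, {
    sex <- ifelse(stats::runif(n) < config$sex_fraction_male,
                  "male", "female")
    age <- rtruncnorm1(n, config$age_mean, config$age_sd,
                       config$age_range[1], config$age_range[2])
    bmi <- rtruncnorm1(n, config$bmi_mean, config$bmi_sd, 16.9, 34.2)
    height <- ifelse(sex == "male", stats::rnorm(n, 1.78, 0.07),
                     stats::rnorm(n, 1.66, 0.06))
    group <- ifelse(stats::runif(n) < config$group_split, "RRT", "MBRT")
    status <- rep("final", n)
    excl <- sample(n, config$n_dropout + config$n_quality_excluded +
                     config$n_validation_excluded)
    status[excl[seq_len(config$n_dropout)]] <- "dropout"
    status[excl[config$n_dropout + seq_len(config$n_quality_excluded)]] <-
      "quality_excluded"
    status[utils::tail(excl, config$n_validation_excluded)] <-
      "validation_excluded"
    data.frame(participant = sprintf("P%03d", seq_len(n)), sex = sex,
               age = round(age, 1), bmi = round(bmi, 1),
               height = round(height, 2),
               body_weight = round(bmi * height^2, 1),
               group = group, status = status, stringsAsFactors = FALSE)
  })
}

#' Training-log simulation configuration
#'
#' Defaults encode the published protocol and outcomes: 7 machines, 2 sets
#' each, 2-3 sessions/week for 8 weeks in four 2-week phases, cohort average
#' strength gain 24 +/- 16% and baseline leg press 154 +/- 54 kg. The
#' individual growth model (log-linear interpolation through a week-4
#' waypoint at 70% of the log gain) is generator plumbing, not an estimate.
#'
#' @param machines machine names (exactly 7).
#' @param sessions_per_week integer range sampled per week.
#' @param weeks program length.
#' @param phase_schedule per-group phase parameter tables.
#' @param gain_mean,gain_sd percent strength gain W0 to W8.
#' @param baseline_legpress_mean,baseline_legpress_sd kg.
#' @param baseline_gain_correlation Gaussian-copula correlation between
#'   baseline leg press and percent gain (negative: weaker participants gain
#'   more, the diminishing-returns pattern of resistance training).
#' @param w4_fraction fraction of the log2 gain realised by week 4.
#' @param compliance_prob per-repetition completion probability.
#' @param start_date first possible training date.
#' @param seed integer seed.
#' @return list of class `training_sim_config`.
#' @export
training_sim_config <- function(machines = MACHINES,
                                sessions_per_week = c(2L, 3L), weeks = 8,
                                phase_schedule = PHASE_SCHEDULE,
                                gain_mean = 24, gain_sd = 16,
                                baseline_legpress_mean = 154,
                                baseline_legpress_sd = 54,
                                baseline_gain_correlation = -0.4,
                                w4_fraction = 0.7, compliance_prob = 0.97,
                                start_date = as.Date("2022-06-01"),
                                seed = 1) {
  if (length(machines) != 7) stop("exactly 7 machines required")
  for (sch in phase_schedule) {
    if (nrow(sch) != 4) stop("4 phases of 2 weeks required")
    if (any(sch$pct_conc <= 0 | sch$pct_conc > 150) ||
        any(sch$pct_ecc <= 0 | sch$pct_ecc > 150)) {
      stop("phase percentages must lie in (0, 150]")
    }
  }
  structure(as.list(environment()), class = "training_sim_config")
}

# relative baseline strength of each machine vs leg press
MACHINE_FACTOR <- c(`Leg press` = 1, `Leg curl` = 0.35, `Back trainer` = 0.5,
                    `Abdominal trainer` = 0.4, `Chest press` = 0.45,
                    `Seated row` = 0.5, `Lat pull` = 0.55)

#' Generate session logs and fitness tests
#'
#' Every enrolled participant trains under their group's phase schedule
#' (2 sets x 7 machines per session). Each participant has a true percent
#' gain drawn from the configured distribution; within a participant all
#' machines share that gain exactly (machine heterogeneity enters only the
#' baseline levels), so with `gain_sd = 0` and `gain_mean = 100` every
#' machine exactly doubles. Dropouts train fewer than `weeks` weeks and get
#' a W0 fitness test only; everyone else is tested at W0, W4 and W8.
#'
#' @param participants table from [generate_cohort()].
#' @param config a [training_sim_config()].
#' @return list with `sessions` (one row per machine-set), `fitness`
#'   (participant, timepoint, machine, max_strength) and `true_gain`
#'   (named percent gains).
#' @export
generate_training_logs <- function(participants,
                                   config = training_sim_config()) {
  if (!all(participants$group %in% names(config$phase_schedule))) {
    stop("unknown group label")
  }
  with_seed(config$seed, {
    n <- nrow(participants)
    # Gaussian copula couples baseline strength and gain (negatively by
    # default); the quantile transform preserves both marginals exactly.
    rho <- config$baseline_gain_correlation
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    q_gain <- sort(rtruncnorm1(n, config$gain_mean, config$gain_sd, -50, Inf))
    q_leg <- sort(rtruncnorm1(n, config$baseline_legpress_mean,
                              config$baseline_legpress_sd, 40, Inf))
    gain <- q_gain[rank(z2, ties.method = "first")]
    legpress0 <- q_leg[rank(z1, ties.method = "first")]
    names(gain) <- names(legpress0) <- participants$participant
    mfac <- MACHINE_FACTOR[config$machines]
    sessions <- vector("list", n)
    fitness <- vector("list", n)
    for (i in seq_len(n)) {
      id <- participants$participant[i]
      sch <- config$phase_schedule[[participants$group[i]]]
      # baseline per machine; small level noise, shared gain
      base <- legpress0[i] * mfac * exp(stats::rnorm(7, 0, 0.08))
      base[1] <- legpress0[i] # leg press pinned to its drawn baseline
      lg <- log2(1 + gain[i] / 100)
      max_at <- function(week) { # log-linear growth through the W4 waypoint
        frac <- if (week <= 4) config$w4_fraction * week / 4 else
          config$w4_fraction + (1 - config$w4_fraction) * (week - 4) / 4
        base * 2^(frac * lg)
      }
      weeks_done <- if (participants$status[i] == "dropout") {
        sample(seq_len(config$weeks - 1), 1)
      } else config$weeks
      rows <- list()
      for (w in seq_len(weeks_done)) {
        ph <- sch[ceiling(w / 2), ]
        k <- sample(seq(config$sessions_per_week[1],
                        config$sessions_per_week[2]), 1)
        days <- sort(sample(0:6, k))
        cur <- max_at(w - 0.5)
        for (d in days) {
          reps_t <- rep(ph$reps, 14L)
          rows[[length(rows) + 1]] <- data.frame(
            participant = id,
            date = config$start_date + (w - 1) * 7 + d,
            machine = rep(config$machines, each = 2),
            program = ph$program,
            weight = round(rep(cur, each = 2) * ph$pct_conc / 100, 1),
            reps_target = reps_t,
            reps_done = stats::rbinom(14L, reps_t, config$compliance_prob),
            max_strength = round(rep(cur, each = 2), 1),
            stringsAsFactors = FALSE)
        }
      }
      sessions[[i]] <- do.call(rbind, rows)
      tps <- if (participants$status[i] == "dropout") "W0" else
        c("W0", "W4", "W8")
      wk <- c(W0 = 0, W4 = 4, W8 = 8)[tps]
      fitness[[i]] <- data.frame(
        participant = id, timepoint = rep(tps, each = 7),
        machine = rep(config$machines, length(tps)),
        max_strength = as.numeric(vapply(wk, max_at, numeric(7))),
        stringsAsFactors = FALSE)
    }
    list(sessions = do.call(rbind, sessions),
         fitness = do.call(rbind, fitness), true_gain = gain)
  })
}

#' Microbiome simulation configuration
#'
#' Hierarchical log-normal composition model: per-ASV baseline log
#' abundances, participant random intercepts giving the within-subject
#' correlation, per-sample noise, softmax to a composition and multinomial
#' reads at negative-binomial depths around `mean_depth` (default 69,000
#' reads/sample). Planted ASVs (16 up, 11 down by default) shift at W4
#' (partial effect) and W8 (full effect), with per-participant magnitude
#' `effect * coupling_strength * gain percentile`, which links community
#' change to strength response.
#'
#' @param n_asv number of ASVs.
#' @param mean_depth mean reads per sample.
#' @param depth_dispersion negative-binomial size parameter of the depths.
#' @param baseline_log_abundance_sd sd of per-ASV baseline log abundances
#'   (natural log).
#' @param within_subject_correlation intraclass correlation of log
#'   abundances within a participant.
#' @param sample_noise_sd per-sample log-abundance noise sd (natural log).
#' @param planted_up,planted_down indices (1..n_asv) of planted ASVs.
#' @param effect_log2fc_w4,effect_log2fc_w8 planted effect sizes in log2
#'   units at W4 and W8 (before coupling scaling).
#' @param coupling_strength multiplier linking a participant's gain
#'   percentile to the magnitude of their planted shift (0 = no link).
#' @param seed integer seed.
#' @return list of class `microbiome_sim_config`.
#' @export
microbiome_sim_config <- function(n_asv = 300, mean_depth = 69000,
                                  depth_dispersion = 100,
                                  baseline_log_abundance_sd = 1.5,
                                  within_subject_correlation = 0.7,
                                  sample_noise_sd = 0.45,
                                  planted_up = 1:16, planted_down = 17:27,
                                  effect_log2fc_w4 = 1.0,
                                  effect_log2fc_w8 = 2.0,
                                  coupling_strength = 1.0, seed = 1) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (length(intersect(planted_up, planted_down))) {
    stop("planted sets must be disjoint")
  }
  if (any(c(planted_up, planted_down) < 1) ||
      any(c(planted_up, planted_down) > n_asv)) {
    stop("planted ASV ids outside 1..n_asv")
  }
  if (!all(is.finite(c(effect_log2fc_w4, effect_log2fc_w8,
                       coupling_strength)))) {
    stop("effect sizes must be finite")
  }
  structure(as.list(environment()), class = "microbiome_sim_config")
}

# small pool of plausible SILVA-style lineages for the mock taxonomy
mock_lineages <- function(n_asv, seed) {
  fams <- list(
    c("Firmicutes", "Clostridia", "Lachnospirales", "Lachnospiraceae",
      c("Roseburia", "Agathobacter", "Lachnoclostridium", "Blautia",
        "Coprococcus")),
    c("Firmicutes", "Clostridia", "Oscillospirales", "Ruminococcaceae",
      c("Faecalibacterium", "Ruminococcus", "Subdoligranulum")),
    c("Firmicutes", "Clostridia", "Oscillospirales", "Oscillospiraceae",
      c("NK4A214_group", "UCG-002")),
    c("Bacteroidota", "Bacteroidia", "Bacteroidales", "Bacteroidaceae",
      c("Bacteroides")),
    c("Bacteroidota", "Bacteroidia", "Bacteroidales", "Prevotellaceae",
      c("Prevotella", "Paraprevotella")),
    c("Actinobacteriota", "Actinobacteria", "Bifidobacteriales",
      "Bifidobacteriaceae", c("Bifidobacterium")),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Butyricicoccaceae",
      c("Butyricicoccus")),
    c("Verrucomicrobiota", "Verrucomicrobiae", "Verrucomicrobiales",
      "Akkermansiaceae", c("Akkermansia")))
  with_seed(seed, {
    vapply(seq_len(n_asv), function(i) {
      f <- fams[[sample(length(fams), 1)]]
      genus <- sample(f[[5]], 1)
      paste0("d__Bacteria;p__", f[1], ";c__", f[2], ";o__", f[3],
             ";f__", f[4], ";g__", genus)
    }, "")
  })
}

#' Generate longitudinal ASV count tables
#'
#' Three stool samples per completing participant (W0, W4, W8; dropouts get
#' W0 only), drawn from the hierarchical composition model of
#' [microbiome_sim_config()]. Returns the ground truth (planted ASVs,
#' per-participant effect multipliers) alongside, so recovery can be tested
#' without leaking it into analysis inputs.
#'
#' @param participants table from [generate_cohort()].
#' @param responder_scores named numeric, participant -> strength gain used
#'   for the coupling (e.g. `true_gain` from [generate_training_logs()]).
#' @param config a [microbiome_sim_config()].
#' @return list with `counts` (ASV x sample integer matrix), `metadata`
#'   (sample-id, participant, timepoint, group), `taxonomy` (asv, lineage)
#'   and `truth` (planted ids, per-participant gain percentile and effect
#'   multiplier).
#' @export
generate_asv_tables <- function(participants, responder_scores,
                                config = microbiome_sim_config()) {
  J <- config$n_asv
  asv_ids <- sprintf("ASV_%04d", seq_len(J))
  rho <- config$within_subject_correlation
  subj_sd <- config$sample_noise_sd * sqrt(rho / (1 - rho))
  pct <- rep(0.5, nrow(participants))
  names(pct) <- participants$participant
  sc <- responder_scores[names(responder_scores) %in% names(pct)]
  pct[names(sc)] <- rank(sc) / (length(sc) + 1)
  eff <- numeric(J)
  eff[config$planted_up] <- 1
  eff[config$planted_down] <- -1
  with_seed(config$seed, {
    a <- stats::rnorm(J, 0, config$baseline_log_abundance_sd)
    # planted ASVs span the mid-to-upper abundance range (the differential
    # taxa being emulated include abundant SCFA producers), so the planted
    # community mass is stable across seeds instead of occasionally all-rare
    spread <- function(k) {
      stats::qnorm(seq(0.30, 0.95, length.out = k)) *
        config$baseline_log_abundance_sd
    }
    if (length(config$planted_up)) {
      a[config$planted_up] <- spread(length(config$planted_up))
    }
    if (length(config$planted_down)) {
      a[config$planted_down] <- spread(length(config$planted_down))
    }
    cols <- list(); meta <- list()
    for (i in seq_len(nrow(participants))) {
      id <- participants$participant[i]
      u <- stats::rnorm(J, 0, subj_sd)
      tps <- if (participants$status[i] == "dropout") "W0" else
        c("W0", "W4", "W8")
      for (tp in tps) {
        delta <- switch(tp, W0 = 0, W4 = config$effect_log2fc_w4,
                        W8 = config$effect_log2fc_w8)
        l <- a + u + stats::rnorm(J, 0, config$sample_noise_sd) +
          log(2) * eff * delta * config$coupling_strength * pct[id]
        p <- exp(l - max(l))
        p <- p / sum(p)
        depth <- stats::rnbinom(1, size = config$depth_dispersion,
                                mu = config$mean_depth)
        depth <- max(depth, 1000L)
        cols[[length(cols) + 1]] <- as.integer(stats::rmultinom(1, depth, p))
        meta[[length(meta) + 1]] <- data.frame(
          `sample-id` = paste0(id, "-", tp), participant = id,
          timepoint = tp, group = participants$group[i],
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
    metadata <- do.call(rbind, meta)
    counts <- do.call(cbind, cols)
    dimnames(counts) <- list(asv_ids, metadata$`sample-id`)
    list(counts = counts, metadata = metadata,
         taxonomy = data.frame(asv = asv_ids,
                               lineage = mock_lineages(J, config$seed + 1),
                               stringsAsFactors = FALSE),
         truth = list(planted_up = asv_ids[config$planted_up],
                      planted_down = asv_ids[config$planted_down],
                      gain_percentile = as.list(round(pct, 4)),
                      effect_log2fc_w4 = config$effect_log2fc_w4,
                      effect_log2fc_w8 = config$effect_log2fc_w8,
                      coupling_strength = config$coupling_strength))
  })
}

# the 34-compound targeted panel: SCFAs, amino acids, bile acid derivates,
# choline/indole/phenolic derivates, polyamines, vitamins (synthetic names)
METABOLITE_PANEL <- c(
  "acetate", "propionate", "butyrate", "valerate", "isobutyrate",
  "isovalerate", "lactate", "succinate",
  "alanine", "glycine", "leucine", "isoleucine", "valine", "glutamate",
  "glutamine", "tryptophan", "tyrosine", "phenylalanine",
  "cholate", "deoxycholate", "lithocholate", "ursodeoxycholate",
  "choline", "betaine", "trimethylamine",
  "indole", "indole-3-acetate", "indole-3-propionate",
  "p-cresol", "hippurate",
  "putrescine", "spermidine",
  "riboflavin", "nicotinate")

#' Generate the targeted metabolite panel (null by construction)
#'
#' Log-normal concentrations for 34 compounds at W0 and W8 with participant
#' level but no time effect, mirroring an intervention that leaves the stool
#' metabolome unchanged.
#'
#' @param participants table from [generate_cohort()]; only completing
#'   participants are sampled.
#' @param seed integer seed.
#' @return data.frame with `participant`, `timepoint` and 34 compound
#'   columns.
#' @export
generate_metabolites <- function(participants, seed = 1) {
  ids <- participants$participant[participants$status != "dropout"]
  with_seed(seed, {
    base_mu <- stats::rnorm(34, 3, 1)
    rows <- lapply(ids, function(id) {
      u <- stats::rnorm(34, 0, 0.4)
      vals <- lapply(c("W0", "W8"), function(tp) {
        conc <- exp(base_mu + u + stats::rnorm(34, 0, 0.3))
        df <- data.frame(participant = id, timepoint = tp,
                         stringsAsFactors = FALSE)
        df[METABOLITE_PANEL] <- as.list(round(conc, 3))
        df
      })
      do.call(rbind, vals)
    })
    do.call(rbind, rows)
  })
}

DIET_VARS <- c(food = 8, drink = 4)
FOOD_VARS <- c("fruit_vegetables", "fish", "meat", "eggs", "dairy",
               "grains", "sweets", "salty_snacks")
DRINK_VARS <- c("water_tea", "coffee", "juice_lemonade", "alcohol")

#' Generate stable diet records
#'
#' Eight food frequencies (ordinal 0-7 occasions/week) and four drink
#' volumes (ml/day) per participant and timepoint: a stable per-participant
#' profile plus small noise (`noise_sd = 0` gives identical records across
#' timepoints, i.e. zero within-participant diet distance).
#'
#' @param participants table from [generate_cohort()].
#' @param seed integer seed.
#' @param noise_sd sd of the per-timepoint wobble, in food-frequency units
#'   (drinks are perturbed proportionally).
#' @return data.frame with `participant`, `timepoint` and the 12 variables.
#' @export
generate_diet <- function(participants, seed = 1, noise_sd = 0.5) {
  ids <- participants$participant[participants$status != "dropout"]
  food_mean <- c(5, 1.5, 3, 2, 4, 5, 3, 2)
  drink_mean <- c(1500, 300, 200, 100)
  with_seed(seed, {
    rows <- lapply(ids, function(id) {
      food_base <- pmin(pmax(stats::rnorm(8, food_mean, 1.5), 0), 7)
      drink_base <- drink_mean * exp(stats::rnorm(4, 0, 0.4))
      vals <- lapply(c("W0", "W4", "W8"), function(tp) {
        food <- pmin(pmax(food_base + stats::rnorm(8, 0, noise_sd), 0), 7)
        drink <- drink_base *
          exp(stats::rnorm(4, 0, noise_sd * 0.16))
        df <- data.frame(participant = id, timepoint = tp,
                         stringsAsFactors = FALSE)
        df[FOOD_VARS] <- as.list(round(food, 2))
        df[DRINK_VARS] <- as.list(round(drink, 1))
        df
      })
      do.call(rbind, vals)
    })
    do.call(rbind, rows)
  })
}
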