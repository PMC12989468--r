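# End-to-end orchestration: simulate -> strength -> responders -> diversity
# -> coupling -> DAA -> permutation -> diet -> prediction -> report, driven
# by one config and one global seed (per-stage seeds derived by name so each
# stage is reproducible in isolation).

#' Full study configuration
#'
#' @param cohort [cohort_config()].
#' @param training [training_sim_config()].
#' @param microbiome [microbiome_sim_config()].
#' @param daa [daa_config()].
#' @param n_subsets permutation subsets for the robustness procedure.
#' @param rarefaction_depth fixed depth, or NULL for 90% of the minimum
#'   sample depth.
#' @param diet_noise_sd diet wobble passed to [generate_diet()].
#' @param n_perm_predict label permutations for the prediction benchmark.
#' @param predict_ntree Random Forest size for the prediction benchmark.
#' @param seed global seed; stage seeds derive from it via [derive_seed()].
#' @param stages character vector of enabled stages (dependency order is
#'   enforced at run time).
#' @return nested list of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         training = training_sim_config(),
                         microbiome = microbiome_sim_config(),
                         daa = daa_config(),
                         n_subsets = 100, rarefaction_depth = NULL,
                         diet_noise_sd = 0.5,
                         n_perm_predict = 200, predict_ntree = 200,
                         seed = 1,
                         stages = c("simulate", "strength", "responders",
                                    "diversity", "coupling", "daa",
                                    "permtest", "diet", "predict")) {
  cohort$seed <- derive_seed(seed, "cohort")
  training$seed <- derive_seed(seed, "training")
  microbiome$seed <- derive_seed(seed, "microbiome")
  structure(as.list(environment()), class = "study_config")
}

#' Write the synthetic study to disk
#'
#' Generates all tables and writes `counts.tsv` (ASV x sample),
#' `taxonomy.tsv`, `metadata.tsv` (QIIME2 sample-metadata dialect),
#' `sessions.tsv`, `fitness.tsv`, `diet.tsv`, `metabolites.tsv` and the
#' ground-truth sidecar `truth.json`.
#'
#' @param config [study_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) the list of generated objects.
#' @export
simulate_study <- function(config = study_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$cohort)
  logs <- generate_training_logs(cohort, config$training)
  asv <- generate_asv_tables(cohort, logs$true_gain, config$microbiome)
  metab <- generate_metabolites(cohort, derive_seed(config$seed, "metabolites"))
  diet <- generate_diet(cohort, derive_seed(config$seed, "diet"),
                        noise_sd = config$diet_noise_sd)
  hdr <- c(tool = "gymbiome", seed = config$seed)
  write_gym_tsv(cohort, file.path(out_dir, "participants.tsv"), hdr)
  write_gym_tsv(logs$sessions, file.path(out_dir, "sessions.tsv"), hdr)
  write_gym_tsv(logs$fitness, file.path(out_dir, "fitness.tsv"), hdr)
  cnt <- data.frame(asv = rownames(asv$counts), asv$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_gym_tsv(cnt, file.path(out_dir, "counts.tsv"), hdr)
  write_gym_tsv(asv$taxonomy, file.path(out_dir, "taxonomy.tsv"), hdr)
  # QIIME2 sample-metadata dialect: no comment header, 'sample-id' column
  write_gym_tsv(asv$metadata, file.path(out_dir, "metadata.tsv"))
  write_gym_tsv(metab, file.path(out_dir, "metabolites.tsv"), hdr)
  write_gym_tsv(diet, file.path(out_dir, "diet.tsv"), hdr)
  truth <- c(asv$truth, list(true_gain = as.list(round(logs$true_gain, 4))))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, logs = logs, asv = asv,
                 metabolites = metab, diet = diet))
}

#' Correlation of within-subject community change with strength gain
#'
#' Joins the within-participant Bray-Curtis distances (default pair W0-W8)
#' with the average strength gain, computes the Pearson correlation, and
#' additionally tests the distances across responder classes with
#' Kruskal-Wallis + Dunn.
#'
#' @param beta_within data.frame from [within_subject_distances()].
#' @param strength data.frame with `participant` and `avg_log2fc_W0W8`.
#' @param labels optional [stratify()] result for the class-stratified test.
#' @param pair which timepoint pair to analyse.
#' @return list with `r`, `p`, `n` and (with labels) `by_class`.
#' @export
run_coupling <- function(beta_within, strength, labels = NULL,
                         pair = "W0-W8") {
  bw <- beta_within[beta_within$pair == pair, ]
  m <- merge(bw, strength[, c("participant", "avg_log2fc_W0W8")],
             by = "participant")
  if (nrow(m) < 3) stop("fewer than 3 matched participants")
  pr <- pearson_r(m$distance, m$avg_log2fc_W0W8)
  out <- list(r = pr$r, p = pr$p, n = pr$n, pair = pair)
  if (!is.null(labels)) {
    cls <- as.character(labels$class[m$participant])
    out$by_class <- kruskal_dunn(m$distance, cls)
  }
  out
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic study,
#' writing all tables, a JSON results bundle and a plain-markdown report to
#' `out_dir`. Disabling a stage skips it and its dependents with a message.
#'
#' @param config [study_config()].
#' @param out_dir output directory.
#' @return (invisibly) the results list.
#' @export
run_all <- function(config = study_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  res <- list(seed = config$seed)
  need <- function(stage, deps) {
    if (!stage %in% stages) return(FALSE)
    miss <- setdiff(deps, stages)
    ok <- all(vapply(deps, function(d) !is.null(res[[d]]), TRUE))
    if (length(miss) || !ok) {
      message("skipping stage '", stage, "': requires ",
              paste(deps, collapse = ", "))
      return(FALSE)
    }
    TRUE
  }
  hdr <- c(tool = "gymbiome", seed = config$seed)

  if ("simulate" %in% stages) {
    res$simulate <- simulate_study(config, out_dir)
  }
  if (need("strength", "simulate")) {
    sim <- res$simulate
    final <- sim$cohort[sim$cohort$status == "final", ]
    sm <- strength_metrics_table(sim$logs$sessions, sim$logs$fitness,
                                 participants = sim$cohort)
    sm <- sm[sm$participant %in% final$participant, ]
    write_gym_tsv(sm, file.path(out_dir, "strength_metrics.tsv"), hdr)
    res$strength <- sm
  }
  if (need("responders", "strength")) {
    sm <- res$strength
    lab <- list(
      legpress = stratify(stats::setNames(log2(sm$legpress_W8 / sm$legpress_W0),
                                          sm$participant)),
      avg_gain = stratify(stats::setNames(sm$avg_log2fc_W0W8, sm$participant)),
      bioage = stratify(stats::setNames(sm$bioage_W8 - sm$bioage_W0,
                                        sm$participant), direction = "lower"))
    pool <- non_hr_pool(lab)
    rtab <- data.frame(participant = sm$participant,
                       legpress = as.character(lab$legpress$class),
                       avg_gain = as.character(lab$avg_gain$class),
                       bioage = as.character(lab$bioage$class),
                       non_hr_pool = sm$participant %in% pool,
                       stringsAsFactors = FALSE)
    write_gym_tsv(rtab, file.path(out_dir, "responders.tsv"), hdr)
    res$responders <- list(labels = lab, pool = pool, table = rtab)
  }
  if (need("diversity", "simulate")) {
    counts <- res$simulate$asv$counts
    md <- res$simulate$asv$metadata
    rar <- rarefy_counts(counts, depth = config$rarefaction_depth,
                         seed = derive_seed(config$seed, "rarefaction"))
    alpha <- alpha_diversity(rar$counts)
    bw <- within_subject_distances(rar$counts, md)
    write_gym_tsv(alpha, file.path(out_dir, "alpha.tsv"),
                  c(hdr, shannon_units = "natural log",
                    rarefaction_depth = rar$depth))
    write_gym_tsv(bw, file.path(out_dir, "beta_within.tsv"), hdr)
    res$diversity <- list(rarefied = rar, alpha = alpha, beta_within = bw)
  }
  if (need("coupling", c("diversity", "strength", "responders"))) {
    res$coupling <- run_coupling(res$diversity$beta_within, res$strength,
                                 labels = res$responders$labels$avg_gain)
  }
  if (need("daa", c("simulate", "responders"))) {
    lab <- res$responders$labels$avg_gain
    hr <- names(lab$class)[lab$class == "HR"]
    res$daa <- run_daa(res$simulate$asv$counts, res$simulate$asv$metadata,
                       participants = hr, config = config$daa)
    write_gym_tsv(res$daa, file.path(out_dir, "daa_results.tsv"), hdr)
    res$hr_ids <- hr
  }
  if (need("permtest", c("daa", "responders"))) {
    ps <- permutation_robustness(
      res$simulate$asv$counts, res$simulate$asv$metadata,
      hr_ids = res$hr_ids, pool_ids = res$responders$pool,
      n_subsets = config$n_subsets,
      seed = derive_seed(config$seed, "permtest"), config = config$daa)
    jsonlite::write_json(
      ps[c("observed_n_sig", "permuted_n_sig", "n_subsets", "empirical_p")],
      file.path(out_dir, "permutation_summary.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    if (!is.null(ps$chance)) {
      tax <- res$simulate$asv$taxonomy
      f4 <- merge(ps$chance, tax, by = "asv")
      write_gym_tsv(f4, file.path(out_dir, "fig_table.tsv"), hdr)
    }
    res$permtest <- ps
  }
  if (need("diet", c("simulate", "responders"))) {
    diet <- res$simulate$diet
    final_ids <- res$strength$participant
    diet <- diet[diet$participant %in% final_ids, ]
    dd <- diet_distances(diet[, c(FOOD_VARS, DRINK_VARS)])
    sam <- sammon_map(dd)
    coords <- data.frame(participant = diet$participant,
                         timepoint = diet$timepoint,
                         x = sam$coordinates[, 1], y = sam$coordinates[, 2],
                         stringsAsFactors = FALSE)
    write_gym_tsv(coords, file.path(out_dir, "diet_coords.tsv"),
                  c(hdr, stress = format(sam$stress, digits = 6)))
    shifts <- diet_shift_by_responder(diet, res$responders$labels$avg_gain)
    write_gym_tsv(shifts$tests, file.path(out_dir, "diet_shift_tests.tsv"),
                  hdr)
    res$diet <- list(sammon = sam, shifts = shifts)
  }
  if (need("predict", c("strength", "responders"))) {
    lab <- res$responders$labels$avg_gain
    keep <- lab$class %in% c("HR", "LR")
    ids <- names(lab$class)[keep]
    feats <- cbind(
      res$strength[match(ids, res$strength$participant),
                   c("legpress_W0", "bioage_W0")],
      res$simulate$cohort[match(ids, res$simulate$cohort$participant),
                          c("age", "bmi")])
    pr <- predict_responders(feats, lab$class[keep],
                             n_perm = config$n_perm_predict,
                             seed = derive_seed(config$seed, "predict"),
                             ntree = config$predict_ntree)
    jsonlite::write_json(
      list(auc = pr$auc, permutation_p = pr$permutation_p,
           n_perm = pr$n_perm,
           feature_importances = as.list(pr$feature_importances)),
      file.path(out_dir, "prediction.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    res$predict <- pr
  }
  write_report(res, config, out_dir)
  invisible(res)
}

write_report <- function(res, config, out_dir) {
  L <- c("# gymbiome pipeline report", "",
         paste0("seed: ", config$seed), "")
  bundle <- list(seed = config$seed)
  if (!is.null(res$simulate)) {
    st <- table(res$simulate$cohort$status)
    L <- c(L, "## Cohort flow",
           paste0("enrolled: ", nrow(res$simulate$cohort)),
           paste0("final: ", st[["final"]],
                  ", dropout: ", st[["dropout"]],
                  ", quality excluded: ", st[["quality_excluded"]],
                  ", validation excluded: ", st[["validation_excluded"]]), "")
    bundle$cohort <- as.list(st)
  }
  if (!is.null(res$strength)) {
    mg <- mean(res$strength$percent_gain)
    L <- c(L, "## Strength",
           paste0("mean percent gain W0-W8: ", round(mg, 1), "%"),
           paste0("mean leg press W0: ",
                  round(mean(res$strength$legpress_W0), 1), " kg"), "")
    bundle$mean_percent_gain <- mg
  }
  if (!is.null(res$coupling)) {
    L <- c(L, "## Community-strength coupling",
           paste0("Pearson r = ", round(res$coupling$r, 3),
                  ", p = ", signif(res$coupling$p, 3),
                  " (n = ", res$coupling$n, ")"), "")
    bundle$coupling <- res$coupling[c("r", "p", "n")]
  }
  if (!is.null(res$permtest)) {
    L <- c(L, "## Differential abundance robustness",
           paste0("observed significant results (HR): ",
                  res$permtest$observed_n_sig),
           paste0("empirical p vs ", res$permtest$n_subsets,
                  " random non-HR subsets: ", res$permtest$empirical_p), "")
    bundle$permutation <- res$permtest[c("observed_n_sig", "empirical_p")]
  }
  if (!is.null(res$diet)) {
    L <- c(L, "## Diet stability",
           paste0("Sammon stress: ",
                  format(res$diet$sammon$stress, digits = 4)), "")
    bundle$sammon_stress <- res$diet$sammon$stress
  }
  if (!is.null(res$predict)) {
    L <- c(L, "## Responder prediction",
           paste0("cross-validated AUC: ", round(res$predict$auc, 3),
                  ", permutation p: ",
                  signif(res$predict$permutation_p, 3)), "")
    bundle$prediction <- res$predict[c("auc", "permutation_p")]
  }
  con <- file(file.path(out_dir, "report.md"), "wb")
  writeLines(L, con, sep = "\n")
  close(con)
  jsonlite::write_json(bundle, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Digest of a results bundle
#'
#' MD5 of every regular file in a pipeline output directory, plus an overall
#' digest; used to verify byte-identical reproduction under a fixed seed.
#'
#' @param out_dir pipeline output directory.
#' @return named character vector of per-file MD5s with an attribute
#'   `overall`.
#' @export
bundle_digest <- function(out_dir) {
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  md5 <- tools::md5sum(files)
  names(md5) <- basename(files)
  attr(md5, "overall") <- unname(tools::md5sum(
    {
      tmp <- tempfile()
      writeLines(paste(names(md5), md5), tmp)
      tmp
    }))
  md5
}
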