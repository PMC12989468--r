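# Paired, bias-corrected differential abundance over timepoint contrasts
# (W4 vs W0, W8 vs W0), and the permutation-subset robustness procedure that
# calibrates the number of discoveries against random non-high-responder
# subsets.
#
# Within-participant log2 fold changes of relative abundance replace a
# random-effects fit: for complete pairs the paired difference IS the exact
# within-participant contrast. The median-centring step removes any shift
# common to all ASVs of a participant-contrast (a compositional / sampling
# fraction artifact), in the spirit of sampling-fraction bias correction.

#' Configuration for the differential-abundance analysis
#'
#' @param pseudocount added to counts before log-ratio (half-count default).
#' @param prevalence_min minimum fraction of analysed samples in which an ASV
#'   must be nonzero to be tested.
#' @param lfc_threshold absolute mean log2 fold change required to call
#'   significance (1 = two-fold).
#' @param p_threshold Holm-adjusted p-value threshold.
#' @param contrasts follow-up timepoints contrasted against W0.
#' @return list of class `daa_config`.
#' @export
daa_config <- function(pseudocount = 0.5, prevalence_min = 0.25,
                       lfc_threshold = 1.0, p_threshold = 0.05,
                       contrasts = c("W4", "W8")) {
  stopifnot(pseudocount > 0, lfc_threshold > 0, p_threshold > 0,
            !"W0" %in% contrasts)
  structure(list(pseudocount = pseudocount, prevalence_min = prevalence_min,
                 lfc_threshold = lfc_threshold, p_threshold = p_threshold,
                 contrasts = contrasts), class = "daa_config")
}

#' Within-participant log2 fold changes of relative abundance
#'
#' For every participant with a W0 sample and at least one follow-up sample,
#' and every ASV passing the prevalence filter, computes
#' `log2((count_t + pc) / depth_t) - log2((count_W0 + pc) / depth_W0)`
#' where depth is the sample's raw total. Participants without a W0 sample
#' are skipped and reported.
#'
#' @param counts ASV x sample count matrix.
#' @param metadata sample metadata (`sample-id`/`sample`, `participant`,
#'   `timepoint`).
#' @param config [daa_config()].
#' @param participants optional subset of participant ids to analyse.
#' @return list with `fc` (list per contrast: participant x ASV matrix of
#'   log2FCs), `asvs` (tested ASV ids), `skipped` (participants lacking W0).
#' @export
paired_log2fc <- function(counts, metadata, config = daa_config(),
                          participants = NULL) {
  md <- normalize_metadata(metadata)
  if (!is.null(participants)) md <- md[md$participant %in% participants, ]
  md <- md[md$sample %in% colnames(counts), ]
  counts <- as.matrix(counts)[, md$sample, drop = FALSE]
  prev <- rowMeans(counts > 0)
  asvs <- rownames(counts)[prev >= config$prevalence_min]
  depth <- colSums(counts)
  logrel <- log2(sweep(counts[asvs, , drop = FALSE] + config$pseudocount,
                       2, depth, "/"))
  bytp <- split(md$sample, md$timepoint)
  pid_of <- stats::setNames(md$participant, md$sample)
  base <- bytp$W0
  if (is.null(base)) stop("no W0 samples in the analysed subset")
  skipped <- setdiff(unique(md$participant), pid_of[base])
  fc <- lapply(config$contrasts, function(tp) {
    fol <- bytp[[tp]]
    pid_fol <- pid_of[fol]
    pid_base <- pid_of[base]
    common <- intersect(pid_fol, pid_base)
    m <- t(logrel[, fol[match(common, pid_fol)], drop = FALSE] -
             logrel[, base[match(common, pid_base)], drop = FALSE])
    rownames(m) <- common
    m
  })
  names(fc) <- config$contrasts
  list(fc = fc, asvs = asvs, skipped = skipped)
}

#' Remove per-participant compositional shifts from a fold-change matrix
#'
#' Subtracts from each participant-contrast vector its median across ASVs,
#' so a shift common to all ASVs (depth / sampling-fraction artifact) is
#' removed while isolated true effects survive.
#'
#' @param fc participant x ASV matrix of log2 fold changes (>= 10 ASVs).
#' @return centred matrix with zero row medians.
#' @export
bias_correct <- function(fc) {
  fc <- as.matrix(fc)
  if (ncol(fc) < 10) stop("need at least 10 ASVs for median centring")
  sweep(fc, 1, apply(fc, 1, stats::median))
}

#' Differential-abundance test on centred fold changes
#'
#' Per ASV and contrast, a one-sample t-test of the centred within-
#' participant log2 fold changes against zero; Holm adjustment across the
#' contrasts within each ASV (the many-to-one, Dunnett-type family); an ASV
#' is significant in a contrast when the Holm p-value is at or below
#' `p_threshold` and the absolute mean log2FC is at least `lfc_threshold`.
#' Zero-variance ASVs get p = 1 with a warning.
#'
#' @param fc_list list per contrast of centred participant x ASV matrices
#'   (as from [paired_log2fc()] + [bias_correct()]).
#' @param config [daa_config()].
#' @return data.frame with `asv`, `contrast`, `mean_log2fc`, `p`, `holm_p`,
#'   `significant`.
#' @export
daa_test <- function(fc_list, config = daa_config()) {
  stopifnot(is.list(fc_list), length(fc_list) >= 1)
  res <- lapply(names(fc_list), function(tp) {
    m <- fc_list[[tp]]
    n <- nrow(m)
    if (n < 5) stop("need at least 5 participants per contrast")
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    tstat <- mu / (sdv / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), n - 1)
    if (any(sdv == 0)) {
      warning(sum(sdv == 0), " zero-variance ASVs set to p = 1")
      p[sdv == 0] <- 1
    }
    data.frame(asv = colnames(m), contrast = tp, mean_log2fc = mu,
               p = p, n = n, stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, res)
  res$holm_p <- stats::ave(res$p, res$asv, FUN = holm_adjust)
  res$significant <- res$holm_p <= config$p_threshold &
    abs(res$mean_log2fc) >= config$lfc_threshold
  res$n <- NULL
  res
}

# one full DAA pass on a participant subset; returns the result table
daa_subset <- function(counts, metadata, ids, config) {
  fc <- paired_log2fc(counts, metadata, config, participants = ids)
  daa_test(lapply(fc$fc, bias_correct), config)
}

#' Run the full paired DAA on a participant subset
#'
#' Convenience wrapper: prevalence filter, paired log2 fold changes, bias
#' correction, per-contrast tests.
#'
#' @inheritParams paired_log2fc
#' @param participants participant ids to analyse (default: all).
#' @return a [daa_test()] result data.frame.
#' @export
run_daa <- function(counts, metadata, participants = NULL,
                    config = daa_config()) {
  daa_subset(counts, metadata, participants, config)
}

#' Summarise observed vs permuted discovery counts
#'
#' The counting convention behind the robustness procedure: the empirical
#' p-value is the plain fraction `#{permuted >= observed} / n_subsets`
#' (no add-one), so 99 of 100 permuted subsets falling below the observed
#' count gives p = 0.01. Per-ASV chance frequencies of 0 are floored at
#' `1 / n_subsets` for the BH q-values and labelled `"< 1/n"` in the report.
#'
#' @param observed_n_sig observed count of significant ASV-contrast results.
#' @param permuted_n_sig integer vector of counts from permuted subsets.
#' @param chance_freq optional named per-ASV fraction of subsets in which the
#'   ASV was significant (any contrast, any direction).
#' @param hr_asvs optional ids of ASVs significant in the observed subset
#'   (the BH family for the q-values).
#' @return list with `observed_n_sig`, `permuted_n_sig`, `empirical_p` and,
#'   when chance frequencies are given, `chance` (data.frame: asv,
#'   chance_freq, q, q_label).
#' @export
summarize_permutation <- function(observed_n_sig, permuted_n_sig,
                                  chance_freq = NULL, hr_asvs = NULL) {
  n <- length(permuted_n_sig)
  if (n < 1) stop("need at least one permuted subset")
  out <- list(observed_n_sig = observed_n_sig,
              permuted_n_sig = as.integer(permuted_n_sig),
              n_subsets = n,
              empirical_p = sum(permuted_n_sig >= observed_n_sig) / n)
  if (!is.null(chance_freq) && length(hr_asvs)) {
    cf <- chance_freq[hr_asvs]
    q <- bh_adjust(pmax(cf, 1 / n))
    out$chance <- data.frame(asv = hr_asvs, chance_freq = as.numeric(cf),
                             q = q,
                             q_label = ifelse(cf == 0,
                                              paste0("< ", format(1 / n)),
                                              format(q, digits = 3)),
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Permutation-subset robustness of HR discoveries
#'
#' Runs the paired DAA on the high-responder set, then on `n_subsets` random
#' draws (without replacement, size-matched to HR) from the non-high-
#' responder pool, and summarises: the empirical p-value that a random
#' subset yields at least as many significant ASV-contrast results as HR,
#' the per-ASV chance frequency of significance across subsets, and BH
#' q-values over the HR-significant ASVs.
#'
#' @param counts ASV x sample count matrix.
#' @param metadata sample metadata.
#' @param hr_ids high-responder participant ids.
#' @param pool_ids non-high-responder pool (disjoint from `hr_ids`, at least
#'   as large).
#' @param n_subsets number of random subsets (100 in the standard analysis).
#' @param seed integer seed.
#' @param config [daa_config()].
#' @return list as from [summarize_permutation()], plus `hr_daa` (the HR
#'   result table).
#' @export
permutation_robustness <- function(counts, metadata, hr_ids, pool_ids,
                                   n_subsets = 100, seed = 1,
                                   config = daa_config()) {
  if (length(intersect(hr_ids, pool_ids))) stop("pool overlaps the HR set")
  if (length(pool_ids) < length(hr_ids)) stop("pool smaller than the HR set")
  if (n_subsets < 1) stop("n_subsets must be >= 1")
  hr <- daa_subset(counts, metadata, hr_ids, config)
  observed <- sum(hr$significant)
  asvs <- unique(hr$asv)
  hits <- stats::setNames(numeric(length(asvs)), asvs)
  permuted <- integer(n_subsets)
  with_seed(seed, {
    for (i in seq_len(n_subsets)) {
      ids <- sample(pool_ids, length(hr_ids))
      # zero-variance warnings are expected in small random subsets
      di <- suppressWarnings(daa_subset(counts, metadata, ids, config))
      permuted[i] <- sum(di$significant)
      sig_asv <- unique(di$asv[di$significant])
      sig_asv <- intersect(sig_asv, asvs)
      hits[sig_asv] <- hits[sig_asv] + 1
    }
  })
  out <- summarize_permutation(observed, permuted,
                               chance_freq = hits / n_subsets,
                               hr_asvs = unique(hr$asv[hr$significant]))
  out$hr_daa <- hr
  out
}
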