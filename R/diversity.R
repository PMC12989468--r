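# Rarefaction, alpha diversity and Bray-Curtis beta diversity on ASV count
# tables (ASVs in rows, samples in columns), plus within-subject distance
# trajectories across the three stool timepoints.

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (via [vegan::rrarefy()]); samples with fewer than `depth` total reads are
#' dropped and reported.
#'
#' @param counts integer matrix, ASVs x samples.
#' @param depth target depth (> 0); default 90% of the minimum sample depth.
#' @param seed integer seed for the subsampling.
#' @return list with `counts` (rarefied ASV x sample matrix) and `dropped`
#'   (character vector of removed sample ids).
#' @export
rarefy_counts <- function(counts, depth = NULL, seed = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  totals <- colSums(counts)
  if (is.null(depth)) depth <- floor(0.9 * min(totals))
  if (depth <= 0) stop("depth must be positive")
  keep <- totals >= depth
  dropped <- colnames(counts)[!keep]
  kept <- counts[, keep, drop = FALSE]
  # rrarefy's "observed counts" advisory fires on any table whose minimum
  # entry exceeds 1; spurious for integer ASV tables
  rar <- with_seed(seed, t(suppressWarnings(vegan::rrarefy(t(kept), depth))))
  storage.mode(rar) <- "integer"
  list(counts = rar, dropped = dropped, depth = depth)
}

#' Per-sample alpha diversity
#'
#' Shannon entropy in natural-log units, observed ASV richness, and Pielou
#' evenness `H / ln(observed)` (NA for single-taxon samples). Intended to be
#' run on a rarefied table.
#'
#' @param counts ASV x sample count matrix.
#' @return data.frame with `sample`, `shannon`, `observed`, `pielou`.
#' @export
alpha_diversity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) stop("all-zero sample in table")
  h <- vegan::diversity(t(counts), index = "shannon")  # natural log
  obs <- colSums(counts > 0)
  data.frame(sample = colnames(counts) %||% as.character(seq_len(ncol(counts))),
             shannon = as.numeric(h), observed = as.integer(obs),
             pielou = ifelse(obs > 1, as.numeric(h) / log(obs), NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, bounded in [0, 1].
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0) || any(y < 0)) stop("counts must be nonnegative")
  s <- sum(x) + sum(y)
  if (s == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(x, y)) / s
}

#' Within-subject Bray-Curtis distance trajectories
#'
#' One record per participant per available timepoint pair (W0-W4, W4-W8,
#' W0-W8) among samples present in the (typically rarefied) table; pairs with
#' a missing or dropped sample are omitted.
#'
#' @param counts ASV x sample count matrix.
#' @param metadata data.frame with `sample.id` (or `sample-id`),
#'   `participant`, `timepoint`.
#' @return data.frame with `participant`, `pair`, `distance`.
#' @export
within_subject_distances <- function(counts, metadata) {
  md <- normalize_metadata(metadata)
  md <- md[md$sample %in% colnames(counts), ]
  pairs <- list(c("W0", "W4"), c("W4", "W8"), c("W0", "W8"))
  out <- lapply(split(md, md$participant), function(m) {
    tp <- stats::setNames(m$sample, m$timepoint)
    recs <- lapply(pairs, function(p) {
      if (all(p %in% names(tp))) {
        data.frame(participant = m$participant[1],
                   pair = paste(p, collapse = "-"),
                   distance = bray_curtis(counts[, tp[[p[1]]]],
                                          counts[, tp[[p[2]]]]),
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, recs)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (is.null(res)) {
    res <- data.frame(participant = character(), pair = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  }
  res
}

# Accept both the QIIME2 'sample-id' header and R-mangled 'sample.id'.
normalize_metadata <- function(metadata) {
  nm <- names(metadata)
  nm[nm %in% c("sample-id", "sample.id", "sample_id")] <- "sample"
  names(metadata) <- nm
  stopifnot(all(c("sample", "participant", "timepoint") %in% nm))
  metadata
}
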