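#' @keywords internal
"_PACKAGE"

#' Derive a stage-specific seed from a global seed
#'
#' All randomness in the pipeline flows from one global seed. Each stage
#' (simulation, rarefaction, permutation, ...) derives its own seed from the
#' global seed and its stage name, so rerunning a single stage reproduces its
#' output regardless of execution order.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small polynomial hash of the stage name; kept well inside 32-bit range
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1048573
  as.integer((abs(as.numeric(seed)) + h * 1009) %% (2^31 - 1))
}

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' library code never perturbs user-level random streams.
#'
#' @param seed integer seed (NULL leaves the RNG untouched).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic TSV writer. Header comment lines ("# key: value") carry
# provenance (seed, parameters) without breaking read_gym_tsv()/QIIME2-style
# readers that skip '#' lines (the 'sample-id' header line of metadata files
# is written un-commented, as in the QIIME2 dialect).
write_gym_tsv <- function(x, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header)) {
    writeLines(paste0("# ", names(header), ": ",
                      vapply(header, as.character, "")), con, sep = "\n")
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a tab-separated table written by the pipeline
#'
#' Skips `#`-prefixed header comments. Also reads QIIME2 sample-metadata
#' style files (plain TSV with a `sample-id` column).
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_gym_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

# rounds to integer deterministically; truncated-normal sampler by rejection
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
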