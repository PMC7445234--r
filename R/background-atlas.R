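#' Remove single-cell and low-count samples
#'
#' Drops samples flagged as single-cell experiments and samples whose total
#' count falls below `min_counts` (strictly: a sample with exactly
#' `min_counts` counts is kept). The gene set is unchanged.
#'
#' @param em An [ExpressionMatrix] in counts.
#' @param metadata Data frame from [read_sample_metadata()] covering every
#'   sample of `em`.
#' @param min_counts Minimum library size retained (default 15000).
#' @return A filtered [ExpressionMatrix].
#' @export
filter_samples <- function(em, metadata, min_counts = 15000) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$unit != "counts") stop("filter_samples expects counts")
  samples <- colnames(em$values)
  if (length(samples) == 0L) stop("empty background: no samples to filter")
  idx <- match(samples, metadata$sample_id)
  if (anyNA(idx)) {
    stop("sample metadata: no row for sample(s) ",
         paste(samples[is.na(idx)], collapse = ", "))
  }
  md <- metadata[idx, , drop = FALSE]
  keep <- !md$is_single_cell & colSums(em$values) >= min_counts
  if (!any(keep)) stop("empty background: all samples removed by filtering")
  .em_select_samples(em, samples[keep])
}

#' Partition samples by library type
#'
#' PolyA and total RNA-seq libraries have systematically different gene
#' coverage, so the background atlas is assembled per library type.
#'
#' @inheritParams filter_samples
#' @return A list with elements `polyA` and `total`, each an
#'   [ExpressionMatrix] (possibly with zero columns).
#' @export
split_by_library_type <- function(em, metadata) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  samples <- colnames(em$values)
  idx <- match(samples, metadata$sample_id)
  if (anyNA(idx)) {
    stop("sample metadata: no row for sample(s) ",
         paste(samples[is.na(idx)], collapse = ", "))
  }
  lt <- metadata$library_type[idx]
  bad <- !lt %in% c("polyA", "total")
  if (any(bad)) {
    stop("unknown library_type '", lt[bad][1L], "' (expected polyA or total)")
  }
  split_one <- function(type) {
    ExpressionMatrix(em$values[, lt == type, drop = FALSE],
                     em$gene_lengths, unit = em$unit)
  }
  list(polyA = split_one("polyA"), total = split_one("total"))
}

# Pearson r between sample columns; 0 when either has zero variance, so an
# all-constant sample can never block the greedy pass.
.safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Greedily select mutually uncorrelated background samples
#'
#' Reproduces the background-assembly rule: a seeded RNG picks a random
#' first sample, then visits the remaining samples in random order and keeps
#' each one iff its Pearson correlation (across all genes, on the scale of
#' the input matrix) with every already-kept sample is below `r_max`.
#'
#' @param em An [ExpressionMatrix] (counts, as selection precedes TPM
#'   normalisation).
#' @param r_max Correlation ceiling (default 0.7, exclusive).
#' @param seed Integer seed making the random visit order reproducible.
#' @return A [BackgroundSet] whose retained samples are pairwise correlated
#'   below `r_max`.
#' @export
decorrelate <- function(em, r_max = 0.7, seed = 1L) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  samples <- colnames(em$values)
  n <- length(samples)
  if (n == 0L) stop("empty background: no samples to decorrelate")
  visit <- withr::with_seed(seed, sample.int(n))
  kept <- visit[1L]
  for (i in visit[-1L]) {
    ok <- TRUE
    for (j in kept) {
      if (.safe_cor(em$values[, i], em$values[, j]) >= r_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  BackgroundSet(.em_select_samples(em, samples[kept]),
                retained_order = samples[kept],
                r_max = r_max, seed = seed)
}

#' Convert raw counts to transcripts per million
#'
#' Per sample: reads are first converted to length-normalised rates
#' (`count / gene length in kb`), then scaled so the rates sum to 1e6. A
#' sample with zero counts everywhere stays all-zero.
#'
#' @param em An [ExpressionMatrix] in counts.
#' @return An [ExpressionMatrix] in TPM; non-degenerate columns sum to 1e6.
#' @export
counts_to_tpm <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$unit != "counts") stop("counts_to_tpm expects counts")
  if (any(em$gene_lengths <= 0)) stop("gene lengths must be positive")
  rate <- em$values / (em$gene_lengths / 1000)
  denom <- colSums(rate)
  denom[denom == 0] <- 1  # all-zero column stays all-zero
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  ExpressionMatrix(tpm, em$gene_lengths, unit = "TPM")
}
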