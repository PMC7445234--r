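# Shannon entropy in bits; 0 * log2(0) := 0.
.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon specificity of one gene in one query sample
#'
#' Measures how specific a gene's expression is to the query sample relative
#' to a background atlas. Two distributions over the `N + 1` sample positions
#' are compared: the idealised profile `P`, a point mass on the query
#' position, and the observed profile `Q`, the expression values over
#' (query, background) scaled to sum to one. The Jensen-Shannon divergence
#' `JSD(P, Q) = H((P + Q)/2) - (H(P) + H(Q))/2` is returned in bits (log
#' base 2), so it lies in `[0, 1]`: 0 means the gene is expressed only in
#' the query (perfectly specific), 1 means maximally non-specific. A gene
#' with zero expression everywhere returns 1.
#'
#' @param query Non-negative scalar: the gene's expression (TPM) in the
#'   query sample.
#' @param background Non-negative vector: the gene's expression across the
#'   background samples.
#' @return JSD in bits, in `[0, 1]`.
#' @examples
#' jsd_specificity(100, c(0, 0, 0))    # 0: perfectly query-specific
#' jsd_specificity(10, c(10, 10, 10))  # ~0.549: uniform, non-specific
#' @export
jsd_specificity <- function(query, background) {
  stopifnot(length(query) == 1L)
  x <- c(query, background)
  if (any(x < 0)) stop("expression values must be non-negative")
  s <- sum(x)
  if (s == 0) return(1)
  q <- x / s
  p <- c(1, numeric(length(background)))
  m <- (p + q) / 2
  d <- .entropy2(m) - (.entropy2(p) + .entropy2(q)) / 2
  min(max(d, 0), 1)
}

# Leave-one-out JSDs for one gene across the background: element i is the
# JSD obtained with background sample i as pseudo-query against the other
# N - 1 samples. Vectorised: with q = v / sum(v) and f(v) = -v * log2(v),
# H(M_i) = sum_j f(q_j / 2) - f(q_i / 2) + f((1 + q_i) / 2), H(P) = 0 and
# H(Q) shared across i.
.background_jsds <- function(background) {
  n <- length(background)
  s <- sum(background)
  if (s == 0) return(rep(1, n))
  q <- background / s
  f <- function(v) ifelse(v > 0, -v * log2(v), 0)
  hq <- .entropy2(q)
  hm <- sum(f(q / 2)) - f(q / 2) + f((1 + q) / 2)
  pmin(pmax(hm - hq / 2, 0), 1)
}

#' Rank z-score of a query JSD against the background rank distribution
#'
#' For each background sample, a pseudo-query JSD is computed by treating
#' that sample as the query against the remaining samples; ranked ascending,
#' these span ranks `1..N`. The query's rank is `1 +` the number of
#' background JSDs strictly below its own, clamped to `[1, N]`, and is
#' z-scored against the moments of the discrete uniform rank distribution:
#' mean `(N + 1)/2`, SD `sqrt((N^2 - 1)/12)`. A strongly negative z means
#' the gene is far more query-specific than a typical background sample.
#'
#' @param query_jsd JSD of the query (from [jsd_specificity()]).
#' @param background_jsds Numeric vector of `N >= 2` pseudo-query JSDs.
#' @return A list with `rank` (integer in `1..N`) and `zscore`.
#' @export
cofactor_zscores <- function(query_jsd, background_jsds) {
  n <- length(background_jsds)
  if (n < 2L) stop("need at least 2 background JSDs (rank SD undefined)")
  rank <- 1L + sum(background_jsds < query_jsd)
  rank <- min(rank, n)
  z <- (rank - (n + 1) / 2) / sqrt((n^2 - 1) / 12)
  list(rank = as.integer(rank), zscore = z)
}

#' Select identity TFs: the lowest-JSD transcription factors
#'
#' The `n_top` TFs with the smallest JSD are called identity TFs for the
#' query phenotype. Ties at the selection boundary are broken by
#' lexicographic TF symbol so the call is deterministic.
#'
#' @param jsd Named numeric vector of per-TF JSDs.
#' @param n_top Number of identity TFs to select (default 10).
#' @return Character vector of `n_top` TF symbols, ascending by JSD.
#' @export
select_identity_tfs <- function(jsd, n_top = 10) {
  if (length(jsd) < n_top) {
    stop("need at least ", n_top, " scored TFs; got ", length(jsd))
  }
  ord <- order(jsd, names(jsd))
  names(jsd)[ord][seq_len(n_top)]
}

#' Select co-factors: TFs significantly more specific than expected
#'
#' A TF is a co-factor when its rank z-score is strictly below `z_cut`
#' (default -1.5) and it is not already an identity TF; the two roles are
#' disjoint.
#'
#' @param zscores Named numeric vector of per-TF rank z-scores.
#' @param identity_tfs Character vector of identity TF symbols.
#' @param z_cut Threshold (default -1.5, strict inequality).
#' @return Character vector of co-factor TF symbols (sorted).
#' @export
select_cofactors <- function(zscores, identity_tfs, z_cut = -1.5) {
  tfs <- names(zscores)[zscores < z_cut]
  sort(setdiff(tfs, identity_tfs))
}

#' Score phenotype specificity of every TF and call roles
#'
#' Runs the full specificity stage: per-TF query JSD, leave-one-out
#' background JSDs, rank z-score, then identity-TF and co-factor calls.
#'
#' @param query_tpm Named numeric vector: TPM of the query sample (names are
#'   gene ids).
#' @param background_tpm Numeric matrix, genes x background samples, TPM,
#'   with gene ids as rownames.
#' @param tf_symbols Character vector naming which genes are TFs; symbols
#'   absent from the expression data are dropped with a warning.
#' @param n_top Number of identity TFs (default 10).
#' @param z_cut Co-factor z threshold (default -1.5).
#' @return A data.frame with columns `tf`, `jsd`, `rank`, `zscore`, `call`
#'   (`identity`, `cofactor` or `none`), sorted ascending by JSD.
#' @export
specificity_scores <- function(query_tpm, background_tpm, tf_symbols,
                               n_top = 10, z_cut = -1.5) {
  if (length(tf_symbols) == 0L) stop("TF list is empty")
  present <- tf_symbols %in% names(query_tpm) &
    tf_symbols %in% rownames(background_tpm)
  if (!all(present)) {
    warning(sum(!present), " TF symbol(s) absent from the expression data ",
            "were dropped", call. = FALSE)
  }
  tfs <- tf_symbols[present]
  if (length(tfs) == 0L) stop("no TF symbols present in the expression data")
  res <- lapply(tfs, function(tf) {
    bg <- background_tpm[tf, ]
    j <- jsd_specificity(query_tpm[[tf]], bg)
    rz <- cofactor_zscores(j, .background_jsds(bg))
    data.frame(tf = tf, jsd = j, rank = rz$rank, zscore = rz$zscore,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, res)
  jsd <- stats::setNames(scores$jsd, scores$tf)
  z <- stats::setNames(scores$zscore, scores$tf)
  identity <- select_identity_tfs(jsd, n_top = n_top)
  cofactors <- select_cofactors(z, identity, z_cut = z_cut)
  scores$call <- ifelse(scores$tf %in% identity, "identity",
                        ifelse(scores$tf %in% cofactors, "cofactor", "none"))
  scores[order(scores$jsd, scores$tf), , drop = FALSE]
}
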