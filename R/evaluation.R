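#' Precision, recall and F1 of a predicted edge set against a gold standard
#'
#' Edges are (source, target) TF pairs; the gold standard is typically
#' cell-type-specific TF ChIP-seq binding restricted to promoter regions.
#' When the prediction carries no directionality
#' (`directed_prediction = FALSE`), a predicted pair counts as a true
#' positive if the gold standard contains it in either orientation, and a
#' gold edge counts as recovered if the unordered pair was predicted.
#'
#' @param predicted,gold Data frames with columns `source_tf`, `target_tf`
#'   (extra columns ignored; duplicate pairs collapse).
#' @param directed_prediction Does the prediction distinguish source from
#'   target? (default `TRUE`).
#' @return A list with `precision`, `recall`, `f1` (all 0 when degenerate).
#' @export
edge_f1 <- function(predicted, gold, directed_prediction = TRUE) {
  pkey <- function(df) unique(paste(df$source_tf, df$target_tf, sep = "\r"))
  ukey <- function(df) unique(ifelse(
    df$source_tf < df$target_tf,
    paste(df$source_tf, df$target_tf, sep = "\r"),
    paste(df$target_tf, df$source_tf, sep = "\r")))
  if (directed_prediction) {
    p <- pkey(predicted)
    g <- pkey(gold)
  } else {
    p <- ukey(predicted)
    g <- ukey(gold)
  }
  tp <- sum(p %in% g)
  precision <- if (length(p) == 0L) 0 else tp / length(p)
  recall <- if (length(g) == 0L) 0 else sum(g %in% p) / length(g)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Validate enhancer-TF assignments against promoter-capture Hi-C
#'
#' An assignment of enhancer E to TF Y is validated when some Hi-C
#' interaction has one anchor overlapping E (by >= 1 base) and the other
#' anchor overlapping a promoter window of Y. The raw (untruncated)
#' enhancer intervals are used: Hi-C anchors are restriction-fragment-scale,
#' so matching against peak-truncated intervals would produce spurious
#' misses.
#'
#' @param enhancers `GRanges` of enhancer intervals with metadata `gene_id`
#'   (the assigned TF) — e.g. `enhancers_raw` from
#'   [build_regulatory_regions()], restricted to TFs in the network.
#' @param promoter_windows `GRanges` of promoter windows with metadata
#'   `gene_id`.
#' @param hic List from [read_hic_interactions()] (`anchor_a`, `anchor_b`,
#'   `kind`).
#' @return Percentage (0-100) of validated assignments.
#' @export
validate_enhancer_assignments <- function(enhancers, promoter_windows, hic) {
  n <- length(enhancers)
  if (n == 0L) stop("nothing to validate: zero enhancer assignments")
  hit_e_a <- IRanges::overlapsAny(hic$anchor_a, enhancers,
                                        ignore.strand = TRUE)
  validated <- logical(n)
  for (i in seq_len(n)) {
    tf <- enhancers$gene_id[i]
    prom <- promoter_windows[promoter_windows$gene_id == tf]
    if (length(prom) == 0L) next
    e <- enhancers[i]
    a_hits_e <- IRanges::overlapsAny(hic$anchor_a, e, ignore.strand = TRUE)
    b_hits_e <- IRanges::overlapsAny(hic$anchor_b, e, ignore.strand = TRUE)
    a_hits_p <- IRanges::overlapsAny(hic$anchor_a, prom, ignore.strand = TRUE)
    b_hits_p <- IRanges::overlapsAny(hic$anchor_b, prom, ignore.strand = TRUE)
    validated[i] <- any((a_hits_e & b_hits_p) | (b_hits_e & a_hits_p))
  }
  100 * mean(validated)
}
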