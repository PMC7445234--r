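#' Build the GRN scaffold from TF ChIP-seq evidence
#'
#' For every candidate source TF with peaks in the (non-phenotype-specific)
#' ChIP-seq atlas and every accessible site of every active region of every
#' candidate target TF, a directed edge source -> target is emitted whenever
#' a source peak shares at least one base with the site. Self-edges
#' (autoregulation) are permitted. Evidence is collapsed so each
#' (source, target, region, peak) combination appears once even when the
#' peak hits several sites of the same region; all distinct supporting
#' peaks are retained.
#'
#' @param sites Accessible sites `GRanges` (metadata `owner_tf`,
#'   `region_id`, `region_type`) from [build_regulatory_regions()].
#' @param chip_atlas `GRanges` of TF ChIP-seq peaks whose `name` metadata
#'   column carries the TF symbol, or a named list of per-TF `GRanges`.
#' @param candidates Character vector of candidate TFs (identity plus
#'   co-factors); only their peak sets are consulted. A candidate absent
#'   from the atlas gets a warning and zero outgoing edges.
#' @return A data.frame of support records: `source_tf`, `target_tf`,
#'   `region_type`, `region_id`, `peak_chrom`, `peak_start`, `peak_end`
#'   (peak coordinates 0-based half-open).
#' @export
build_scaffold <- function(sites, chip_atlas, candidates) {
  if (is.list(chip_atlas) && !is(chip_atlas, "GRanges")) {
    grl <- chip_atlas
    chip <- unlist(GenomicRanges::GRangesList(lapply(grl, function(g) {
      GenomicRanges::granges(g)
    })), use.names = FALSE)
    chip$name <- rep(names(grl), vapply(grl, length, integer(1)))
  } else {
    chip <- chip_atlas
    if (is.null(chip$name)) stop("chip_atlas needs a 'name' metadata column")
  }
  absent <- setdiff(candidates, unique(chip$name))
  if (length(absent) > 0L) {
    warning("no ChIP-seq peaks in the atlas for candidate TF(s): ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  chip <- chip[chip$name %in% candidates]
  empty <- data.frame(source_tf = character(), target_tf = character(),
                      region_type = character(), region_id = character(),
                      peak_chrom = character(), peak_start = integer(),
                      peak_end = integer(), stringsAsFactors = FALSE)
  if (length(chip) == 0L || length(sites) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(chip, sites, ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  q <- chip[S4Vectors::queryHits(hits)]
  s <- sites[S4Vectors::subjectHits(hits)]
  df <- data.frame(
    source_tf = q$name,
    target_tf = s$owner_tf,
    region_type = s$region_type,
    region_id = s$region_id,
    peak_chrom = as.character(GenomicRanges::seqnames(q)),
    peak_start = GenomicRanges::start(q) - 1L,
    peak_end = GenomicRanges::end(q),
    stringsAsFactors = FALSE
  )
  df <- unique(df)
  df[order(df$source_tf, df$target_tf, df$region_id, df$peak_start),
     , drop = FALSE]
}

# does any co-factor fail the connectivity rule on this edge set?
.failing_cofactors <- function(edges, identity_tfs, cofactors) {
  uniq <- unique(edges[, c("source_tf", "target_tf")])
  vapply(cofactors, function(cf) {
    out_ok <- any(uniq$source_tf == cf & uniq$target_tf %in% identity_tfs)
    in_ok <- any(uniq$target_tf == cf & uniq$source_tf %in% identity_tfs)
    !(out_ok && in_ok)
  }, logical(1))
}

#' Prune co-factors that are not wired to the identity core
#'
#' Every co-factor kept in the network must regulate at least one identity
#' TF and be regulated by at least one identity TF. Removal is iterated to
#' a fixpoint: deleting a co-factor deletes its edges, which can strip a
#' previously qualifying co-factor of its last qualifying partner, so a
#' single pass is not enough. Identity TFs are never removed. The fixpoint
#' is unique, so the result does not depend on input order.
#'
#' @param edges Support-record data.frame from [build_scaffold()].
#' @param identity_tfs,cofactors Character vectors of TF symbols.
#' @param scores Optional specificity table (`tf`, `jsd`, `zscore`) used to
#'   annotate the node table.
#' @return A [CoreGRN] (complex table empty; see [classify_all_regions()]).
#' @export
filter_cofactor_connectivity <- function(edges, identity_tfs, cofactors,
                                         scores = NULL) {
  keep_cf <- sort(unique(cofactors))
  edges <- edges[edges$source_tf %in% c(identity_tfs, keep_cf) &
                   edges$target_tf %in% c(identity_tfs, keep_cf),
                 , drop = FALSE]
  repeat {
    if (length(keep_cf) == 0L) break
    fail <- .failing_cofactors(edges, identity_tfs, keep_cf)
    if (!any(fail)) break
    drop <- keep_cf[fail]
    keep_cf <- keep_cf[!fail]
    edges <- edges[!(edges$source_tf %in% drop | edges$target_tf %in% drop),
                   , drop = FALSE]
  }
  nodes <- data.frame(
    tf = c(sort(unique(identity_tfs)), keep_cf),
    role = c(rep("identity", length(unique(identity_tfs))),
             rep("cofactor", length(keep_cf))),
    stringsAsFactors = FALSE
  )
  if (!is.null(scores)) {
    idx <- match(nodes$tf, scores$tf)
    nodes$jsd <- scores$jsd[idx]
    nodes$zscore <- scores$zscore[idx]
  }
  CoreGRN(nodes = nodes, edges = edges)
}

# max reciprocal overlap between any peak of a and any peak of b (0 if none
# overlap); and whether any pair overlaps by >= 1 bp.
.best_reciprocal_overlap <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
  if (length(hits) == 0L) return(c(ro = 0, touches = 0))
  ro <- reciprocal_overlap(a[S4Vectors::queryHits(hits)],
                           b[S4Vectors::subjectHits(hits)])
  c(ro = max(ro), touches = 1)
}

.ppi_lookup <- function(ppi) {
  key <- ifelse(ppi$protein_a < ppi$protein_b,
                paste(ppi$protein_a, ppi$protein_b, sep = "\r"),
                paste(ppi$protein_b, ppi$protein_a, sep = "\r"))
  tapply(ppi$score, key, max)
}

#' Classify co-bound TFs in one region as cooperative, competitive or independent
#'
#' Within a single regulatory region, TFs bind cooperatively (as a physical
#' complex) when their supporting ChIP-seq peaks reciprocally overlap by at
#' least `ro_min` AND a protein-protein interaction with confidence above
#' `ppi_min` links them. An undirected graph over the bound TFs with edges
#' for qualifying pairs is built and its connected components of size >= 2
#' are the cooperative complexes. TFs whose peaks overlap another TF's
#' peaks (by >= 1 base) but join no component bind competitively; TFs whose
#' peaks touch nobody are independent.
#'
#' @param region_edges Support records of one region (rows of the
#'   [build_scaffold()] table sharing one `region_id`).
#' @param ppi PPI data.frame (`protein_a`, `protein_b`, `score`).
#' @param ppi_min Confidence floor, strict (default 800).
#' @param ro_min Reciprocal-overlap floor, inclusive (default 0.62).
#' @return A list: `cooperative` (list of character vectors, each a complex),
#'   `competitive` (character), `independent` (character).
#' @export
classify_binding <- function(region_edges, ppi, ppi_min = 800, ro_min = 0.62) {
  tfs <- sort(unique(region_edges$source_tf))
  peaks_of <- lapply(tfs, function(tf) {
    e <- region_edges[region_edges$source_tf == tf, , drop = FALSE]
    unique(.bed0_to_granges(e$peak_chrom, e$peak_start, e$peak_end))
  })
  names(peaks_of) <- tfs
  n <- length(tfs)
  if (n == 0L) {
    return(list(cooperative = list(), competitive = character(),
                independent = character()))
  }
  scores <- .ppi_lookup(ppi)
  coop_pairs <- matrix(FALSE, n, n)
  touch <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        bro <- .best_reciprocal_overlap(peaks_of[[i]], peaks_of[[j]])
        touch[i, j] <- touch[j, i] <- bro["touches"] > 0
        key <- paste(min(tfs[i], tfs[j]), max(tfs[i], tfs[j]), sep = "\r")
        sc <- scores[key]
        coop_pairs[i, j] <- coop_pairs[j, i] <-
          bro["ro"] >= ro_min && !is.na(sc) && sc > ppi_min
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(coop_pairs, mode = "undirected")
  igraph::V(g)$name <- tfs
  comp <- igraph::components(g)
  coop <- list()
  for (k in seq_len(comp$no)) {
    members <- tfs[comp$membership == k]
    if (length(members) >= 2L) coop[[length(coop) + 1L]] <- sort(members)
  }
  coop <- coop[order(vapply(coop, `[[`, character(1), 1L))]
  in_coop <- tfs %in% unlist(coop)
  competitive <- tfs[!in_coop & apply(touch, 1, any)]
  independent <- tfs[!in_coop & !apply(touch, 1, any)]
  list(cooperative = coop, competitive = competitive,
       independent = independent)
}

#' Classify binding in every region of a network
#'
#' Runs [classify_binding()] region by region (a TF pair may be cooperative
#' in one region and competitive in another) and assembles the complex
#' table: one row per cooperative complex and one singleton row per
#' competitive TF; independent TFs are not listed.
#'
#' @param edges Support-record data.frame ([build_scaffold()] schema).
#' @inheritParams classify_binding
#' @return A data.frame `region_id`, `complex_id`, `members`
#'   (comma-separated, sorted), `mode` (`cooperative` / `competitive`).
#' @export
classify_all_regions <- function(edges, ppi, ppi_min = 800, ro_min = 0.62) {
  out <- list()
  for (rid in sort(unique(edges$region_id))) {
    re <- edges[edges$region_id == rid, , drop = FALSE]
    cls <- classify_binding(re, ppi, ppi_min = ppi_min, ro_min = ro_min)
    k <- 0L
    for (members in cls$cooperative) {
      k <- k + 1L
      out[[length(out) + 1L]] <- data.frame(
        region_id = rid, complex_id = sprintf("%s:c%d", rid, k),
        members = paste(members, collapse = ","), mode = "cooperative",
        stringsAsFactors = FALSE)
    }
    for (tf in cls$competitive) {
      k <- k + 1L
      out[[length(out) + 1L]] <- data.frame(
        region_id = rid, complex_id = sprintf("%s:c%d", rid, k),
        members = tf, mode = "competitive", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(region_id = character(), complex_id = character(),
                      members = character(), mode = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Calibrate the reciprocal-overlap threshold from labelled TF pairs
#'
#' Given reciprocal-overlap samples for known-interacting (positive) and
#' known-non-interacting (negative) TF pairs, finds the overlap level above
#' which a pair is more likely to interact than not: the smallest observed
#' overlap value `t` such that at every observed value `>= t` the
#' class-normalised frequency of positives strictly exceeds that of
#' negatives. When the two samples are not separable above any observed
#' value an error is raised.
#'
#' Overlap samples can be supplied directly, or computed from labelled pairs
#' and a multi-cell-type ChIP atlas with [compute_pair_overlaps()].
#'
#' @param positive_overlaps,negative_overlaps Numeric vectors in `[0, 1]`.
#' @return An object of class `overlap_calibration`: list with `threshold`,
#'   `positive_overlaps`, `negative_overlaps`.
#' @examples
#' calibrate_overlap_threshold(c(0.7, 0.8, 0.9), c(0.1, 0.2, 0.3))$threshold
#' @export
calibrate_overlap_threshold <- function(positive_overlaps, negative_overlaps) {
  pos <- positive_overlaps
  neg <- negative_overlaps
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both labelled overlap samples must be nonempty")
  }
  if (any(c(pos, neg) < 0 | c(pos, neg) > 1)) {
    stop("overlap values must lie in [0, 1]")
  }
  observed <- sort(unique(c(pos, neg)))
  dominates <- vapply(observed, function(v) {
    mean(pos == v) > mean(neg == v)
  }, logical(1))
  # threshold: smallest observed value from which positives dominate at
  # every observed level upward
  ok <- rev(cumprod(rev(dominates))) == 1
  if (!any(ok)) stop("classes not separable above any threshold")
  structure(list(threshold = observed[which(ok)[1L]],
                 positive_overlaps = pos,
                 negative_overlaps = neg),
            class = "overlap_calibration")
}

#' @export
print.overlap_calibration <- function(x, ...) {
  cat(sprintf("overlap_calibration: threshold %.4f (%d positive, %d negative samples)\n",
              x$threshold, length(x$positive_overlaps),
              length(x$negative_overlaps)))
  invisible(x)
}

#' Per-pair best reciprocal peak overlaps across cell types
#'
#' For each labelled TF pair and each cell type where both TFs have peaks,
#' the maximum reciprocal overlap between any peak of one TF and any peak
#' of the other is collected; the pooled values feed
#' [calibrate_overlap_threshold()].
#'
#' @param pairs Data frame with columns `tf_a`, `tf_b`.
#' @param chip_atlas_multi Named list (cell type) of named lists (TF) of
#'   peak `GRanges`.
#' @return Numeric vector of overlap values (one per pair x cell type with
#'   data).
#' @export
compute_pair_overlaps <- function(pairs, chip_atlas_multi) {
  vals <- numeric()
  for (ct in names(chip_atlas_multi)) {
    atlas <- chip_atlas_multi[[ct]]
    for (i in seq_len(nrow(pairs))) {
      a <- atlas[[pairs$tf_a[i]]]
      b <- atlas[[pairs$tf_b[i]]]
      if (is.null(a) || is.null(b)) next
      vals <- c(vals, .best_reciprocal_overlap(a, b)[["ro"]])
    }
  }
  vals
}
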