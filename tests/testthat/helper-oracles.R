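# Shared helpers: quick constructors and independent oracles used to
# cross-check the package's vectorised implementations.

# GRanges from 0-based half-open coordinates (BED convention), mirroring
# how the file readers convert.
gr0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         ...)
}

# Brute-force overlap by literal base counting.
bf_overlap_length <- function(chrom_a, s0a, e0a, chrom_b, s0b, e0b) {
  if (chrom_a != chrom_b) return(0L)
  length(intersect(seq.int(s0a, e0a - 1L), seq.int(s0b, e0b - 1L)))
}

# Independent JSD oracle via the KL-divergence decomposition
# JSD(P, Q) = [KL(P || M) + KL(Q || M)] / 2 with M = (P + Q)/2, log base 2.
jsd_oracle <- function(query, background) {
  x <- c(query, background)
  if (sum(x) == 0) return(1)
  q <- x / sum(x)
  p <- c(1, numeric(length(background)))
  m <- (p + q) / 2
  kl <- function(a, b) {
    keep <- a > 0
    sum(a[keep] * log2(a[keep] / b[keep]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# Union-find oracle for connected components over an explicit pair list.
uf_components <- function(nodes, pairs) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (length(pairs) > 0) {
    for (pr in pairs) {
      ra <- find(pr[1]); rb <- find(pr[2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  unname(split(nodes, roots))
}

# Delete-until-stable oracle for the co-factor connectivity rule, working
# on an adjacency matrix rather than edge tables.
prune_oracle <- function(adj, identity_tfs, cofactors) {
  keep <- c(identity_tfs, cofactors)
  repeat {
    a <- adj[keep, keep, drop = FALSE]
    ids <- intersect(keep, identity_tfs)
    bad <- Filter(function(cf) {
      !(any(a[cf, ids]) && any(a[ids, cf]))
    }, intersect(keep, cofactors))
    if (length(bad) == 0) break
    keep <- setdiff(keep, bad)
  }
  keep
}

# Edge table with the full scaffold schema from a bare (source, target)
# pair list; peak fields are placeholders unless supplied.
make_edges <- function(source_tf, target_tf,
                       region_id = paste0(target_tf, ":prom1"),
                       region_type = "promoter",
                       peak_chrom = "chr1", peak_start = 0L,
                       peak_end = 100L) {
  n <- length(source_tf)
  data.frame(source_tf = source_tf, target_tf = target_tf,
             region_type = rep_len(region_type, n),
             region_id = rep_len(region_id, n),
             peak_chrom = rep_len(peak_chrom, n),
             peak_start = rep_len(peak_start, n),
             peak_end = rep_len(peak_end, n), stringsAsFactors = FALSE)
}

# Random interval pair generator shared by the interval-algebra checks.
random_intervals <- function(n, max_pos = 2000L, max_width = 300L,
                             chroms = c("chr1", "chr2")) {
  s <- sample.int(max_pos, n, replace = TRUE) - 1L
  w <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + w, stringsAsFactors = FALSE)
}

# Small planted expression world used by the specificity tests: 10 marker
# genes expressed only in the query, a few minority-expressed co-factor
# genes, the rest broadly expressed.
make_marker_matrix <- function(n_genes = 30, n_bg = 12, n_markers = 10,
                               seed = 42) {
  withr::with_seed(seed, {
    genes <- sprintf("G%02d", seq_len(n_genes))
    bg <- matrix(stats::rlnorm(n_genes * n_bg, log(50), 0.4),
                 nrow = n_genes, dimnames = list(genes, paste0("S", seq_len(n_bg))))
    query <- stats::setNames(stats::rlnorm(n_genes, log(50), 0.4), genes)
    markers <- genes[seq_len(n_markers)]
    bg[markers, ] <- 0
    query[markers] <- 500
    list(query = query, background = bg, markers = markers, genes = genes)
  })
}
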