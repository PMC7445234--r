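#' Generate a synthetic multi-omics bundle with a planted core network
#'
#' Writes a fully consistent set of pipeline inputs — expression compendium,
#' sample metadata, TF list, promoter annotation, enhancer-gene
#' associations, H3K4me3 / H3K27ac / DNase peak sets, TF ChIP-seq atlas,
#' PPI table and promoter-capture Hi-C interactions — around a planted
#' ground-truth network, so every pipeline stage can be exercised with no
#' external downloads and recovery can be asserted exactly.
#'
#' The planted world: `n_identity` identity TFs are expressed essentially
#' only in the query sample (zero background counts, so their JSD is 0);
#' `n_cofactors` co-factors are expressed strongly in the query and weakly
#' in a ~10% minority of background samples, which places their query JSD
#' at rank 1 among the background pseudo-queries and hence their rank
#' z-score below -1.5 by construction; all remaining TFs are broadly
#' expressed. Every candidate TF gets an H3K4me3-marked promoter, one or
#' two H3K27ac-marked enhancers (truncated regions carrying a DNase site),
#' and the planted directed edges are realised as ChIP-seq peaks placed in
#' disjoint 200-bp slots inside the accessible sites of their supporting
#' region. Planted cooperative complexes get byte-identical member peaks
#' plus a PPI score of 900; one planted competitive pair gets identical
#' peaks but a PPI score of 300; all other co-bound TFs occupy disjoint
#' slots. Hi-C interactions link each planted enhancer to its owner's
#' promoter window. The planted network satisfies the co-factor
#' connectivity rule by construction.
#'
#' With all noise rates at their default 0 the bundle is exactly
#' recoverable: the reconstructed edge set equals the planted one (F1 = 1).
#' `peak_dropout_rate` removes each enhancer's H3K27ac peak independently
#' (inactivating the enhancer); `decoy_edge_rate` adds unplanted ChIP
#' peaks; `expression_noise_sd` multiplies every count by a log-normal
#' factor; `hic_drop_rate` removes each enhancer's Hi-C interaction
#' independently.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the bundle is byte-identical given the seed.
#' @param n_tfs,n_background Compendium size (defaults 200 TFs, 50
#'   background samples).
#' @param n_identity,n_cofactors Planted core size (defaults 10 and 5).
#' @param peak_dropout_rate,decoy_edge_rate,expression_noise_sd,hic_drop_rate
#'   Noise settings, all 0 by default.
#' @param n_lowcount_decoys,n_singlecell_decoys Extra background samples
#'   that the atlas filters must remove (defaults 0).
#' @return Invisibly, the planted truth: a list with `identity_tfs`,
#'   `cofactors`, `edges` (data.frame `source_tf`, `target_tf`,
#'   `region_id`, `region_type`), `complexes` (data.frame `region_id`,
#'   `members`, `mode`), `enhancer_map` (data.frame `tf`, `enhancer_id`,
#'   surviving `h3k27ac` flag, `hic` flag), `files`, `seed`. Also written
#'   as `truth.json`.
#' @export
generate_bundle <- function(out_dir, seed = 1L,
                            n_tfs = 200, n_background = 50,
                            n_identity = 10, n_cofactors = 5,
                            peak_dropout_rate = 0, decoy_edge_rate = 0,
                            expression_noise_sd = 0, hic_drop_rate = 0,
                            n_lowcount_decoys = 0, n_singlecell_decoys = 0) {
  if (n_identity < 1 || n_cofactors < 0 ||
      n_tfs < n_identity + n_cofactors + 1) {
    stop("config cannot satisfy the planted-network invariants: need ",
         "n_tfs > n_identity + n_cofactors and n_identity >= 1")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  truth <- withr::with_seed(seed, .generate_bundle_impl(
    out_dir, n_tfs, n_background, n_identity, n_cofactors,
    peak_dropout_rate, decoy_edge_rate, expression_noise_sd, hic_drop_rate,
    n_lowcount_decoys, n_singlecell_decoys))
  truth$seed <- as.integer(seed)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

.generate_bundle_impl <- function(out_dir, n_tfs, n_background,
                                  n_identity, n_cofactors,
                                  peak_dropout_rate, decoy_edge_rate,
                                  expression_noise_sd, hic_drop_rate,
                                  n_lowcount_decoys, n_singlecell_decoys) {
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  identity_tfs <- sort(sample(tfs, n_identity))
  cofactors <- sort(sample(setdiff(tfs, identity_tfs), n_cofactors))
  candidates <- c(identity_tfs, cofactors)

  ## --- genome layout: one gene locus per 100 kb, two chromosomes --------
  half <- ceiling(n_tfs / 2)
  chrom <- ifelse(seq_len(n_tfs) <= half, "chr1", "chr2")
  slot <- ifelse(seq_len(n_tfs) <= half, seq_len(n_tfs),
                 seq_len(n_tfs) - half)
  tss1 <- 200000L + (slot - 1L) * 100000L  # 1-based TSS
  strand <- rep(c("+", "-"), length.out = n_tfs)
  names(tss1) <- names(chrom) <- names(strand) <- tfs
  tss0 <- tss1 - 1L

  promoters <- data.frame(gene_id = tfs, chrom = chrom, tss = tss1,
                          strand = strand, stringsAsFactors = FALSE)

  ## --- expression compendium -------------------------------------------
  bg_ids <- sprintf("BG%02d", seq_len(n_background))
  gene_lengths <- sample(800:3000, n_tfs, replace = TRUE)
  # broadly-expressed genes carry the library size: scale their mean so
  # every sample clears the 15,000-count filter with ample margin
  n_broad <- n_tfs - n_identity - n_cofactors
  base_mean <- max(200, ceiling(2.5 * 15000 / n_broad))
  counts <- matrix(round(stats::rlnorm(n_tfs * (n_background + 1),
                                       meanlog = log(base_mean),
                                       sdlog = 0.5)),
                   nrow = n_tfs,
                   dimnames = list(tfs, c(bg_ids, "query")))
  counts[identity_tfs, bg_ids] <- 0
  counts[identity_tfs, "query"] <- 1000
  m_express <- max(1L, round(0.1 * n_background))
  cof_samples <- list()
  for (cf in cofactors) {
    expressing <- sample(bg_ids, m_express)
    counts[cf, bg_ids] <- 0
    counts[cf, expressing] <- 100
    counts[cf, "query"] <- 1000
    cof_samples[[cf]] <- expressing
  }
  if (expression_noise_sd > 0) {
    counts <- round(counts * matrix(
      exp(stats::rnorm(length(counts), 0, expression_noise_sd)),
      nrow = nrow(counts)))
  }
  metadata <- data.frame(sample_id = c(bg_ids, "query"),
                         library_type = "total",
                         is_single_cell = 0L, stringsAsFactors = FALSE)
  if (n_lowcount_decoys > 0) {
    ids <- sprintf("LOW%02d", seq_len(n_lowcount_decoys))
    low <- matrix(round(stats::rlnorm(n_tfs * n_lowcount_decoys,
                                      meanlog = log(20), sdlog = 0.3)),
                  nrow = n_tfs, dimnames = list(tfs, ids))
    counts <- cbind(counts, low)
    metadata <- rbind(metadata, data.frame(sample_id = ids,
                                           library_type = "total",
                                           is_single_cell = 0L))
  }
  if (n_singlecell_decoys > 0) {
    ids <- sprintf("SC%02d", seq_len(n_singlecell_decoys))
    sc <- matrix(round(stats::rlnorm(n_tfs * n_singlecell_decoys,
                                     meanlog = log(200), sdlog = 0.5)),
                 nrow = n_tfs, dimnames = list(tfs, ids))
    counts <- cbind(counts, sc)
    metadata <- rbind(metadata, data.frame(sample_id = ids,
                                           library_type = "total",
                                           is_single_cell = 1L))
  }
  em <- ExpressionMatrix(counts, gene_lengths, unit = "counts")

  ## --- regulatory architecture of the candidates ------------------------
  # promoter DNase site sits in the strand-independent core of the window;
  # enhancer j of a gene sits 30*j kb left of the TSS.
  region_rows <- list()
  enh_assoc <- list()
  k4_peaks <- list()
  k27_peaks <- list()
  dnase_peaks <- list()
  enhancer_map <- list()
  slots_per <- c(promoter = 4L, enhancer = 5L)
  for (tf in candidates) {
    t0 <- tss0[[tf]]
    ch <- chrom[[tf]]
    k4_peaks[[tf]] <- data.frame(chrom = ch, start = t0 - 1700L,
                                 end = t0 + 1700L)
    prom_id <- paste0(tf, ":prom1")
    region_rows[[prom_id]] <- data.frame(
      region_id = prom_id, target = tf, region_type = "promoter",
      chrom = ch, site_start0 = t0 - 400L, n_slots = slots_per[["promoter"]],
      stringsAsFactors = FALSE)
    dnase_peaks[[prom_id]] <- data.frame(chrom = ch, start = t0 - 400L,
                                         end = t0 + 400L)
    n_enh <- sample(1:2, 1L)
    for (j in seq_len(n_enh)) {
      s0 <- t0 - 30000L * j
      eid <- sprintf("ENH_%s_%d", tf, j)
      enh_assoc[[eid]] <- data.frame(enhancer_id = eid, chrom = ch,
                                     start = s0, end = s0 + 3000L,
                                     gene_id = tf, stringsAsFactors = FALSE)
      keep_k27 <- stats::runif(1) >= peak_dropout_rate
      if (keep_k27) {
        k27_peaks[[eid]] <- data.frame(chrom = ch, start = s0 + 500L,
                                       end = s0 + 2500L)
        region_rows[[eid]] <- data.frame(
          region_id = eid, target = tf, region_type = "enhancer",
          chrom = ch, site_start0 = s0 + 1000L,
          n_slots = slots_per[["enhancer"]], stringsAsFactors = FALSE)
      }
      dnase_peaks[[eid]] <- data.frame(chrom = ch, start = s0 + 1000L,
                                       end = s0 + 2000L)
      enhancer_map[[eid]] <- data.frame(tf = tf, enhancer_id = eid,
                                        chrom = ch, start = s0,
                                        end = s0 + 3000L,
                                        h3k27ac = keep_k27,
                                        stringsAsFactors = FALSE)
    }
  }
  regions <- do.call(rbind, region_rows)
  regions$next_slot <- 1L
  rownames(regions) <- regions$region_id

  ## --- planted complexes and competitive pair ---------------------------
  # complexes need >= 7 distinct members + 2 competitive TFs
  complex_sizes <- if (length(candidates) >= 9) c(2L, 3L, 2L) else integer()
  pool <- sample(candidates)
  planted_complexes <- list()
  chip <- list()      # rows: chrom, start, end, name
  edges <- list()     # rows: source_tf, target_tf, region_id, region_type

  place_peak <- function(region_id, source, slot_index = NULL) {
    r <- regions[region_id, ]
    s <- if (is.null(slot_index)) r$next_slot else slot_index
    if (is.null(slot_index)) {
      if (s > r$n_slots) return(NULL)
      regions[region_id, "next_slot"] <<- s + 1L
    }
    p <- data.frame(chrom = r$chrom, start = r$site_start0 + 200L * (s - 1L),
                    end = r$site_start0 + 200L * s, name = source,
                    stringsAsFactors = FALSE)
    chip[[length(chip) + 1L]] <<- p
    edges[[length(edges) + 1L]] <<- data.frame(
      source_tf = source, target_tf = r$target, region_id = region_id,
      region_type = r$region_type, stringsAsFactors = FALSE)
    p
  }

  host_pool <- sample(candidates)
  hi <- 1L
  for (size in complex_sizes) {
    members <- sort(pool[seq_len(size)])
    pool <- pool[-seq_len(size)]
    # host complex k at a region of a distinct target: promoter for odd,
    # first enhancer (if active) for even complexes
    host <- host_pool[hi]; hi <- hi + 1L
    rid <- paste0(host, ":prom1")
    alt <- sprintf("ENH_%s_1", host)
    if (hi %% 2L == 0L && alt %in% rownames(regions)) rid <- alt
    s <- regions[rid, "next_slot"]
    regions[rid, "next_slot"] <- s + 1L
    for (m in members) place_peak(rid, m, slot_index = s)
    planted_complexes[[length(planted_complexes) + 1L]] <- data.frame(
      region_id = rid, members = paste(members, collapse = ","),
      mode = "cooperative", stringsAsFactors = FALSE)
  }
  competitive_pair <- character()
  if (length(pool) >= 2) {
    competitive_pair <- sort(pool[1:2])
    pool <- pool[-(1:2)]
    host <- host_pool[hi]; hi <- hi + 1L
    rid <- paste0(host, ":prom1")
    s <- regions[rid, "next_slot"]
    regions[rid, "next_slot"] <- s + 1L
    for (m in competitive_pair) place_peak(rid, m, slot_index = s)
    planted_complexes[[length(planted_complexes) + 1L]] <- data.frame(
      region_id = rid, members = competitive_pair, mode = "competitive",
      stringsAsFactors = FALSE)
  }

  ## --- connectivity edges and random extras -----------------------------
  edge_exists <- function(s, t) {
    any(vapply(edges, function(e) e$source_tf == s && e$target_tf == t,
               logical(1)))
  }
  add_edge <- function(s, t) {
    # try the target's regions in random order until a slot is free
    rids <- sample(regions$region_id[regions$target == t])
    for (rid in rids) {
      if (!is.null(place_peak(rid, s))) return(TRUE)
    }
    FALSE
  }
  for (cf in cofactors) {
    if (!any(vapply(edges, function(e)
      e$source_tf == cf && e$target_tf %in% identity_tfs, logical(1)))) {
      if (!add_edge(cf, sample(identity_tfs, 1L))) {
        stop("generation error: could not satisfy the co-factor ",
             "connectivity invariant (out-edge)")
      }
    }
    if (!any(vapply(edges, function(e)
      e$target_tf == cf && e$source_tf %in% identity_tfs, logical(1)))) {
      if (!add_edge(sample(identity_tfs, 1L), cf)) {
        stop("generation error: could not satisfy the co-factor ",
             "connectivity invariant (in-edge)")
      }
    }
  }
  for (tf in identity_tfs) {
    for (src in sample(candidates, 2L)) {
      if (!edge_exists(src, tf)) add_edge(src, tf)
    }
  }
  n_extra <- round(0.05 * length(candidates)^2)
  for (i in seq_len(n_extra)) {
    s <- sample(candidates, 1L)
    t <- sample(candidates, 1L)
    if (!edge_exists(s, t)) add_edge(s, t)
  }

  ## --- decoy ChIP peaks (false-edge noise) ------------------------------
  if (decoy_edge_rate > 0) {
    for (rid in regions$region_id) {
      for (s in candidates) {
        if (stats::runif(1) < decoy_edge_rate &&
            !edge_exists(s, regions[rid, "target"])) {
          place_peak(rid, s)
        }
      }
    }
  }

  edges <- unique(do.call(rbind, edges))
  chip <- do.call(rbind, chip)

  ## --- PPI table ---------------------------------------------------------
  ppi <- list()
  for (pc in planted_complexes) {
    if (pc$mode[1] != "cooperative") next
    members <- strsplit(pc$members[1], ",")[[1]]
    prs <- utils::combn(members, 2)
    for (k in seq_len(ncol(prs))) {
      ppi[[length(ppi) + 1L]] <- data.frame(protein_a = prs[1, k],
                                            protein_b = prs[2, k],
                                            score = 900L)
    }
  }
  if (length(competitive_pair) == 2) {
    ppi[[length(ppi) + 1L]] <- data.frame(protein_a = competitive_pair[1],
                                          protein_b = competitive_pair[2],
                                          score = 300L)
  }
  seen <- vapply(ppi, function(p)
    paste(sort(c(p$protein_a, p$protein_b)), collapse = "\r"), character(1))
  n_decoy_ppi <- 20L
  tries <- 0L
  while (n_decoy_ppi > 0 && tries < 200L) {
    tries <- tries + 1L
    pr <- sample(tfs, 2L)
    key <- paste(sort(pr), collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    ppi[[length(ppi) + 1L]] <- data.frame(protein_a = pr[1], protein_b = pr[2],
                                          score = sample(100:790, 1L))
    n_decoy_ppi <- n_decoy_ppi - 1L
  }
  ppi <- do.call(rbind, ppi)

  ## --- Hi-C interactions -------------------------------------------------
  enhancer_map <- do.call(rbind, enhancer_map)
  rownames(enhancer_map) <- NULL
  enhancer_map$hic <- stats::runif(nrow(enhancer_map)) >= hic_drop_rate
  hic <- list()
  for (i in seq_len(nrow(enhancer_map))) {
    if (!enhancer_map$hic[i]) next
    tf <- enhancer_map$tf[i]
    t0 <- tss0[[tf]]
    hic[[length(hic) + 1L]] <- data.frame(
      chrom_a = enhancer_map$chrom[i],
      start_a = enhancer_map$start[i] - 500L,
      end_a = enhancer_map$end[i] + 500L,
      chrom_b = chrom[[tf]], start_b = t0 - 1500L, end_b = t0 + 1501L,
      kind = "promoter-other", stringsAsFactors = FALSE)
  }
  # a few promoter-promoter decoys between non-candidate genes
  others <- setdiff(tfs, candidates)
  for (k in seq_len(min(3L, length(others) %/% 2))) {
    pr <- sample(others, 2L)
    hic[[length(hic) + 1L]] <- data.frame(
      chrom_a = chrom[[pr[1]]], start_a = tss0[[pr[1]]] - 1500L,
      end_a = tss0[[pr[1]]] + 1501L,
      chrom_b = chrom[[pr[2]]], start_b = tss0[[pr[2]]] - 1500L,
      end_b = tss0[[pr[2]]] + 1501L,
      kind = "promoter-promoter", stringsAsFactors = FALSE)
  }
  hic <- do.call(rbind, hic)

  ## --- write everything ---------------------------------------------------
  files <- list(
    expression = file.path(out_dir, "expression.tsv"),
    metadata = file.path(out_dir, "sample_metadata.tsv"),
    tf_list = file.path(out_dir, "tf_list.txt"),
    promoters = file.path(out_dir, "promoters.tsv"),
    enhancers = file.path(out_dir, "enhancers.tsv"),
    h3k4me3 = file.path(out_dir, "h3k4me3.bed"),
    h3k27ac = file.path(out_dir, "h3k27ac.bed"),
    dnase = file.path(out_dir, "dnase.bed"),
    chip_atlas = file.path(out_dir, "chip_atlas.bed"),
    ppi = file.path(out_dir, "ppi.tsv"),
    hic = file.path(out_dir, "hic.tsv")
  )
  write_expression_table(em, files$expression)
  wt <- function(df, path, col.names = TRUE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  }
  wt(metadata, files$metadata)
  writeLines(tfs, files$tf_list)
  wt(promoters, files$promoters)
  wt(do.call(rbind, enh_assoc), files$enhancers)
  wt(do.call(rbind, k4_peaks), files$h3k4me3, col.names = FALSE)
  k27 <- if (length(k27_peaks) > 0) do.call(rbind, k27_peaks) else
    data.frame(chrom = character(), start = integer(), end = integer())
  wt(k27, files$h3k27ac, col.names = FALSE)
  wt(do.call(rbind, dnase_peaks), files$dnase, col.names = FALSE)
  wt(chip[order(chip$name, chip$chrom, chip$start), ], files$chip_atlas,
     col.names = FALSE)
  wt(ppi, files$ppi)
  wt(hic, files$hic)

  complexes <- do.call(rbind, planted_complexes)
  rownames(edges) <- NULL
  list(identity_tfs = identity_tfs,
       cofactors = cofactors,
       edges = edges[order(edges$source_tf, edges$target_tf,
                           edges$region_id), , drop = FALSE],
       complexes = complexes,
       competitive_pair = competitive_pair,
       enhancer_map = enhancer_map,
       cofactor_expressing_samples = cof_samples,
       n_background = n_background,
       files = lapply(files, normalizePath),
       noise = list(peak_dropout_rate = peak_dropout_rate,
                    decoy_edge_rate = decoy_edge_rate,
                    expression_noise_sd = expression_noise_sd,
                    hic_drop_rate = hic_drop_rate))
}
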