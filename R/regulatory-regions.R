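#' Build strand-aware promoter windows around annotated TSSs
#'
#' Each promoter is the window covering `up` bases upstream and `down` bases
#' downstream of the TSS (the TSS base counts as the first downstream base),
#' so unclipped windows have width `up + down` on either strand. Windows
#' running off the chromosome start are clipped, reducing their width.
#'
#' @param promoters Data frame from [read_promoter_annotation()] (`gene_id`,
#'   `chrom`, `tss` 1-based, `strand`).
#' @param up,down Upstream / downstream extents in bp (defaults 1500 / 500).
#' @return A `GRanges` with metadata columns `gene_id` and `region_id`
#'   (`<gene>:prom<k>` for the k-th annotated promoter of a gene).
#' @export
build_promoter_window <- function(promoters, up = 1500, down = 500) {
  stopifnot(up > 0, down > 0)
  t <- promoters$tss
  plus <- promoters$strand == "+"
  start1 <- ifelse(plus, t - up, t - down + 1)
  end1 <- ifelse(plus, t + down - 1, t + up)
  start1 <- pmax(start1, 1)
  k <- stats::ave(seq_along(t), promoters$gene_id, FUN = seq_along)
  GenomicRanges::GRanges(
    seqnames = promoters$chrom,
    ranges = IRanges::IRanges(start = start1, end = end1),
    strand = promoters$strand,
    gene_id = promoters$gene_id,
    region_id = paste0(promoters$gene_id, ":prom", k)
  )
}

#' Flag promoters overlapping an H3K4me3 peak as active
#'
#' A promoter window is active iff it shares at least one base with at least
#' one phenotype-specific H3K4me3 peak (strand-blind).
#'
#' @param windows Promoter windows from [build_promoter_window()].
#' @param h3k4me3 `GRanges` of H3K4me3 peaks.
#' @return Logical vector along `windows`.
#' @export
call_active_promoters <- function(windows, h3k4me3) {
  IRanges::overlapsAny(windows, h3k4me3, ignore.strand = TRUE)
}

#' Call active enhancers and truncate them to their H3K27ac peaks
#'
#' Only enhancers linked to a TF whose promoter is active are evaluated. An
#' enhancer is active iff it overlaps at least one H3K27ac peak; its
#' interval is then truncated to the intersection with each overlapping
#' peak, so an enhancer hit by two disjoint peaks yields two truncated
#' intervals sharing one `region_id`. Inactive enhancers are dropped.
#'
#' @param associations `GRanges` from [read_enhancer_associations()]
#'   (metadata `enhancer_id`, `gene_id`).
#' @param active_tfs Character vector of TFs with at least one active
#'   promoter.
#' @param h3k27ac `GRanges` of H3K27ac peaks.
#' @return A `GRanges` of truncated enhancer intervals with metadata columns
#'   `owner_tf`, `region_id`, `region_type` (`"enhancer"`).
#' @export
call_active_enhancers <- function(associations, active_tfs, h3k27ac) {
  assoc <- associations[associations$gene_id %in% active_tfs]
  hits <- GenomicRanges::findOverlaps(assoc, h3k27ac, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    out <- GenomicRanges::GRanges()
    out$owner_tf <- character()
    out$region_id <- character()
    out$region_type <- character()
    return(out)
  }
  q <- assoc[S4Vectors::queryHits(hits)]
  s <- h3k27ac[S4Vectors::subjectHits(hits)]
  trunc <- IRanges::pintersect(GenomicRanges::ranges(q),
                               GenomicRanges::ranges(s))
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(q),
    ranges = trunc,
    owner_tf = q$gene_id,
    region_id = q$enhancer_id,
    region_type = "enhancer"
  )
  unique(out)
}

#' Intersect regulatory regions with accessible chromatin
#'
#' DNase-seq (or any accessibility) peaks falling inside active promoter or
#' truncated enhancer intervals define the potentially active regulatory
#' sites; only these sites can support regulatory edges. Each site is the
#' intersection of one peak with one region interval and inherits the
#' region's metadata. Regions without any accessible site simply produce no
#' sites (they are retained upstream but can support no edges).
#'
#' @param regions `GRanges` of active region intervals with metadata
#'   `owner_tf`, `region_id`, `region_type`.
#' @param dnase `GRanges` of accessibility peaks.
#' @return A `GRanges` of accessible sites carrying the same metadata.
#' @export
compute_accessible_sites <- function(regions, dnase) {
  hits <- GenomicRanges::findOverlaps(regions, dnase, ignore.strand = TRUE)
  q <- regions[S4Vectors::queryHits(hits)]
  s <- dnase[S4Vectors::subjectHits(hits)]
  sites <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(q),
    ranges = IRanges::pintersect(GenomicRanges::ranges(q),
                                 GenomicRanges::ranges(s)),
    owner_tf = q$owner_tf,
    region_id = q$region_id,
    region_type = q$region_type
  )
  unique(sites)
}

#' Build all active regulatory regions and accessible sites for a TF set
#'
#' Convenience wrapper running the whole regulatory-region stage for the
#' candidate TFs (identity TFs plus co-factors): promoter windows, H3K4me3
#' activity, enhancer linkage and H3K27ac truncation, then DNase gating. A
#' TF without any active promoter contributes no regions at all — its
#' enhancers are never evaluated.
#'
#' @param candidates Character vector of candidate TF symbols.
#' @param promoters Promoter annotation data frame.
#' @param associations Enhancer-gene associations (`GRanges`).
#' @param h3k4me3,h3k27ac,dnase Peak `GRanges`. `dnase = NULL` (with
#'   `dnase_required = FALSE`) disables accessibility gating: every region
#'   interval then counts as one accessible site.
#' @param up,down Promoter window extents.
#' @param dnase_required When `TRUE` (default) a missing `dnase` set is an
#'   error rather than a silent relaxation.
#' @return A list: `regions` (`GRanges` of active region intervals),
#'   `sites` (`GRanges` of accessible sites), `active_tfs` (character),
#'   `promoter_windows` (all candidate windows, with `active` flag),
#'   `enhancers_raw` (untruncated intervals of the active enhancers, used
#'   for Hi-C validation).
#' @export
build_regulatory_regions <- function(candidates, promoters, associations,
                                     h3k4me3, h3k27ac, dnase = NULL,
                                     up = 1500, down = 500,
                                     dnase_required = TRUE) {
  if (is.null(dnase) && dnase_required) {
    stop("accessibility peaks are required (set dnase_required = FALSE to ",
         "relax the DNase gate)")
  }
  prom <- promoters[promoters$gene_id %in% candidates, , drop = FALSE]
  windows <- build_promoter_window(prom, up = up, down = down)
  windows$active <- call_active_promoters(windows, h3k4me3)
  active_win <- windows[windows$active]
  active_tfs <- unique(active_win$gene_id)

  prom_regions <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(active_win),
    ranges = GenomicRanges::ranges(active_win),
    owner_tf = active_win$gene_id,
    region_id = active_win$region_id,
    region_type = "promoter"
  )
  enh_regions <- call_active_enhancers(associations, active_tfs, h3k27ac)
  regions <- c(prom_regions, enh_regions)

  if (is.null(dnase)) {
    message("accessibility gating disabled: treating every active region ",
            "interval as accessible")
    sites <- regions
  } else {
    sites <- compute_accessible_sites(regions, dnase)
  }
  enh_raw <- associations[associations$enhancer_id %in%
                            unique(enh_regions$region_id)]
  list(regions = regions, sites = sites, active_tfs = active_tfs,
       promoter_windows = windows, enhancers_raw = enh_raw)
}

#' Summarise regions as a table
#'
#' One row per region interval: owner TF, type, id, 0-based half-open
#' coordinates, and the number of accessible sites the region carries.
#'
#' @param regions,sites `GRanges` as returned by
#'   [build_regulatory_regions()].
#' @return A data.frame.
#' @export
regions_table <- function(regions, sites) {
  if (length(regions) == 0L) {
    return(data.frame(owner_tf = character(), region_type = character(),
                      region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_accessible_sites = integer(),
                      stringsAsFactors = FALSE))
  }
  n_sites <- table(sites$region_id)
  df <- cbind(
    data.frame(owner_tf = regions$owner_tf,
               region_type = regions$region_type,
               region_id = regions$region_id,
               stringsAsFactors = FALSE),
    .granges_to_bed0(regions)
  )
  df$n_accessible_sites <- as.integer(n_sites[df$region_id])
  df$n_accessible_sites[is.na(df$n_accessible_sites)] <- 0L
  df[order(df$owner_tf, df$region_type, df$region_id, df$start), , drop = FALSE]
}
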