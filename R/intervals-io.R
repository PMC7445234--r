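#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom methods is
NULL

# All genomic coordinates live in GRanges (1-based, closed) internally.
# Every BED-convention file (0-based, half-open) is converted on read and
# converted back on write, so no off-by-one can leak across module borders.

.bed0_to_granges <- function(chrom, start0, end0, strand = NULL, ...) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = if (is.null(strand)) "*" else strand,
    ...
  )
}

.granges_to_bed0 <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read a BED / narrowPeak file of peaks
#'
#' Reads BED3, BED6 or ENCODE narrowPeak into a `GRanges`. Coordinates in the
#' file are 0-based half-open (BED convention) and are converted to the
#' 1-based closed convention `GRanges` uses. The `name` column (4th field) is
#' kept in `mcols(x)$name` — for TF ChIP-seq atlases it carries the TF
#' symbol — and narrowPeak's `signalValue` is kept as `mcols(x)$signal`.
#'
#' @param path Path to the peak file.
#' @param format One of `"auto"`, `"bed3"`, `"bed6"`, `"narrowPeak"`.
#'   `"auto"` infers the format from the column count (3, 4-6, or 10).
#' @return A `GRanges` with metadata columns `name` (character, `NA` when
#'   absent) and `signal` (numeric, `NA` when absent).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tpk1", "chr1\t500\t800\tpk2"), bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, format = c("auto", "bed3", "bed6", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(.bed0_to_granges(character(), integer(), integer(),
                            name = character(), signal = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], ": fewer than 3 tab-separated fields")
  }
  if (format == "auto") {
    format <- if (all(nf >= 10L)) "narrowPeak" else if (all(nf >= 4L)) "bed6" else "bed3"
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    stop("malformed BED line ", which(is.na(start0) | is.na(end0))[1L],
         ": non-integer coordinates")
  }
  if (any(start0 < 0L)) {
    stop("invalid interval at line ", which(start0 < 0L)[1L],
         ": negative start coordinate")
  }
  if (any(end0 <= start0)) {
    stop("invalid interval at line ", which(end0 <= start0)[1L],
         ": start >= end (intervals must have positive width)")
  }
  name <- rep(NA_character_, length(lines))
  signal <- rep(NA_real_, length(lines))
  strand <- rep("*", length(lines))
  if (format %in% c("bed6", "narrowPeak")) {
    has4 <- nf >= 4L
    name[has4] <- vapply(fields[has4], `[[`, character(1), 4L)
    has6 <- nf >= 6L
    s <- vapply(fields[has6], `[[`, character(1), 6L)
    s[!s %in% c("+", "-")] <- "*"
    strand[has6] <- s
  }
  if (format == "narrowPeak") {
    if (any(nf < 10L)) stop("narrowPeak requires 10 fields; line ",
                            which(nf < 10L)[1L], " has fewer")
    signal <- as.numeric(vapply(fields, `[[`, character(1), 7L))
  }
  .bed0_to_granges(chrom, start0, end0, strand = strand,
                   name = name, signal = signal)
}

#' Write peaks as BED
#'
#' Inverse of [read_bed()]: writes a `GRanges` as BED with 0-based half-open
#' coordinates. A `name` metadata column, when present, becomes the 4th field.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  df <- .granges_to_bed0(gr)
  if (!is.null(gr$name)) df$name <- gr$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pairwise overlap length of two interval vectors
#'
#' The number of shared bases between `a[i]` and `b[i]`. Zero when the
#' intervals lie on different chromosomes or do not intersect; strand is
#' ignored. This is the primitive behind every "overlaps at least one peak"
#' rule in the pipeline.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return Integer vector of shared base counts.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' overlap_length(a, b)  # 50
#' @export
overlap_length <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  if (n == 0L) return(integer())
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ov <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  as.integer(pmax(0L, ifelse(same, ov, 0L)))
}

#' Pairwise reciprocal overlap fraction
#'
#' `min(shared / width(a), shared / width(b))`: the symmetric overlap
#' stringency used to decide whether two TFs' ChIP-seq peaks occupy the same
#' site. Equals 1 for identical intervals and 0 for disjoint ones.
#'
#' @inheritParams overlap_length
#' @return Numeric vector in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  ov <- overlap_length(a, b)
  n <- length(ov)
  if (n == 0L) return(numeric())
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  pmin(ov / GenomicRanges::width(a), ov / GenomicRanges::width(b))
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, ": missing required column(s): ", paste(missing, collapse = ", "))
  }
}

#' Read a gene-level expression table
#'
#' Tab-separated with header: `gene_id`, `gene_length`, then one column per
#' sample. Values are raw counts or TPM depending on provenance.
#'
#' @param path Path to the TSV.
#' @param unit `"counts"` or `"TPM"`; recorded on the returned object.
#' @return An [ExpressionMatrix] object.
#' @export
read_expression_table <- function(path, unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .require_columns(df, c("gene_id", "gene_length"), "expression table")
  samples <- setdiff(names(df), c("gene_id", "gene_length"))
  if (length(samples) == 0L) stop("expression table: no sample columns")
  values <- as.matrix(df[, samples, drop = FALSE])
  rownames(values) <- df$gene_id
  ExpressionMatrix(values, gene_lengths = df$gene_length, unit = unit)
}

#' Write an expression table
#' @param em An [ExpressionMatrix].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values),
                   gene_length = em$gene_lengths,
                   em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' TSV with columns `sample_id`, `library_type` (`polyA` or `total`) and
#' `is_single_cell` (0/1).
#'
#' @param path Path to the TSV.
#' @return A data.frame with those columns.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("sample_id", "library_type", "is_single_cell"),
                   "sample metadata")
  bad <- !df$library_type %in% c("polyA", "total")
  if (any(bad)) {
    stop("sample metadata: unknown library_type '", df$library_type[bad][1L],
         "' (expected polyA or total)")
  }
  df$is_single_cell <- as.logical(as.integer(df$is_single_cell))
  df
}

#' Read a protein-protein interaction table
#'
#' TSV with columns `protein_a`, `protein_b`, `score` (STRING-style integer
#' confidence in 0..1000). Pairs are unordered; self-interactions and scores
#' outside the range are rejected.
#'
#' @param path Path to the TSV.
#' @return A data.frame `protein_a`, `protein_b`, `score`.
#' @export
read_ppi_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("protein_a", "protein_b", "score"), "PPI table")
  if (any(df$score < 0 | df$score > 1000)) {
    stop("PPI table: score outside [0, 1000] at row ",
         which(df$score < 0 | df$score > 1000)[1L])
  }
  if (any(df$protein_a == df$protein_b)) {
    stop("PPI table: self-interaction at row ",
         which(df$protein_a == df$protein_b)[1L])
  }
  df
}

#' Read promoter annotation
#'
#' TSV with columns `gene_id`, `chrom`, `tss`, `strand`. The `tss` column is
#' the 1-based position of the transcription start base; `strand` is `+` or
#' `-`. A gene may carry several rows (alternative promoters).
#'
#' @param path Path to the TSV.
#' @return A data.frame `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_promoter_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("gene_id", "chrom", "tss", "strand"),
                   "promoter annotation")
  if (any(df$tss < 1)) stop("promoter annotation: tss must be >= 1")
  if (any(!df$strand %in% c("+", "-"))) {
    stop("promoter annotation: strand must be + or -")
  }
  df
}

#' Read enhancer-gene associations
#'
#' GeneHancer-style TSV with columns `enhancer_id`, `chrom`, `start`, `end`
#' (0-based half-open), `gene_id`: each row links one enhancer interval to a
#' putative target gene.
#'
#' @param path Path to the TSV.
#' @return A `GRanges` with metadata columns `enhancer_id` and `gene_id`.
#' @export
read_enhancer_associations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("enhancer_id", "chrom", "start", "end", "gene_id"),
                   "enhancer associations")
  if (any(df$start < 0)) stop("enhancer associations: negative coordinates")
  if (any(df$end <= df$start)) {
    stop("enhancer associations: start >= end at row ",
         which(df$end <= df$start)[1L])
  }
  .bed0_to_granges(df$chrom, df$start, df$end,
                   enhancer_id = df$enhancer_id, gene_id = df$gene_id)
}

#' Read promoter-capture Hi-C interactions
#'
#' 7-column TSV: `chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`,
#' `end_b`, `kind` (anchor coordinates 0-based half-open; `kind` is
#' `promoter-promoter` or `promoter-other`).
#'
#' @param path Path to the TSV.
#' @return A list with `anchor_a`, `anchor_b` (`GRanges` of equal length) and
#'   `kind` (character).
#' @export
read_hic_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("chrom_a", "start_a", "end_a",
                         "chrom_b", "start_b", "end_b", "kind"),
                   "Hi-C interactions")
  list(anchor_a = .bed0_to_granges(df$chrom_a, df$start_a, df$end_a),
       anchor_b = .bed0_to_granges(df$chrom_b, df$start_b, df$end_b),
       kind = df$kind)
}

#' Write a reconstructed core network to disk
#'
#' Emits the three result tables: `edges.tsv` (`source_tf`, `target_tf`,
#' `region_type`, `region_id`, `peak_chrom`, `peak_start`, `peak_end`; one row
#' per supporting peak, peak coordinates 0-based half-open), `nodes.tsv`
#' (`tf`, `role`, `jsd`, `zscore`) and `complexes.tsv` (`region_id`,
#' `complex_id`, `members`, `mode`). Tables are sorted for reproducible
#' diffs: nodes by role then symbol, edges by source, target, region.
#'
#' @param grn A [CoreGRN].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the three files.
#' @export
write_network <- function(grn, dir) {
  stopifnot(inherits(grn, "CoreGRN"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edges <- grn$edges
  edges$peak_start <- edges$peak_start  # already 0-based in the edge table
  edges <- edges[order(edges$source_tf, edges$target_tf, edges$region_id,
                       edges$peak_start), , drop = FALSE]
  nodes <- grn$nodes
  nodes <- nodes[order(match(nodes$role, c("identity", "cofactor")),
                       nodes$tf), , drop = FALSE]
  complexes <- grn$complexes
  complexes <- complexes[order(complexes$region_id, complexes$complex_id),
                         , drop = FALSE]
  paths <- file.path(dir, c("edges.tsv", "nodes.tsv", "complexes.tsv"))
  utils::write.table(edges, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nodes, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(complexes, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a network written by [write_network()]
#' @param dir Directory holding `edges.tsv`, `nodes.tsv`, `complexes.tsv`.
#' @return A [CoreGRN].
#' @export
read_network <- function(dir) {
  read1 <- function(f, cols) {
    df <- utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                            colClasses = NA)
    .require_columns(df, cols, f)
    df
  }
  CoreGRN(
    nodes = read1("nodes.tsv", c("tf", "role", "jsd", "zscore")),
    edges = read1("edges.tsv", c("source_tf", "target_tf", "region_type",
                                 "region_id", "peak_chrom", "peak_start",
                                 "peak_end")),
    complexes = read1("complexes.tsv", c("region_id", "complex_id",
                                         "members", "mode"))
  )
}

#' Warn when two interval sets share no chromosome names
#'
#' Chromosome names are matched as exact strings throughout; a `chr1` vs `1`
#' naming mismatch silently empties every overlap. This preflight check makes
#' that loud.
#'
#' @param a,b `GRanges` (or anything with `seqnames`).
#' @param what Label used in the warning.
#' @return Invisibly, `TRUE` when at least one name is shared.
#' @export
check_shared_chromosomes <- function(a, b, what = "input sets") {
  ca <- unique(as.character(GenomicRanges::seqnames(a)))
  cb <- unique(as.character(GenomicRanges::seqnames(b)))
  shared <- length(intersect(ca, cb)) > 0L
  if (!shared && length(ca) > 0L && length(cb) > 0L) {
    warning(what, " share zero chromosome names; ",
            "check chr-prefix conventions", call. = FALSE)
  }
  invisible(shared)
}
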