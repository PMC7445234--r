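#' Gene-by-sample expression matrix with gene lengths
#'
#' Lightweight container used throughout the pipeline: a numeric matrix of
#' non-negative values (genes in rows, samples in columns), the gene lengths
#' in base pairs needed for TPM normalisation, and the unit of the values.
#'
#' @param values Numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param gene_lengths Positive integer vector, one per gene, aligned to the
#'   rows of `values`.
#' @param unit `"counts"` or `"TPM"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(values, gene_lengths, unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (ncol(values) > 0L && is.null(colnames(values))) {
    stop("values must have sample ids as colnames")
  }
  if (ncol(values) == 0L) colnames(values) <- character()
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (length(gene_lengths) != nrow(values)) {
    stop("gene_lengths must align with the rows of values")
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  structure(list(values = values,
                 gene_lengths = as.numeric(gene_lengths),
                 unit = unit),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# subset by sample ids (keeps gene lengths aligned)
.em_select_samples <- function(em, sample_ids) {
  ExpressionMatrix(em$values[, sample_ids, drop = FALSE],
                   em$gene_lengths, unit = em$unit)
}

#' Decorrelated background expression set
#'
#' Result of [decorrelate()]: the retained samples (in the order they were
#' accepted by the greedy pass), the correlation ceiling, the RNG seed, and
#' the library type when known.
#'
#' @param matrix An [ExpressionMatrix] restricted to the retained samples.
#' @param retained_order Character vector of sample ids in acceptance order.
#' @param r_max Pearson correlation ceiling used during selection.
#' @param seed Integer seed that drove the greedy pass.
#' @param library_type `"polyA"`, `"total"` or `NA`.
#' @return An object of class `BackgroundSet`.
#' @export
BackgroundSet <- function(matrix, retained_order, r_max, seed,
                          library_type = NA_character_) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  stopifnot(identical(sort(colnames(matrix$values)), sort(retained_order)))
  structure(list(matrix = matrix,
                 retained_order = retained_order,
                 r_max = r_max,
                 seed = as.integer(seed),
                 library_type = library_type),
            class = "BackgroundSet")
}

#' @export
print.BackgroundSet <- function(x, ...) {
  cat(sprintf("BackgroundSet: %d samples (%s), r < %.2f, seed %d\n",
              length(x$retained_order),
              ifelse(is.na(x$library_type), "library type unknown",
                     x$library_type),
              x$r_max, x$seed))
  invisible(x)
}

#' Reconstructed core gene regulatory network
#'
#' Holds the three result tables of a reconstruction: `nodes` (`tf`, `role`,
#' `jsd`, `zscore`), `edges` (`source_tf`, `target_tf`, `region_type`,
#' `region_id`, `peak_chrom`, `peak_start`, `peak_end`; one row per
#' supporting ChIP-seq peak, coordinates 0-based half-open) and `complexes`
#' (`region_id`, `complex_id`, `members`, `mode`).
#'
#' @param nodes,edges,complexes Data frames as described above.
#' @return An object of class `CoreGRN`.
#' @export
CoreGRN <- function(nodes, edges, complexes = NULL) {
  if (is.null(complexes)) {
    complexes <- data.frame(region_id = character(), complex_id = character(),
                            members = character(), mode = character(),
                            stringsAsFactors = FALSE)
  }
  if (!all(c("tf", "role") %in% names(nodes))) stop("nodes needs tf, role")
  if (is.null(nodes$jsd)) nodes$jsd <- rep(NA_real_, nrow(nodes))
  if (is.null(nodes$zscore)) nodes$zscore <- rep(NA_real_, nrow(nodes))
  need <- c("source_tf", "target_tf", "region_type", "region_id",
            "peak_chrom", "peak_start", "peak_end")
  miss <- setdiff(need, names(edges))
  if (length(miss) > 0L) stop("edges missing column(s): ",
                              paste(miss, collapse = ", "))
  structure(list(nodes = nodes, edges = edges, complexes = complexes),
            class = "CoreGRN")
}

#' @export
print.CoreGRN <- function(x, ...) {
  uniq <- unique(x$edges[, c("source_tf", "target_tf")])
  cat(sprintf(paste0("CoreGRN: %d TFs (%d identity, %d co-factor), ",
                     "%d directed edges (%d support peaks), %d complex calls\n"),
              nrow(x$nodes), sum(x$nodes$role == "identity"),
              sum(x$nodes$role == "cofactor"),
              nrow(uniq), nrow(x$edges), nrow(x$complexes)))
  invisible(x)
}
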