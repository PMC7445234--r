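#' Default pipeline configuration
#'
#' Returns the full parameter set with its defaults: `n_top = 10` identity
#' TFs, co-factor threshold `z_cut = -1.5`, library-size floor
#' `min_counts = 15000`, background correlation ceiling `r_max = 0.7`,
#' promoter window `up = 1500` / `down = 500` bp, PPI confidence floor
#' `ppi_min = 800`, reciprocal-overlap floor `ro_min = 0.62`, `seed = 1`,
#' and mandatory accessibility gating (`dnase_required = TRUE`).
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(n_top = 10, z_cut = -1.5, min_counts = 15000, r_max = 0.7,
       up = 1500, down = 500, ppi_min = 800, ro_min = 0.62, seed = 1L,
       dnase_required = TRUE, query_sample = "query")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of input paths and parameters, fills unset parameters
#' from [default_config()], applies `overrides`, and validates that every
#' referenced input path exists.
#'
#' @param path YAML file. Recognised path keys: `expression`, `metadata`,
#'   `tf_list`, `promoters`, `enhancers`, `h3k4me3`, `h3k27ac`, `dnase`,
#'   `chip_atlas`, `ppi`, optional `hic`, `gold_edges`, plus `out_dir`.
#' @param overrides Named list overriding file values (e.g. from CLI flags).
#' @return A validated config list.
#' @export
load_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  validate_config(cfg)
}

#' Validate a pipeline configuration list
#' @param cfg Named list of paths and parameters.
#' @return The config, with defaults filled in.
#' @export
validate_config <- function(cfg) {
  cfg <- utils::modifyList(default_config(), cfg)
  required <- c("expression", "metadata", "tf_list", "promoters",
                "enhancers", "h3k4me3", "h3k27ac", "chip_atlas", "ppi")
  if (isTRUE(cfg$dnase_required)) required <- c(required, "dnase")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0L) {
    stop("config error: missing input path(s): ",
         paste(missing, collapse = ", "))
  }
  for (key in intersect(c(required, "dnase", "hic", "gold_edges"),
                        names(cfg))) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config error: ", key, " path does not exist: ", cfg[[key]])
    }
  }
  stopifnot(cfg$n_top >= 1, cfg$min_counts >= 0, cfg$r_max > 0,
            cfg$up > 0, cfg$down > 0, cfg$ppi_min >= 0, cfg$ppi_min <= 1000,
            cfg$ro_min >= 0, cfg$ro_min <= 1)
  cfg
}

.stage <- function(name, expr) {
  message("[", name, "] starting")
  tryCatch(expr, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full core-network reconstruction pipeline
#'
#' Executes the four-stage workflow: (1) background assembly — library-size
#' and single-cell filtering, library-type split, greedy decorrelation, TPM
#' normalisation; (2) specificity — per-TF JSD against the background,
#' identity-TF and co-factor calls; (3) regulatory regions — promoter
#' windows, H3K4me3 activity, GeneHancer-style enhancer linkage with
#' H3K27ac truncation, DNase accessibility gating; (4) network — ChIP-seq
#' scaffold, co-factor connectivity filtering, cooperative/competitive
#' complex calls. Optionally (5) evaluation against a gold-standard edge
#' set and promoter-capture Hi-C interactions. Each stage logs its counts
#' and writes its table under `cfg[["out_dir"]]` when set.
#'
#' @param cfg Config list (see [validate_config()] / [load_run_config()]).
#' @return A list: `grn` ([CoreGRN]), `scores` (specificity table),
#'   `background` ([BackgroundSet]), `regions` (regulatory-region stage
#'   output), `scaffold` (pre-filter support records), `metrics` (list,
#'   possibly empty).
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  out_dir <- cfg[["out_dir"]]
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  ## stage 1: background atlas
  bgres <- .stage("background", {
    em <- read_expression_table(cfg$expression, unit = "counts")
    metadata <- read_sample_metadata(cfg$metadata)
    if (!cfg$query_sample %in% colnames(em$values)) {
      stop("query sample '", cfg$query_sample, "' not in expression table")
    }
    query_counts <- .em_select_samples(em, cfg$query_sample)
    bg_counts <- .em_select_samples(
      em, setdiff(colnames(em$values), cfg$query_sample))
    bg_counts <- filter_samples(bg_counts, metadata,
                                min_counts = cfg$min_counts)
    by_type <- split_by_library_type(bg_counts, metadata)
    qtype <- metadata$library_type[metadata$sample_id == cfg$query_sample]
    if (length(qtype) != 1L) stop("query sample missing from metadata")
    chosen <- by_type[[qtype]]
    if (ncol(chosen$values) == 0L) {
      stop("no background samples with library type ", qtype)
    }
    bg <- decorrelate(chosen, r_max = cfg$r_max, seed = cfg$seed)
    bg$library_type <- qtype
    message("[background] retained ", length(bg$retained_order), " of ",
            ncol(chosen$values), " ", qtype, " samples")
    list(background = bg,
         background_tpm = counts_to_tpm(bg$matrix),
         query_tpm = counts_to_tpm(query_counts))
  })

  ## stage 2: specificity
  scores <- .stage("specificity", {
    tf_symbols <- readLines(cfg$tf_list)
    tf_symbols <- tf_symbols[nzchar(tf_symbols)]
    s <- specificity_scores(
      query_tpm = bgres$query_tpm$values[, 1L],
      background_tpm = bgres$background_tpm$values,
      tf_symbols = tf_symbols,
      n_top = cfg$n_top, z_cut = cfg$z_cut)
    message("[specificity] scored ", nrow(s), " TFs; ",
            sum(s$call == "identity"), " identity, ",
            sum(s$call == "cofactor"), " co-factor")
    if (!is.null(out_dir)) {
      utils::write.table(s, file.path(out_dir, "scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    s
  })
  identity_tfs <- scores$tf[scores$call == "identity"]
  cofactors <- scores$tf[scores$call == "cofactor"]
  candidates <- c(identity_tfs, cofactors)

  ## stage 3: regulatory regions
  regres <- .stage("regions", {
    promoters <- read_promoter_annotation(cfg$promoters)
    associations <- read_enhancer_associations(cfg$enhancers)
    h3k4me3 <- read_bed(cfg$h3k4me3)
    h3k27ac <- read_bed(cfg$h3k27ac)
    dnase <- if (!is.null(cfg[["dnase"]])) read_bed(cfg[["dnase"]]) else NULL
    pw <- build_promoter_window(
      promoters[promoters$gene_id %in% candidates, , drop = FALSE])
    check_shared_chromosomes(pw, h3k4me3,
                             "promoter annotation and H3K4me3 peaks")
    r <- build_regulatory_regions(
      candidates, promoters, associations, h3k4me3, h3k27ac, dnase,
      up = cfg$up, down = cfg$down, dnase_required = cfg$dnase_required)
    message("[regions] ", length(r$active_tfs), " of ", length(candidates),
            " candidate TFs have an active promoter; ",
            length(unique(r$regions$region_id[r$regions$region_type ==
                                                "enhancer"])),
            " active enhancers; ", length(r$sites), " accessible sites")
    if (!is.null(out_dir)) {
      utils::write.table(regions_table(r$regions, r$sites),
                         file.path(out_dir, "regions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    r
  })

  ## stage 4: network
  grn <- .stage("network", {
    chip <- .read_chip_atlas(cfg$chip_atlas)
    ppi <- read_ppi_table(cfg$ppi)
    scaffold <- build_scaffold(regres$sites, chip, candidates)
    message("[network] scaffold: ",
            nrow(unique(scaffold[, c("source_tf", "target_tf")])),
            " directed edges (", nrow(scaffold), " support records)")
    g <- filter_cofactor_connectivity(scaffold, identity_tfs, cofactors,
                                      scores = scores)
    g$complexes <- classify_all_regions(g$edges, ppi,
                                        ppi_min = cfg$ppi_min,
                                        ro_min = cfg$ro_min)
    message("[network] after co-factor filter: ", nrow(g$nodes), " TFs, ",
            nrow(unique(g$edges[, c("source_tf", "target_tf")])),
            " directed edges; ",
            sum(g$complexes$mode == "cooperative"), " cooperative complexes")
    attr(g, "scaffold") <- scaffold
    if (!is.null(out_dir)) write_network(g, out_dir)
    g
  })

  ## stage 5: evaluation (optional)
  metrics <- list()
  if (!is.null(cfg[["gold_edges"]]) || !is.null(cfg[["hic"]])) {
    metrics <- .stage("evaluation", {
      m <- list()
      if (!is.null(cfg[["gold_edges"]])) {
        gold <- utils::read.delim(cfg[["gold_edges"]], stringsAsFactors = FALSE)
        .require_columns(gold, c("source_tf", "target_tf"), "gold edges")
        gold <- gold[gold$source_tf %in% grn$nodes$tf &
                       gold$target_tf %in% grn$nodes$tf, , drop = FALSE]
        m <- c(m, edge_f1(grn$edges, gold, directed_prediction = TRUE))
      }
      if (!is.null(cfg[["hic"]])) {
        hic <- read_hic_interactions(cfg[["hic"]])
        enh <- regres$enhancers_raw[
          regres$enhancers_raw$gene_id %in% grn$nodes$tf]
        m$pct_enhancers_validated <- validate_enhancer_assignments(
          enh, regres$promoter_windows, hic)
      }
      if (!is.null(out_dir)) {
        jsonlite::write_json(m, file.path(out_dir, "metrics.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      m
    })
  }

  list(grn = grn, scores = scores, background = bgres$background,
       regions = regres, scaffold = attr(grn, "scaffold"), metrics = metrics)
}

# ChIP atlas: either one BED whose name column is the TF symbol, or a
# directory of <TF>.bed files.
.read_chip_atlas <- function(path) {
  if (dir.exists(path)) {
    beds <- list.files(path, pattern = "\\.(bed|narrowPeak)$",
                       full.names = TRUE)
    if (length(beds) == 0L) stop("no BED files in ChIP atlas directory ", path)
    atlas <- lapply(beds, read_bed)
    names(atlas) <- sub("\\.(bed|narrowPeak)$", "", basename(beds))
    return(atlas)
  }
  chip <- read_bed(path)
  if (all(is.na(chip$name))) {
    stop("ChIP atlas BED needs a name column carrying the TF symbol")
  }
  chip
}
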