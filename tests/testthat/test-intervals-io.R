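test_that("read_bed maps fields and rejects invalid intervals", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr2\t0\t50"), bed)
  gr <- read_bed(bed)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), c("chr1", "chr2"))
  expect_equal(GenomicRanges::start(gr) - 1L, c(100L, 0L))  # 0-based starts
  expect_equal(GenomicRanges::end(gr), c(200L, 50L))
  expect_equal(GenomicRanges::width(gr), c(100L, 50L))

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t10\t110\tpk1\t0\t.\t8.5\t-1\t-1\t50", np)
  peak <- read_bed(np, format = "narrowPeak")
  expect_equal(peak$signal, 8.5)
  expect_equal(peak$name, "pk1")

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), bad)
  expect_error(read_bed(bad), "line 2")
  writeLines("chr1\t-5\t100", bad)
  expect_error(read_bed(bad), "negative")
  writeLines("chr1\t100\t100", bad)
  expect_error(read_bed(bad), "positive width")
})

test_that("overlap_length matches its closed form on the worked cases", {
  expect_equal(overlap_length(gr0("chr1", 100, 200), gr0("chr1", 150, 250)), 50L)
  # half-open abutment shares no base
  expect_equal(overlap_length(gr0("chr1", 100, 200), gr0("chr1", 200, 300)), 0L)
  expect_equal(overlap_length(gr0("chr1", 100, 200), gr0("chr2", 100, 200)), 0L)
})

test_that("reciprocal_overlap matches hand-derived values", {
  expect_equal(reciprocal_overlap(gr0("chr1", 100, 200), gr0("chr1", 100, 200)), 1.0)
  expect_equal(reciprocal_overlap(gr0("chr1", 100, 200), gr0("chr1", 150, 250)), 0.5)
  expect_equal(reciprocal_overlap(gr0("chr1", 0, 1000), gr0("chr1", 0, 100)), 0.1)
})

test_that("overlap_length is symmetric and bounds reciprocal_overlap", {
  withr::with_seed(7, {
    a <- random_intervals(500)
    b <- random_intervals(500)
  })
  ga <- gr0(a$chrom, a$start, a$end)
  gb <- gr0(b$chrom, b$start, b$end)
  ov_ab <- overlap_length(ga, gb)
  expect_identical(ov_ab, overlap_length(gb, ga))
  # definitional identity: the min of the two fractions is ov / max(width)
  expect_equal(reciprocal_overlap(ga, gb),
               ov_ab / pmax(a$end - a$start, b$end - b$start))
  # and it never exceeds the larger fraction ov / min(width)
  expect_true(all(reciprocal_overlap(ga, gb) <=
                    ov_ab / pmin(a$end - a$start, b$end - b$start)))
})

test_that("tabular readers enforce their schemas", {
  ppi <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tscore", "A\tB\t900"), ppi)
  expect_equal(read_ppi_table(ppi)$score, 900)
  writeLines(c("protein_a\tprotein_b\tscore", "A\tB\t1001"), ppi)
  expect_error(read_ppi_table(ppi), "\\[0, 1000\\]")
  writeLines(c("protein_a\tprotein_b\tscore", "A\tA\t500"), ppi)
  expect_error(read_ppi_table(ppi), "self-interaction")
  writeLines(c("protein_a\tprotein_b", "A\tB"), ppi)
  expect_error(read_ppi_table(ppi), "score")

  enh <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("enhancer_id\tchrom\tstart\tend\tgene_id",
               "E1\tchr1\t500\t400\tG1"), enh)
  expect_error(read_enhancer_associations(enh), "start >= end")

  md <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlibrary_type\tis_single_cell",
               "S1\tscRNA\t0"), md)
  expect_error(read_sample_metadata(md), "library_type")
})

test_that("a network round-trips losslessly through write/read", {
  nodes <- data.frame(tf = c("A", "B", "C"),
                      role = c("identity", "identity", "cofactor"),
                      jsd = c(0, 0.1, 0.3), zscore = c(-1.7, -1.7, -1.6),
                      stringsAsFactors = FALSE)
  edges <- make_edges(c("A", "B", "C"), c("B", "C", "A"),
                      peak_start = c(10L, 20L, 30L),
                      peak_end = c(110L, 120L, 130L))
  cx <- data.frame(region_id = "B:prom1", complex_id = "B:prom1:c1",
                   members = "A,C", mode = "cooperative",
                   stringsAsFactors = FALSE)
  grn <- CoreGRN(nodes, edges, cx)
  dir <- withr::local_tempdir()
  write_network(grn, dir)
  back <- read_network(dir)
  expect_setequal(do.call(paste, back$edges), do.call(paste, edges))
  expect_setequal(back$nodes$tf, nodes$tf)
  expect_equal(back$complexes$members, "A,C")
})

test_that("an empty network writes valid header-only tables", {
  grn <- CoreGRN(data.frame(tf = character(), role = character()),
                 make_edges(character(), character()))
  dir <- withr::local_tempdir()
  write_network(grn, dir)
  back <- read_network(dir)
  expect_equal(nrow(back$edges), 0L)
  expect_equal(nrow(back$nodes), 0L)
  expect_equal(nrow(back$complexes), 0L)
})

test_that("expression tables round-trip", {
  em <- ExpressionMatrix(matrix(c(1, 2, 3, 4), 2,
                                dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                         gene_lengths = c(1000, 2000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em, path)
  back <- read_expression_table(path)
  expect_equal(back$values, em$values)
  expect_equal(back$gene_lengths, em$gene_lengths)
})

test_that("disjoint chromosome naming triggers the preflight warning", {
  expect_warning(
    check_shared_chromosomes(gr0("chr1", 0, 10), gr0("1", 0, 10)),
    "zero chromosome names")
  expect_silent(check_shared_chromosomes(gr0("chr1", 0, 10),
                                         gr0("chr1", 5, 15)))
})
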