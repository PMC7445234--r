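prom_df <- function(gene_id, chrom, tss, strand) {
  data.frame(gene_id = gene_id, chrom = chrom, tss = tss, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("promoter windows cover 1500 bp upstream and 500 bp downstream", {
  # + strand, TSS at 0-based 10000 (1-based 10001): [8500, 10500) 0-based
  w <- build_promoter_window(prom_df("A", "chr1", 10001, "+"))
  expect_equal(GenomicRanges::start(w) - 1L, 8500L)
  expect_equal(GenomicRanges::end(w), 10500L)
  expect_equal(GenomicRanges::width(w), 2000L)
  # - strand mirror: [9501, 11501) 0-based
  wm <- build_promoter_window(prom_df("A", "chr1", 10001, "-"))
  expect_equal(GenomicRanges::start(wm) - 1L, 9501L)
  expect_equal(GenomicRanges::end(wm), 11501L)
  expect_equal(GenomicRanges::width(wm), 2000L)
  # clipping at the chromosome start
  wc <- build_promoter_window(prom_df("A", "chr1", 101, "+"))
  expect_equal(GenomicRanges::start(wc) - 1L, 0L)
  expect_equal(GenomicRanges::end(wc), 600L)
})

test_that("multiple promoters of one gene get distinct region ids", {
  w <- build_promoter_window(prom_df(c("A", "A", "B"), "chr1",
                                     c(10001, 50001, 90001), "+"))
  expect_equal(w$region_id, c("A:prom1", "A:prom2", "B:prom1"))
})

test_that("promoter activity needs >= 1 shared base with an H3K4me3 peak", {
  w <- build_promoter_window(prom_df(c("A", "B", "C"), "chr1",
                                     c(10001, 10001, 10001),
                                     c("+", "+", "+")))
  # peak overlapping the tail by 100 bases; abutting peak; and none
  expect_equal(call_active_promoters(w[1], gr0("chr1", 10400, 10600)), TRUE)
  expect_equal(call_active_promoters(w[2], gr0("chr1", 10500, 10600)), FALSE)
  expect_equal(call_active_promoters(w, GenomicRanges::GRanges()),
               c(FALSE, FALSE, FALSE))
})

test_that("enhancers are gated on the owner's promoter and truncated to peaks", {
  assoc <- gr0("chr1", c(1000, 5000), c(2000, 6000),
               enhancer_id = c("E1", "E2"), gene_id = c("A", "B"))
  k27 <- gr0("chr1", c(1500, 5100), c(2500, 5200))
  # only A's promoter is active: B's enhancer is never evaluated
  act <- call_active_enhancers(assoc, active_tfs = "A", h3k27ac = k27)
  expect_equal(act$region_id, "E1")
  expect_equal(GenomicRanges::start(act) - 1L, 1500L)  # truncated to [1500,2000)
  expect_equal(GenomicRanges::end(act), 2000L)

  # two disjoint peaks produce two truncated intervals of one enhancer
  k27b <- gr0("chr1", c(1100, 1800), c(1300, 1900))
  act2 <- call_active_enhancers(assoc, "A", k27b)
  expect_equal(length(act2), 2L)
  expect_equal(unique(act2$region_id), "E1")

  # no H3K27ac anywhere: nothing is emitted
  act3 <- call_active_enhancers(assoc, c("A", "B"), GenomicRanges::GRanges())
  expect_equal(length(act3), 0L)
})

test_that("accessible sites are intersections contained in their regions", {
  regions <- gr0("chr1", 8500, 10500, owner_tf = "A",
                 region_id = "A:prom1", region_type = "promoter")
  sites <- compute_accessible_sites(regions, gr0("chr1", 10000, 11000))
  expect_equal(GenomicRanges::start(sites) - 1L, 10000L)
  expect_equal(GenomicRanges::end(sites), 10500L)
  # DNase peak covering the whole region: site equals the region
  sites2 <- compute_accessible_sites(regions, gr0("chr1", 8000, 11000))
  expect_equal(GenomicRanges::ranges(sites2), GenomicRanges::ranges(regions))
  # no overlap: no sites (region remains, supports no edges)
  expect_equal(length(compute_accessible_sites(regions,
                                               gr0("chr1", 20000, 21000))), 0L)
})

test_that("every accessible site lies within its region on random fixtures", {
  withr::with_seed(29, {
    for (rep in seq_len(20)) {
      r <- random_intervals(15, max_pos = 5000, max_width = 800)
      d <- random_intervals(25, max_pos = 5000, max_width = 400)
      regions <- gr0(r$chrom, r$start, r$end,
                     owner_tf = sprintf("T%02d", seq_len(15)),
                     region_id = sprintf("R%02d", seq_len(15)),
                     region_type = "promoter")
      sites <- compute_accessible_sites(regions, gr0(d$chrom, d$start, d$end))
      if (length(sites) == 0) next
      parent <- regions[match(sites$region_id, regions$region_id)]
      expect_true(all(overlap_length(sites, parent) ==
                        GenomicRanges::width(sites)))
    }
  })
})

test_that("the DNase gate is mandatory unless explicitly relaxed", {
  prom <- prom_df("A", "chr1", 10001, "+")
  assoc <- gr0("chr1", 1000, 2000, enhancer_id = "E1", gene_id = "A")
  k4 <- gr0("chr1", 8500, 10500)
  k27 <- gr0("chr1", 1500, 2500)
  expect_error(build_regulatory_regions("A", prom, assoc, k4, k27,
                                        dnase = NULL),
               "accessibility")
  expect_message(
    r <- build_regulatory_regions("A", prom, assoc, k4, k27, dnase = NULL,
                                  dnase_required = FALSE),
    "gating disabled")
  # without gating, every region interval is its own accessible site
  expect_equal(length(r$sites), length(r$regions))
})
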