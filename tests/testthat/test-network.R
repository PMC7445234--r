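site1 <- function() {
  gr0("chr1", 10000, 10500, owner_tf = "Y", region_id = "Y:prom1",
      region_type = "promoter")
}

test_that("scaffold edges need a ChIP peak overlapping an accessible site", {
  chip <- gr0("chr1", 10050, 10250, name = "X")
  # Y has no peaks in the atlas: warns once, then proceeds
  expect_warning(edges <- build_scaffold(site1(), chip,
                                         candidates = c("X", "Y")),
                 "Y")
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$source_tf, "X")
  expect_equal(edges$target_tf, "Y")
  expect_equal(edges$region_type, "promoter")
  expect_equal(edges$peak_start, 10050L)  # original peak, not the intersection

  # empty site list (no accessibility): no edges at all
  empty_sites <- site1()[0]
  expect_equal(nrow(suppressWarnings(
    build_scaffold(empty_sites, chip, c("X", "Y")))), 0L)

  # peak outside the site: no edge
  far <- gr0("chr1", 20000, 20200, name = "X")
  expect_equal(nrow(suppressWarnings(
    build_scaffold(site1(), far, c("X", "Y")))), 0L)
})

test_that("scaffold only consults candidate TFs and warns on missing ones", {
  chip <- gr0("chr1", c(10050, 10050), c(10250, 10250), name = c("X", "Z"))
  # Z is not a candidate: its peak must not create an edge
  edges <- suppressWarnings(build_scaffold(site1(), chip, c("X", "Y")))
  expect_equal(unique(edges$source_tf), "X")
  expect_warning(build_scaffold(site1(), chip, c("X", "Y", "W")),
                 "W")
})

test_that("duplicate evidence collapses; self-edges are permitted", {
  sites <- c(site1(), gr0("chr1", 10300, 10450, owner_tf = "Y",
                          region_id = "Y:prom1", region_type = "promoter"))
  chip <- gr0("chr1", 10050, 10400, name = "Y")
  edges <- build_scaffold(sites, chip, candidates = "Y")
  expect_equal(nrow(edges), 1L)   # one peak hitting two sites of one region
  expect_equal(edges$source_tf, edges$target_tf)  # autoregulation kept
})

test_that("co-factor connectivity pruning follows the hand-traced cases", {
  # identity {A}; B->A and A->B qualify B; C regulates only the co-factor B
  e1 <- make_edges(c("B", "A", "C"), c("A", "B", "B"))
  g1 <- filter_cofactor_connectivity(e1, "A", c("B", "C"))
  expect_setequal(g1$nodes$tf, c("A", "B"))
  expect_false("C" %in% g1$edges$source_tf)

  # C->A present but nothing regulates C: fails the incoming condition
  e2 <- make_edges(c("C", "B", "A"), c("A", "A", "B"))
  g2 <- filter_cofactor_connectivity(e2, "A", c("B", "C"))
  expect_false("C" %in% g2$nodes$tf)

  # no co-factors: identity network passes through unchanged
  e3 <- make_edges(c("A", "B"), c("B", "A"))
  g3 <- filter_cofactor_connectivity(e3, c("A", "B"), character())
  expect_equal(nrow(g3$edges), 2L)
})

test_that("pruning cascades: removing one co-factor can disqualify another", {
  # B qualifies only through C's edges? construct: identity {A};
  # C: C->A, A->C (qualifies while present)... make C depend on B instead:
  # B: B->A, A->B qualifies; C: C->A but incoming only from B, so C falls;
  # then D: D->C, C->D depended entirely on C and falls next.
  e <- make_edges(c("B", "A", "C", "B", "D", "C"),
                  c("A", "B", "A", "C", "C", "D"))
  g <- filter_cofactor_connectivity(e, "A", c("B", "C", "D"))
  expect_setequal(g$nodes$tf, c("A", "B"))
})

test_that("binding classification follows the reciprocal-overlap and PPI rules", {
  ppi <- data.frame(protein_a = c("U", "U"), protein_b = c("V", "W"),
                    score = c(850L, 999L), stringsAsFactors = FALSE)
  # identical peaks (ro = 1), PPI 850 > 800: cooperative pair
  e <- make_edges(c("U", "V"), "Y", peak_start = c(100L, 100L),
                  peak_end = c(300L, 300L))
  cls <- classify_binding(e, ppi)
  expect_equal(cls$cooperative, list(c("U", "V")))

  # ro = 0.5 fails the 62% rule even at PPI 999: competitive
  e2 <- make_edges(c("U", "W"), "Y", peak_start = c(100L, 200L),
                   peak_end = c(300L, 400L))
  cls2 <- classify_binding(e2, ppi)
  expect_equal(cls2$cooperative, list())
  expect_setequal(cls2$competitive, c("U", "W"))

  # overlapping peaks without any PPI record: competitive, not cooperative
  e3 <- make_edges(c("U", "Z"), "Y", peak_start = c(100L, 100L),
                   peak_end = c(300L, 300L))
  cls3 <- classify_binding(e3, ppi)
  expect_setequal(cls3$competitive, c("U", "Z"))

  # disjoint peaks: independent
  e4 <- make_edges(c("U", "V"), "Y", peak_start = c(100L, 500L),
                   peak_end = c(300L, 700L))
  cls4 <- classify_binding(e4, ppi)
  expect_setequal(cls4$independent, c("U", "V"))
})

test_that("cooperative complexes extend through connected components", {
  ppi <- data.frame(protein_a = c("U", "V"), protein_b = c("V", "W"),
                    score = c(850L, 900L), stringsAsFactors = FALSE)
  # U-V ro 0.8, V-W ro 0.7, U-W ro 0.5: one complex {U, V, W} by connectivity
  e <- make_edges(c("U", "V", "W"), "Y",
                  peak_start = c(100L, 120L, 150L),
                  peak_end = c(200L, 220L, 250L))
  # check the planted overlaps first
  u <- gr0("chr1", 100, 200); v <- gr0("chr1", 120, 220); w <- gr0("chr1", 150, 250)
  expect_equal(reciprocal_overlap(u, v), 0.8)
  expect_equal(reciprocal_overlap(v, w), 0.7)
  expect_equal(reciprocal_overlap(u, w), 0.5)
  cls <- classify_binding(e, ppi)
  expect_equal(cls$cooperative, list(c("U", "V", "W")))
})

test_that("classification partitions the bound TFs of a region", {
  withr::with_seed(31, {
    for (rep in seq_len(25)) {
      n <- sample(2:6, 1)
      tfs <- LETTERS[seq_len(n)]
      iv <- random_intervals(n, max_pos = 600, max_width = 250,
                             chroms = "chr1")
      e <- make_edges(tfs, "Y", peak_start = iv$start, peak_end = iv$end)
      pairs <- t(utils::combn(tfs, 2))
      ppi <- data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
                        score = sample(600:1000, nrow(pairs), replace = TRUE),
                        stringsAsFactors = FALSE)
      cls <- classify_binding(e, ppi)
      all_called <- c(unlist(cls$cooperative), cls$competitive,
                      cls$independent)
      expect_setequal(all_called, tfs)
      expect_equal(length(all_called), n)  # disjoint cover, no TF twice
    }
  })
})

test_that("threshold calibration separates labelled overlap samples", {
  cal <- calibrate_overlap_threshold(c(0.7, 0.8, 0.9), c(0.1, 0.2, 0.3))
  expect_equal(cal$threshold, 0.7)
  expect_equal(calibrate_overlap_threshold(rep(1, 4), rep(0, 4))$threshold, 1)
  expect_error(calibrate_overlap_threshold(c(0.2, 0.5), c(0.2, 0.5)),
               "not separable")
  expect_error(calibrate_overlap_threshold(numeric(), c(0.1)), "nonempty")
})

test_that("pair overlaps pool the best reciprocal overlap per cell type", {
  atlas <- list(
    ct1 = list(U = gr0("chr1", c(0, 1000), c(100, 1100)),
               V = gr0("chr1", 50, 150)),
    ct2 = list(U = gr0("chr1", 0, 100), V = gr0("chr1", 500, 600))
  )
  pairs <- data.frame(tf_a = "U", tf_b = "V", stringsAsFactors = FALSE)
  vals <- compute_pair_overlaps(pairs, atlas)
  expect_equal(vals, c(0.5, 0))  # best of ct1's two U peaks; disjoint in ct2
})
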