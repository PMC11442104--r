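reg <- region_spec("chr1", 1, 1000)

test_that("selection keeps clean cultivar-B-specific positions and rejects the rest", {
  a <- pileup_df("chr1", c(100, 200, 300), rep("A", 3),
                 list(c(A = 10), c(A = 5, G = 5), c(A = 10)), region = reg)
  b <- pileup_df("chr1", c(100, 200, 300), rep("A", 3),
                 list(c(G = 12), c(G = 10), c(A = 6, G = 6)), region = reg)
  sites <- select_target_snps(a, b, filters = selection_filters())
  # pos 100: clean homozygous alt; pos 200: cultivar A polymorphic;
  # pos 300: index 0.5 outside [1,1]
  expect_identical(sites$pos, 100L)
  expect_identical(sites$alt, "G")
  expect_identical(sites$index_B, 1)
  expect_identical(sites$label, "homozygous")
})

test_that("multi-allelic cultivar-B positions are rejected", {
  a <- pileup_df("chr1", 100, "A", list(c(A = 20)), region = reg)
  b <- pileup_df("chr1", 100, "A", list(c(G = 10, T = 10)), region = reg)
  f <- selection_filters(index_B_range = c(0, 1), index_B_exclusive = TRUE)
  expect_identical(nrow(select_target_snps(a, b, filters = f)), 0L)
})

test_that("depth bounds apply per cultivar", {
  a <- pileup_df("chr1", c(100, 200), c("A", "A"),
                 list(c(A = 3), c(A = 40)), region = reg)
  b <- pileup_df("chr1", c(100, 200), c("A", "A"),
                 list(c(G = 12), c(G = 12)), region = reg)
  f <- selection_filters(min_depth = 6, max_depth = 30)
  sites <- select_target_snps(a, b, filters = f)
  expect_identical(nrow(sites), 0L)  # pos 100 too shallow in A, 200 too deep
})

test_that("mismatched pileup regions are an explicit error", {
  a <- pileup_df("chr1", 100, "A", list(c(A = 10)), region = reg)
  b <- pileup_df("chr1", 100, "A", list(c(G = 10)),
                 region = region_spec("chr2", 1, 1000))
  expect_error(select_target_snps(a, b), "do not match")
})

test_that("hetero_select applies the dosage interval and relabels", {
  mk <- function(idx, depth) data.frame(
    chrom = "c", pos = seq_along(idx), ref = "A", alt = "G", index_A = 0,
    index_B = idx, depth_A = depth, depth_B = depth,
    label = NA_character_, stringsAsFactors = FALSE)
  # depth 100, ploidy 4 dosage 1: 0.26 inside the simplex interval, 0.90 out
  kept <- hetero_select(mk(c(0.26, 0.90), 100L), 4, 1)
  expect_identical(kept$pos, 1L)
  expect_identical(kept$label, "simplex")
  # depth 5 diploid: interval is [0, 1], everything kept
  kept2 <- hetero_select(mk(c(0, 0.4, 1), 5L), 2, 1)
  expect_identical(nrow(kept2), 3L)
  expect_true(all(kept2$label == "heterozygous_diploid"))
  expect_error(hetero_select(mk(0.5, 10L), 2, 2), "dosage")
})

test_that("hetero_select calibration: retains true dosage, rejects impostors", {
  conf <- 0.95
  for (dos in 1:3) {
    truth <- simulate_snp_sites(800, 100, dos, 4, seed = 100 + dos)
    kept <- hetero_select(truth, 4, dos, conf)
    expect_gte(nrow(kept) / nrow(truth), conf - 0.02)
    for (other in setdiff(1:3, dos)) {
      cross <- hetero_select(truth, 4, other, conf)
      expect_lte(nrow(cross) / nrow(truth), 0.05)
    }
  }
  # spiked homozygous sites leak at most 1 - confidence
  hom <- simulate_snp_sites(400, 100, 1, 4, seed = 9)
  hom$index_B <- rep(c(0, 1), length.out = nrow(hom))
  expect_lte(nrow(hetero_select(hom, 4, 1, conf)) / nrow(hom), 0.05)
})

test_that("progeny filter keeps sites heterozygous in the bulk", {
  sites <- data.frame(chrom = "c", pos = c(10L, 20L, 30L), ref = "A",
                      alt = "G", index_A = 0, index_B = 1,
                      depth_A = 20L, depth_B = 20L, label = "homozygous",
                      stringsAsFactors = FALSE)
  prog <- pileup_df("c", c(10, 20), c("A", "A"),
                    list(c(A = 9, G = 11), c(A = 20)))
  kept <- progeny_filter(sites, prog)
  # 11/20 lies inside the depth-20 interval for Binom(20, 1/2); 0/20 does
  # not; pos 30 is absent from the bulk
  expect_identical(kept$pos, 10L)
})

test_that("tightening filters never adds sites (monotonicity)", {
  spec <- fixture_spec(genome_length = 20000, n_snps = 10, depth = 15,
                       seed = 31)
  ref <- generate_reference(spec)
  fx <- generate_alignments(spec, ref)
  r <- region_spec("chrSim", 1, 20000)
  a <- extract_pileup(fx$sam_A, ref, r)
  b <- extract_pileup(fx$sam_B, ref, r)
  loose <- select_target_snps(a, b, ref, selection_filters(
    min_depth = 4, index_B_range = c(0.5, 1)))
  for (f in list(selection_filters(min_depth = 8, index_B_range = c(0.5, 1)),
                 selection_filters(min_depth = 4, index_B_range = c(0.9, 1)),
                 selection_filters(min_depth = 8, index_B_range = c(1, 1)))) {
    tight <- select_target_snps(a, b, ref, f)
    expect_true(all(tight$pos %in% loose$pos))
    expect_lte(nrow(tight), nrow(loose))
  }
})

test_that("progeny filtering on the demonstration fixture preserves true sites", {
  run <- demo_run()
  prog <- extract_pileup(run$fx$sam_progeny, run$ref,
                         region_spec("chrSim", 1, run$spec$genome_length))
  before <- run$res$sites
  after <- progeny_filter(before, prog)
  expect_lte(nrow(after), nrow(before))
  # the bulk really is heterozygous at every true site, so most survive
  expect_gte(nrow(after) / nrow(before), 0.8)
})
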