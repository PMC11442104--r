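fab_primer <- function(chrom, start, end, orientation, kind, target_pos,
                       seq = strrep("A", end - start + 1),
                       label = "homozygous", penalty = 1) {
  data.frame(chrom = chrom, start = start, end = end,
             orientation = orientation, kind = kind, target_pos = target_pos,
             target_label = label, allele = "G", seq = seq, tm = 60, gc = 50,
             penalty = penalty, mismatch_pos = 3L, stringsAsFactors = FALSE)
}

rand_ref <- function(n, seed = 5) {
  set.seed(seed)
  ref <- Biostrings::DNAStringSet(
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  names(ref) <- "chrT"
  ref
}

test_that("tri-ARMS spacing outside 100-300 bp yields no marker", {
  ref <- rand_ref(3000)
  for (gap in c(50L, 400L)) {
    primers <- rbind(
      fab_primer("chrT", 983L, 1000L, "forward", "specific_A", 1000L),
      fab_primer("chrT", 1000L + gap - 17L, 1000L + gap, "forward",
                 "specific_B", 1000L + gap))
    out <- assemble_tri_arms(primers, ref,
                             params = primer_params(tm_min = 0, tm_opt = 50,
                                                    tm_max = 100, gc_min = 0,
                                                    gc_max = 100, min_depth = 0))
    expect_identical(nrow(out), 0L)
  }
})

test_that("tri-ARMS product arithmetic follows the coordinate contract", {
  ref <- rand_ref(3000)
  primers <- rbind(
    fab_primer("chrT", 983L, 1000L, "forward", "specific_A", 1000L),
    fab_primer("chrT", 1183L, 1200L, "forward", "specific_B", 1200L))
  out <- assemble_tri_arms(primers, ref,
                           params = primer_params(tm_min = 0, tm_opt = 50,
                                                  tm_max = 100, gc_min = 0,
                                                  gc_max = 100, min_depth = 0))
  expect_identical(nrow(out), 1L)
  expect_identical(out$spacing, 200L)
  # common primer (reverse) lies 100-700 bp beyond the nearer 3' end
  expect_gte(out$start_common, 1300L)
  expect_lte(out$end_common, 1900L)
  # 3' ends stay anchored on the SNPs; the pair shares one primer length
  expect_identical(out$end_A, 1000L)
  expect_identical(out$end_B, 1200L)
  expect_identical(out$end_A - out$start_A, out$end_B - out$start_B)
  expect_identical(out$product_A, out$end_common - out$start_A + 1L)
  expect_identical(out$product_B, out$end_common - out$start_B + 1L)
  expect_identical(out$product_A - out$product_B, out$spacing)
  expect_false(out$trans_risk)
})

test_that("tri-ARMS pairs at heterozygous sites carry the trans-risk flag", {
  ref <- rand_ref(3000)
  primers <- rbind(
    fab_primer("chrT", 983L, 1000L, "forward", "specific_A", 1000L,
               label = "simplex"),
    fab_primer("chrT", 1183L, 1200L, "forward", "specific_B", 1200L,
               label = "simplex"))
  out <- assemble_tri_arms(primers, ref,
                           params = primer_params(tm_min = 0, tm_opt = 50,
                                                  tm_max = 100, gc_min = 0,
                                                  gc_max = 100, min_depth = 0))
  expect_true(all(out$trans_risk))
})

test_that("tetra-ARMS needs both opposite-orientation specifics at the SNP", {
  ref <- rand_ref(3000)
  lone <- fab_primer("chrT", 983L, 1000L, "forward", "specific_A", 1000L)
  out <- assemble_tetra_arms(lone, ref,
                             params = primer_params(tm_min = 0, tm_opt = 50,
                                                    tm_max = 100, gc_min = 0,
                                                    gc_max = 100, min_depth = 0))
  expect_identical(nrow(out), 0L)
})

test_that("tetra-ARMS fulfils the product-size identities", {
  ref <- rand_ref(3000)
  primers <- rbind(
    fab_primer("chrT", 983L, 1000L, "forward", "specific_A", 1000L),
    fab_primer("chrT", 1000L, 1017L, "reverse", "specific_B", 1000L))
  out <- assemble_tetra_arms(primers, ref,
                             params = primer_params(tm_min = 0, tm_opt = 50,
                                                    tm_max = 100, gc_min = 0,
                                                    gc_max = 100, min_depth = 0))
  expect_identical(nrow(out), 1L)
  expect_identical(out$product_A, out$end_common_right - 983L + 1L)
  expect_identical(out$product_B, 1017L - out$start_common_left + 1L)
  expect_identical(out$product_outer,
                   out$end_common_right - out$start_common_left + 1L)
  expect_gt(out$product_outer, max(out$product_A, out$product_B))
  # overlap identity: the allele products double-cover the span between
  # the two specific primers' 5' ends
  expect_identical(out$product_A + out$product_B,
                   out$product_outer + (1017L - 983L + 1L))
  expect_gte(abs(out$product_A - out$product_B), 50L)
})

test_that("in-silico PCR demands a perfect 3' terminus and unique locus", {
  set.seed(9)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
  fwd <- substr(tmpl, 101, 120)
  rev <- armscaps:::revcomp(substr(tmpl, 381, 400))
  expect_identical(in_silico_pcr(fwd, rev, tmpl), 300L)
  # one internal mismatch tolerated, 3'-terminal mismatch fatal
  fwd_int <- fwd
  substr(fwd_int, 18, 18) <- setdiff(c("A","C","G","T"), substr(fwd, 18, 18))[1]
  expect_identical(in_silico_pcr(fwd_int, rev, tmpl), 300L)
  fwd_term <- fwd
  substr(fwd_term, 20, 20) <- setdiff(c("A","C","G","T"), substr(fwd, 20, 20))[1]
  expect_null(in_silico_pcr(fwd_term, rev, tmpl))
  # span cap
  expect_null(in_silico_pcr(fwd, rev, tmpl, max_product = 200L))
  # duplicated locus is non-specific
  expect_error(in_silico_pcr(fwd, rev, paste0(tmpl, tmpl)), "non-specific")
})

test_that("every assembled marker amplifies exactly as predicted (haplotype oracle)", {
  run <- demo_run()
  tri <- run$res$tri; tetra <- run$res$tetra
  expect_gte(nrow(tri), 1L)
  expect_gte(nrow(tetra), 1L)
  for (i in seq_len(nrow(tri))) {
    m <- tri[i, ]
    o <- tri_pcr_oracle(m, run$hap)
    expect_identical(o$product_A, m$product_A)
    expect_identical(o$product_B, m$product_B)
    expect_true(o$clean)
    expect_identical(abs(m$product_A - m$product_B), m$spacing)
  }
  for (i in seq_len(nrow(tetra))) {
    m <- tetra[i, ]
    o <- tetra_pcr_oracle(m, run$hap)
    expect_identical(o$product_A, m$product_A)
    expect_identical(o$product_B, m$product_B)
    expect_identical(o$outer_ref, m$product_outer)
    expect_identical(o$outer_alt, m$product_outer)
    expect_true(o$clean)
  }
})

test_that("density profile bins markers and sites correctly", {
  empty <- marker_density_profile(list(), NULL)
  expect_identical(nrow(empty), 0L)
  one <- data.frame(marker_type = "tetra_arms", snp_pos = 1500000L)
  sites <- data.frame(pos = c(200L, 1500000L))
  prof <- marker_density_profile(one, sites, bin_size = 1e6)
  expect_identical(prof$bin, c(1L, 2L))
  expect_identical(prof$n_tetra_arms, c(0L, 1L))
  expect_identical(prof$n_snps, c(1L, 1L))
})
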