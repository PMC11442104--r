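# a 50 nt context with a SNP at position 25 (T in cultivar A, C in B)
ctx50 <- local({
  ref <- Biostrings::DNAStringSet("TTGACCTAGGCATCGATTGCGCAATGCCTAGGATCGTTACGGCATTGACC")
  names(ref) <- "chr1"
  ref
})
site25 <- data.frame(chrom = "chr1", pos = 25L, ref = "T", alt = "C",
                     label = "homozygous", stringsAsFactors = FALSE)
wide <- primer_params(len_min = 18, len_opt = 18, len_max = 18,
                      tm_min = 0, tm_opt = 50, tm_max = 100,
                      gc_min = 0, gc_max = 100, max_single_base_run = 10)

test_that("specific primers pin the 3' end on the SNP and carry the designed mismatch", {
  p <- design_specific_primers(site25, ctx50, params = wide)
  fwd_alt <- p[p$orientation == "forward" & p$kind == "specific_B", ]
  expect_identical(fwd_alt$start, 8L)
  expect_identical(fwd_alt$end, 25L)
  expect_identical(fwd_alt$seq, "AGGCATCGATTGCGCCAC")
  fwd_ref <- p[p$orientation == "forward" & p$kind == "specific_A", ]
  expect_identical(fwd_ref$seq, "AGGCATCGATTGCGCCAT")
  expect_true(all(p$mismatch_pos == 3L))
})

test_that("reverse specific primers are reported on their own strand", {
  p <- design_specific_primers(site25, ctx50, params = wide)
  rev_alt <- p[p$orientation == "reverse" & p$kind == "specific_B", ]
  expect_identical(rev_alt$start, 25L)
  expect_identical(rev_alt$end, 42L)
  # template strand with the alt allele, reverse-complemented, then the
  # deliberate substitution two bases upstream of the 3' terminus
  tmpl <- paste0("C", substr("TTGACCTAGGCATCGATTGCGCAATGCCTAGGATCGTTACGGCATTGACC", 26, 42))
  manual <- armscaps:::revcomp(tmpl)
  orig <- substr(manual, 16, 16)
  substr(manual, 16, 16) <- armscaps:::.MISMATCH_SUB[[orig]]
  expect_identical(rev_alt$seq, manual)
  # 3' terminus is the complement of the targeted allele
  expect_identical(substr(rev_alt$seq, 18, 18), "G")
})

test_that("a neighboring polymorphism inside every footprint suppresses the primer", {
  pu <- list(A = pileup_df("chr1", c(15, 25), c("G", "T"),
                           list(c(G = 5, T = 5), c(T = 10))),
             B = pileup_df("chr1", c(15, 25), c("G", "T"),
                           list(c(G = 10), c(C = 10))))
  params <- primer_params(len_min = 18, len_opt = 18, len_max = 18,
                          tm_min = 0, tm_opt = 50, tm_max = 100,
                          gc_min = 0, gc_max = 100, max_single_base_run = 10,
                          min_depth = 0)
  p <- design_specific_primers(site25, ctx50, pileups = pu, params = params)
  # position 15 is polymorphic in cultivar A: all forward footprints (8-25)
  # contain it; reverse footprints (25-42) do not
  expect_false(any(p$orientation == "forward"))
  expect_true(any(p$orientation == "reverse"))
})

test_that("primer design is deterministic", {
  a <- design_specific_primers(site25, ctx50, params = wide)
  b <- design_specific_primers(site25, ctx50, params = wide)
  expect_identical(a, b)
})

test_that("penalty arithmetic and optimum", {
  params <- primer_params()
  expect_identical(primer_penalty(list(tm = 60, len = 22), params), 0)
  expect_identical(primer_penalty(list(tm = 62, len = 22), params), 2)
  expect_identical(primer_penalty(list(tm = 60, len = 26), params), 2)
  expect_identical(primer_penalty(list(tm = 59, seq = "ACGTACGTACGTACGTACGTACGT"),
                                  params), 2)
})

test_that("common primer equals the exhaustive enumeration oracle", {
  set.seed(11)
  seqchr <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                  collapse = "")
  ref <- Biostrings::DNAStringSet(seqchr); names(ref) <- "w"
  params <- primer_params(tm_min = 40, tm_opt = 50, tm_max = 65,
                          gc_min = 20, gc_max = 80, min_depth = 0)
  for (ori in c("forward", "reverse")) {
    got <- design_common_primer(region_spec("w", 20, 90), ori, ref,
                                params = params)
    # brute force: every (start, len), scalar thermodynamics
    best <- NULL
    for (s in 20:90) for (len in params$len_min:params$len_max) {
      e <- s + len - 1L
      if (e > 90) next
      sq <- substr(seqchr, s, e)
      if (ori == "reverse") sq <- armscaps:::revcomp(sq)
      if (armscaps:::max_base_run(sq) > params$max_single_base_run) next
      gc <- armscaps:::gc_percent(sq)
      if (gc < params$gc_min || gc > params$gc_max) next
      tm <- melting_temperature(sq)
      if (tm < params$tm_min || tm > params$tm_max) next
      pen <- primer_penalty(list(tm = tm, len = len), params)
      if (is.null(best) || pen < best$penalty ||
          (pen == best$penalty && s < best$start))
        best <- list(start = s, end = e, seq = sq, penalty = pen, tm = tm)
    }
    expect_identical(got$start, best$start)
    expect_identical(got$seq, best$seq)
    expect_equal(got$penalty, best$penalty)
    expect_equal(got$tm, best$tm)
  }
})

test_that("common primers are exact reference substrings and avoid known sites", {
  run <- demo_run()
  refchr <- as.character(run$ref[["chrSim"]])
  commons <- rbind(
    data.frame(start = run$res$tri$start_common, end = run$res$tri$end_common,
               seq = run$res$tri$seq_common,
               ori = ifelse(run$res$tri$orientation == "forward",
                            "reverse", "forward")),
    data.frame(start = run$res$tetra$start_common_left,
               end = run$res$tetra$end_common_left,
               seq = run$res$tetra$seq_common_left, ori = "forward"),
    data.frame(start = run$res$tetra$start_common_right,
               end = run$res$tetra$end_common_right,
               seq = run$res$tetra$seq_common_right, ori = "reverse"))
  for (i in seq_len(nrow(commons))) {
    sub <- substr(refchr, commons$start[i], commons$end[i])
    want <- if (commons$ori[i] == "reverse") armscaps:::revcomp(sub) else sub
    expect_identical(commons$seq[i], want)
    hit <- run$res$sites$pos >= commons$start[i] &
      run$res$sites$pos <= commons$end[i]
    expect_false(any(hit))
  }
})

test_that("windows with no usable candidate yield no common primer", {
  ref <- ctx50
  # window shorter than len_min
  expect_null(design_common_primer(region_spec("chr1", 10, 20), "forward",
                                   ref, params = wide))
  # a known SNP in every possible footprint
  expect_null(design_common_primer(region_spec("chr1", 10, 40), "forward", ref,
                                   known_sites = data.frame(pos = c(25L)),
                                   params = primer_params(
                                     len_min = 18, len_opt = 18, len_max = 18,
                                     tm_min = 0, tm_opt = 50, tm_max = 100,
                                     gc_min = 0, gc_max = 100,
                                     max_single_base_run = 10)))
})
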