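# Shared fixtures, built once per test run and cached.
.cache <- new.env(parent = emptyenv())

# replicates sized so Monte-Carlo noise sits >= 5 standard errors below the
# smallest |binomial CDF - quantile target| at this depth (otherwise the
# empirical quantile can legitimately land one grid step away)
mc_replicates <- function(d, conf = 0.95) {
  gaps <- c()
  for (dp in list(c(1, 2), c(1, 4), c(2, 4), c(3, 4))) {
    p <- dp[1] / dp[2]
    for (tg in c((1 - conf) / 2, 1 - (1 - conf) / 2)) {
      k <- qbinom(tg, d, p)
      gaps <- c(gaps, abs(pbinom(k, d, p) - tg))
      if (k > 0) gaps <- c(gaps, abs(pbinom(k - 1, d, p) - tg))
    }
  }
  max(1e5, ceiling(0.975 * 0.025 * (5 / min(gaps))^2))
}

# write a hand-built SAM file: reads is a list of list(pos =, seq =)
write_hand_sam <- function(path, chrom, chrom_len, reads, mapq = 60) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    lines <- c(lines, sprintf("r%03d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                              i, chrom, r$pos, mapq, nchar(r$seq), r$seq,
                              strrep("I", nchar(r$seq))))
  }
  writeLines(lines, path)
  path
}

# brute-force pileup oracle: recount aligned bases by re-parsing the SAM
# text (fixture reads are all-match CIGAR, high quality, primary)
brute_force_pileup <- function(sam_path, refseq) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- list(A = integer(nchar(refseq)), C = integer(nchar(refseq)),
                 G = integer(nchar(refseq)), T = integer(nchar(refseq)))
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    pos <- as.integer(f[4]); seq <- f[10]
    stopifnot(grepl("^[0-9]+M$", f[6]))
    for (i in seq_len(nchar(seq))) {
      b <- substr(seq, i, i)
      if (b %in% c("A", "C", "G", "T"))
        counts[[b]][pos + i - 1L] <- counts[[b]][pos + i - 1L] + 1L
    }
  }
  depth <- counts$A + counts$C + counts$G + counts$T
  keep <- which(depth >= 1L)
  refb <- strsplit(refseq, "")[[1]]
  out <- data.frame(pos = keep, ref = refb[keep], A = counts$A[keep],
                    C = counts$C[keep], G = counts$G[keep],
                    T = counts$T[keep], depth = depth[keep],
                    stringsAsFactors = FALSE)
  out[out$ref %in% c("A", "C", "G", "T"), , drop = FALSE]
}

# build a pileup data.frame row by row from base counts, for direct tests
# of selection logic without alignment files
pileup_df <- function(chrom, pos, ref, counts_list,
                      region = NULL) {
  rows <- lapply(seq_along(pos), function(i) {
    cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    cnt[names(counts_list[[i]])] <- as.integer(counts_list[[i]])
    data.frame(chrom = chrom, pos = as.integer(pos[i]), ref = ref[i],
               A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
               depth = sum(cnt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(region)) attr(out, "region") <- region
  out
}

# canonical end-to-end run (100 kb, 40 SNPs, depth 30), cached
demo_run <- function() {
  if (!is.null(.cache$demo)) return(.cache$demo)
  spec <- demo_fixture_spec(seed = 1L)
  ref <- generate_reference(spec)
  fx <- generate_alignments(spec, ref, dir = file.path(tempdir(), "demo_fx"),
                            progeny = TRUE)
  res <- marker_pipeline(ref, fx$sam_A, fx$sam_B)
  .cache$demo <- list(spec = spec, ref = ref, fx = fx, res = res,
                      hap = fixture_haplotypes(ref, fx$truth))
  .cache$demo
}

# two-density fixture: 50 vs 500 SNPs/Mb in adjacent 500 kb bins, cached
density_run <- function() {
  if (!is.null(.cache$density)) return(.cache$density)
  spec <- density_fixture_spec(seed = 1L)
  ref <- generate_reference(spec)
  fx <- generate_alignments(spec, ref, dir = file.path(tempdir(), "dens_fx"))
  res <- marker_pipeline(ref, fx$sam_A, fx$sam_B)
  prof <- marker_density_profile(list(res$tri, res$tetra), res$sites,
                                 bin_size = 5e5)
  .cache$density <- list(spec = spec, ref = ref, fx = fx, res = res,
                         prof = prof)
  .cache$density
}

# run the tri-ARMS in-silico PCR oracle for one marker row; returns the
# observed (product_A, product_B) as predicted by amplification on the two
# haplotypes, plus logical "clean" (no cross-allele product)
tri_pcr_oracle <- function(m, hap, max_product = 2000L) {
  amp <- function(specific, template) {
    if (m$orientation == "forward")
      in_silico_pcr(specific, m$seq_common, template, max_product)
    else
      in_silico_pcr(m$seq_common, specific, template, max_product)
  }
  pA <- amp(m$seq_A, hap$ref)
  pB <- amp(m$seq_B, hap$alt)
  cross <- c(amp(m$seq_A, hap$alt), amp(m$seq_B, hap$ref))
  list(product_A = pA, product_B = pB, clean = is.null(cross))
}

tetra_pcr_oracle <- function(m, hap, max_product = 2000L) {
  if (m$orientation_A == "forward") {
    ampA <- function(tmpl) in_silico_pcr(m$seq_A, m$seq_common_right, tmpl, max_product)
    ampB <- function(tmpl) in_silico_pcr(m$seq_common_left, m$seq_B, tmpl, max_product)
  } else {
    ampA <- function(tmpl) in_silico_pcr(m$seq_common_left, m$seq_A, tmpl, max_product)
    ampB <- function(tmpl) in_silico_pcr(m$seq_B, m$seq_common_right, tmpl, max_product)
  }
  outer_ref <- in_silico_pcr(m$seq_common_left, m$seq_common_right, hap$ref, max_product)
  outer_alt <- in_silico_pcr(m$seq_common_left, m$seq_common_right, hap$alt, max_product)
  list(product_A = ampA(hap$ref), product_B = ampB(hap$alt),
       outer_ref = outer_ref, outer_alt = outer_alt,
       clean = is.null(ampA(hap$alt)) && is.null(ampB(hap$ref)))
}

caps_oracle <- function(m, hap, enzymes) {
  enz <- enzymes[enzymes$name == m$enzyme, ]
  pr <- in_silico_pcr(m$seq_fwd, m$seq_rev, hap$ref)
  pa <- in_silico_pcr(m$seq_fwd, m$seq_rev, hap$alt)
  prod_ref <- substr(hap$ref, m$start_fwd, m$end_rev)
  prod_alt <- substr(hap$alt, m$start_fwd, m$end_rev)
  list(size_ref = pr, size_alt = pa,
       fragments_ref = sort(digest(prod_ref, enz)),
       fragments_alt = sort(digest(prod_alt, enz)))
}
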