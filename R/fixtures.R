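#' Specify a synthetic resequencing fixture
#'
#' Describes a synthetic study: a random reference sequence, a set of SNP
#' positions with per-cultivar variant-allele dosages, and uniform
#' pre-aligned short-read coverage for two cultivars (plus an optional
#' progeny bulk). Reads are synthesized already aligned (all-match CIGAR,
#' uniform Q40 base qualities) so the whole pipeline is testable without an
#' aligner; per-base substitution errors are injected at `error_rate`.
#'
#' @param genome_length reference length in bp.
#' @param gc_content expected GC fraction of the reference.
#' @param n_snps number of SNP positions (ignored when `snp_positions` given).
#' @param snp_positions optional explicit 1-based SNP positions; must be
#'   unique and at least `read_length` from either end.
#' @param ploidy sample ploidy.
#' @param dosage_A,dosage_B variant-allele copies carried by cultivar A / B
#'   at every site, in `[0, ploidy]`. The default (`0` and `ploidy`) is the
#'   homozygous cultivar-B-specific case.
#' @param depth mean per-position coverage.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param min_snp_gap minimum spacing enforced between random SNP positions.
#' @param n_clusters number of SNP clusters placed at tri-ARMS-compatible
#'   spacing (real cultivar-pair SNPs are clustered, not uniform; a uniform
#'   scatter at small n would under-represent the 100-300 bp neighbor pairs
#'   tri-ARMS markers require).
#' @param cluster_size SNPs per cluster.
#' @param cluster_gaps range of within-cluster neighbor spacing (bp).
#' @param caps_sites number of SNPs deliberately placed inside an AluI
#'   (`AGCT`) recognition site with the variant allele breaking it,
#'   emulating the small fraction of restriction-site-overlapping SNPs a
#'   genome-scale run always contains but a small random sample may miss.
#' @param seed integer seed; every derived artifact is deterministic in it.
#' @param chrom name of the single reference sequence.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(genome_length = 1e5, gc_content = 0.5, n_snps = 40,
                         snp_positions = NULL, ploidy = 2, dosage_A = 0,
                         dosage_B = ploidy, depth = 30, read_length = 100,
                         error_rate = 0.001, min_snp_gap = 2 * read_length,
                         n_clusters = 0L, cluster_size = 3L,
                         cluster_gaps = c(110L, 150L), caps_sites = 0L,
                         seed = 1L, chrom = "chrSim") {
  genome_length <- as.integer(genome_length)
  read_length <- as.integer(read_length)
  if (genome_length < read_length)
    stop("genome_length must be at least read_length", call. = FALSE)
  stopifnot(dosage_A >= 0, dosage_A <= ploidy, dosage_B >= 0, dosage_B <= ploidy)
  if (!is.null(snp_positions)) {
    snp_positions <- sort(unique(as.integer(snp_positions)))
    if (any(snp_positions < read_length) ||
        any(snp_positions > genome_length - read_length))
      stop("snp_positions must be at least read_length from the ends",
           call. = FALSE)
    n_snps <- length(snp_positions)
  }
  if (n_clusters * cluster_size + caps_sites > n_snps)
    stop("clustered and CAPS-designated SNPs exceed n_snps", call. = FALSE)
  structure(list(genome_length = genome_length, gc_content = gc_content,
                 n_snps = as.integer(n_snps), snp_positions = snp_positions,
                 ploidy = as.integer(ploidy), dosage_A = as.integer(dosage_A),
                 dosage_B = as.integer(dosage_B), depth = depth,
                 read_length = read_length, error_rate = error_rate,
                 min_snp_gap = as.integer(min_snp_gap),
                 n_clusters = as.integer(n_clusters),
                 cluster_size = as.integer(cluster_size),
                 cluster_gaps = as.integer(cluster_gaps),
                 caps_sites = as.integer(caps_sites),
                 seed = as.integer(seed), chrom = chrom),
            class = "fixture_spec")
}

#' Generate the synthetic reference sequence
#'
#' Seeded i.i.d. bases at the requested GC content, as a
#' [Biostrings::DNAStringSet]; optionally written to FASTA.
#'
#' @param spec a [fixture_spec()].
#' @param path optional FASTA output path.
#' @return a `DNAStringSet` with one sequence named `spec$chrom`.
#' @export
generate_reference <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  p_gc <- spec$gc_content / 2
  p_at <- (1 - spec$gc_content) / 2
  seqchr <- with_seed(spec$seed, paste(
    sample(BASES, spec$genome_length, replace = TRUE,
           prob = c(p_at, p_gc, p_gc, p_at)), collapse = ""))
  ref <- Biostrings::DNAStringSet(seqchr)
  names(ref) <- spec$chrom
  if (!is.null(path)) Biostrings::writeXStringSet(ref, path)
  ref
}

# choose SNP positions and alleles for a fixture (deterministic in seed)
.fixture_truth <- function(spec, reference) {
  refchr <- as.character(reference[[spec$chrom]])
  lo <- spec$read_length
  hi <- spec$genome_length - spec$read_length
  if (!is.null(spec$snp_positions)) {
    pos <- spec$snp_positions
    forced_alt <- rep(NA_character_, length(pos))
  } else {
    placed <- with_seed(spec$seed + 7L, {
      taken <- integer(0)   # positions already used (gap enforced against them)
      far_enough <- function(p) !length(taken) ||
        min(abs(outer(p, taken, "-"))) >= spec$min_snp_gap
      draw_clear <- function() {
        for (k in seq_len(5000L)) {
          p <- sample(lo:hi, 1L)
          if (far_enough(p)) return(p)
        }
        stop("could not place SNPs with the requested gap", call. = FALSE)
      }
      pos <- integer(0); forced_alt <- character(0)
      # CAPS-designated SNPs: inside an AluI site, variant breaks the site
      if (spec$caps_sites > 0L) {
        alu <- gregexpr("AGCT", refchr, fixed = TRUE)[[1]]
        alu <- alu[alu >= lo & alu + 3L <= hi]
        alu <- sample(alu)
        need <- spec$caps_sites
        for (a in alu) {
          if (need == 0L) break
          p <- a + 1L  # the G of AGCT; any substitution breaks the site
          if (!far_enough(p)) next
          r <- substr(refchr, p, p)
          alt_ok <- NULL
          for (alt in setdiff(BASES, r)) {
            ctx <- refchr
            substr(ctx, p, p) <- alt
            if (!grepl("AGCT", substr(ctx, p - 3L, p + 3L), fixed = TRUE)) {
              alt_ok <- alt; break
            }
          }
          if (is.null(alt_ok)) next
          pos <- c(pos, p); forced_alt <- c(forced_alt, alt_ok)
          taken <- c(taken, p); need <- need - 1L
        }
        if (need > 0L)
          stop("reference contains too few usable AluI sites", call. = FALSE)
      }
      # clustered SNPs at tri-ARMS-compatible neighbor spacing
      for (k in seq_len(spec$n_clusters)) {
        repeat {
          gaps <- sample(spec$cluster_gaps[1]:spec$cluster_gaps[2],
                         spec$cluster_size - 1L, replace = TRUE)
          anchor <- sample(lo:(hi - sum(gaps)), 1L)
          members <- anchor + c(0L, cumsum(gaps))
          if (all(vapply(members, far_enough, logical(1)))) {
            pos <- c(pos, members)
            forced_alt <- c(forced_alt, rep(NA_character_, length(members)))
            taken <- c(taken, members)
            break
          }
        }
      }
      # remaining singles
      n_single <- spec$n_snps - length(pos)
      for (k in seq_len(max(0L, n_single))) {
        p <- draw_clear()
        pos <- c(pos, p); forced_alt <- c(forced_alt, NA_character_)
        taken <- c(taken, p)
      }
      list(pos = pos, forced_alt = forced_alt)
    })
    o <- order(placed$pos)
    pos <- placed$pos[o]
    forced_alt <- placed$forced_alt[o]
  }
  ref_allele <- strsplit(refchr, "")[[1]][pos]
  alt_allele <- with_seed(spec$seed + 11L, vapply(seq_along(pos), function(i) {
    if (!is.na(forced_alt[i])) forced_alt[i]
    else sample(setdiff(BASES, ref_allele[i]), 1)
  }, character(1)))
  data.frame(chrom = spec$chrom, pos = pos, ref = ref_allele,
             alt = alt_allele, dosage_A = spec$dosage_A,
             dosage_B = spec$dosage_B, stringsAsFactors = FALSE)
}

# in-place single-character substitutions on a vector of read strings
.edit_reads <- function(reads, read_idx, offsets, bases) {
  for (k in seq_along(read_idx)) {
    i <- read_idx[k]
    substr(reads[i], offsets[k], offsets[k]) <- bases[k]
  }
  reads
}

.write_sam <- function(reads, starts, spec, path, sample_name) {
  rl <- spec$read_length
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", spec$chrom, spec$genome_length),
              sprintf("@RG\tID:%s\tSM:%s", sample_name, sample_name))
  qual <- strrep("I", rl)
  body <- sprintf("%s_%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  sample_name, seq_along(reads), spec$chrom, starts, rl,
                  reads, qual)
  writeLines(c(header, body), path)
  invisible(path)
}

# simulate one sample's reads: per read and per overlapped SNP, the variant
# allele is drawn Bernoulli(dosage/ploidy), so per-position alt counts are
# Binomial(local depth, dosage/ploidy)
.simulate_sample_sam <- function(spec, refchr, truth, dosage, ploidy,
                                 path, sample_name, seed) {
  rl <- spec$read_length
  L <- spec$genome_length
  n_reads <- max(1L, as.integer(round(spec$depth * L / rl)))
  with_seed(seed, {
    starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
    reads <- substring(refchr, starts, starts + rl - 1L)
    p <- dosage / ploidy
    if (p > 0) {
      for (j in seq_len(nrow(truth))) {
        pos <- truth$pos[j]
        idx <- which(starts <= pos & starts + rl - 1L >= pos)
        if (!length(idx)) next
        take <- idx[runif(length(idx)) < p]
        if (length(take))
          reads <- .edit_reads(reads, take, pos - starts[take] + 1L,
                               rep(truth$alt[j], length(take)))
      }
    }
    if (spec$error_rate > 0) {
      n_err <- rbinom(1, n_reads * rl, spec$error_rate)
      if (n_err > 0) {
        ri <- sample.int(n_reads, n_err, replace = TRUE)
        off <- sample.int(rl, n_err, replace = TRUE)
        cur <- substr(reads[ri], off, off)  # vectorized extract is fine
        new <- vapply(cur, function(b) sample(setdiff(BASES, b), 1),
                      character(1), USE.NAMES = FALSE)
        reads <- .edit_reads(reads, ri, off, new)
      }
    }
    .write_sam(reads, starts, spec, path, sample_name)
  })
}

#' Generate synthetic alignments for two cultivars (and optional progeny)
#'
#' Writes plain-text SAM files with perfectly aligned reads whose
#' variant-allele counts follow Binomial(depth, dosage/ploidy) at each SNP.
#' The progeny bulk, when requested, draws every site at dosage 1 of ploidy
#' 2 (the equal-allele-ratio expectation for a random F2 bulk).
#'
#' @param spec a [fixture_spec()].
#' @param reference the `DNAStringSet` from [generate_reference()].
#' @param dir output directory (created if needed).
#' @param progeny also generate a progeny-bulk SAM.
#' @return list with `reference` (FASTA path), `sam_A`, `sam_B`, optional
#'   `sam_progeny`, and `truth` (data.frame of pos/ref/alt/dosages).
#' @export
generate_alignments <- function(spec, reference, dir = tempfile("fixture"),
                                progeny = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refchr <- as.character(reference[[spec$chrom]])
  truth <- .fixture_truth(spec, reference)
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(reference, fa)
  sam_A <- file.path(dir, "cultivarA.sam")
  sam_B <- file.path(dir, "cultivarB.sam")
  .simulate_sample_sam(spec, refchr, truth, spec$dosage_A, spec$ploidy,
                       sam_A, "cultivarA", spec$seed + 101L)
  .simulate_sample_sam(spec, refchr, truth, spec$dosage_B, spec$ploidy,
                       sam_B, "cultivarB", spec$seed + 202L)
  out <- list(reference = fa, sam_A = sam_A, sam_B = sam_B, truth = truth,
              spec = spec)
  if (progeny) {
    sam_P <- file.path(dir, "progeny.sam")
    .simulate_sample_sam(spec, refchr, truth, 1L, 2L, sam_P, "progeny",
                         spec$seed + 303L)
    out$sam_progeny <- sam_P
  }
  out
}

#' Build cultivar haplotype sequences from fixture truth
#'
#' Applies each cultivar's fixed alleles to the reference, yielding the two
#' template strings used by the in-silico PCR and digestion oracles. Only
#' meaningful for homozygous dosages (0 or ploidy); heterozygous sites take
#' the allele carried at non-zero dosage for the "variant" haplotype.
#'
#' @param reference `DNAStringSet`.
#' @param truth data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param chrom sequence name.
#' @return list with `ref` and `alt` haplotype strings.
#' @export
fixture_haplotypes <- function(reference, truth, chrom = truth$chrom[1]) {
  refchr <- as.character(reference[[chrom]])
  altchr <- refchr
  for (j in seq_len(nrow(truth)))
    substr(altchr, truth$pos[j], truth$pos[j]) <- truth$alt[j]
  list(ref = refchr, alt = altchr)
}

#' Canonical end-to-end demonstration fixture
#'
#' The study conditions used by the package's end-to-end checks: a 100 kb
#' diploid genome at 50% GC with 40 homozygous cultivar-B-specific SNPs
#' (400 SNPs/Mb) sequenced to depth 30. Six clusters of three SNPs at
#' 110-150 bp neighbor spacing emulate the clustered SNP distribution of
#' real cultivar pairs (the substrate of tri-ARMS markers), and six SNPs
#' sit inside AluI sites, emulating the few-percent of
#' restriction-site-overlapping SNPs a genome-scale run always contains.
#'
#' @param seed integer seed.
#' @return a [fixture_spec()].
#' @export
demo_fixture_spec <- function(seed = 1L) {
  fixture_spec(genome_length = 1e5, gc_content = 0.5, n_snps = 40,
               ploidy = 2, dosage_A = 0, dosage_B = 2, depth = 30,
               n_clusters = 6L, cluster_size = 3L, caps_sites = 6L,
               seed = seed)
}

#' Two-density fixture for the SNP-density/marker-type relation
#'
#' A 1 Mb diploid genome split into two 500 kb bins holding 25 and 250
#' random SNPs (50 vs 500 SNPs/Mb) at depth 20. Positions are uniform
#' within each bin with a 40 bp minimum gap, so tri-ARMS-compatible
#' neighbor spacings (100-300 bp) arise naturally in the dense bin and are
#' rare in the sparse one, while tetra-ARMS markers (one SNP each) remain
#' available in both.
#'
#' @param seed integer seed.
#' @return a [fixture_spec()].
#' @export
density_fixture_spec <- function(seed = 1L) {
  rl <- 100L
  min_gap <- 40L
  pos <- with_seed(seed + 31L, {
    draw_bin <- function(n, lo, hi) {
      out <- integer(0)
      while (length(out) < n) {
        cand <- sort(unique(c(out, sample(lo:hi, n - length(out)))))
        out <- cand[c(TRUE, diff(cand) >= min_gap)]
      }
      out
    }
    c(draw_bin(25L, rl, 5e5L - min_gap),
      draw_bin(250L, 5e5L + min_gap, 1e6L - rl))
  })
  fixture_spec(genome_length = 1e6, gc_content = 0.5, snp_positions = pos,
               ploidy = 2, dosage_A = 0, dosage_B = 2, depth = 20,
               read_length = rl, seed = seed)
}

#' Simulate a table of selected SNP sites at known dosage
#'
#' Draws per-site variant read counts `X ~ Binomial(depth, dosage/ploidy)`
#' and returns the corresponding site table (cultivar A clean at index 0),
#' the direct input contract of [hetero_select()]. Used for calibration
#' checks of interval-based genotype filtering without simulating reads.
#'
#' @param n_sites number of sites.
#' @param depth fixed coverage depth per site.
#' @param dosage,ploidy true variant dosage of cultivar B.
#' @param seed integer seed.
#' @param chrom sequence name for the synthetic sites.
#' @return a site data.frame (see [select_target_snps()] for columns).
#' @export
simulate_snp_sites <- function(n_sites, depth, dosage, ploidy, seed = 1L,
                               chrom = "chrSim") {
  x <- with_seed(seed, rbinom(n_sites, depth, dosage / ploidy))
  data.frame(chrom = chrom, pos = seq_len(n_sites) * 1000L,
             ref = "A", alt = "G",
             index_A = 0, index_B = x / depth,
             depth_A = as.integer(depth), depth_B = as.integer(depth),
             label = NA_character_, stringsAsFactors = FALSE)
}
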