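# Accept BAM (indexed) or plain SAM (test fixtures); SAM is converted to a
# sorted, indexed temporary BAM. A .bam without its index is an error, per
# the sorted-and-indexed input contract.
ensure_indexed_bam <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- sub("\\.sam$", "", file.path(tempdir(), paste0(
      basename(tools::file_path_sans_ext(path)), "_",
      substr(tools::md5sum(path), 1, 8))))
    bam <- paste0(dest, ".bam")
    if (!file.exists(bam))
      bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                              indexDestination = TRUE)
    return(bam)
  }
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path)))
    stop("missing BAM index (.bai) for ", path,
         "; index the file with Rsamtools::indexBam or samtools index",
         call. = FALSE)
  path
}

#' Extract per-position allele counts from an alignment
#'
#' Produces one row per reference position in `region` with at least one
#' read surviving the filters: duplicate, secondary, supplementary and
#' unmapped reads are excluded; only aligned `A/C/G/T` read bases are
#' counted (insertions, deletions and reference skips are ignored);
#' positions whose reference base is `N` are never emitted. All positions
#' are 1-based inclusive.
#'
#' @param alignment path to a coordinate-sorted indexed BAM, or a plain SAM
#'   (converted and indexed on the fly).
#' @param reference FASTA path or `DNAStringSet`.
#' @param region a [region_spec()].
#' @param min_base_quality minimum base quality (default 13).
#' @param min_mapping_quality minimum mapping quality (default 20).
#' @param max_depth pileup depth cap (generous default).
#' @return data.frame with columns `chrom, pos, ref, A, C, G, T, depth`,
#'   ordered by `pos`, with the queried region attached as attribute
#'   `"region"`. `depth` always equals the sum of the four base counts.
#' @export
extract_pileup <- function(alignment, reference, region,
                           min_base_quality = 13L, min_mapping_quality = 20L,
                           max_depth = 100000L) {
  stopifnot(inherits(region, "region_spec"))
  ref <- load_reference(reference)
  if (!region$chrom %in% names(ref))
    stop("sequence '", region$chrom, "' not present in the reference",
         call. = FALSE)
  bam <- ensure_indexed_bam(alignment)
  which <- GenomicRanges::GRanges(region$chrom,
                                  IRanges::IRanges(region$start, region$end))
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE),
    which = which)
  pp <- Rsamtools::PileupParam(max_depth = max_depth,
                               min_base_quality = min_base_quality,
                               min_mapq = min_mapping_quality,
                               min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               ignore_query_Ns = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  raw <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  raw <- raw[raw$nucleotide %in% BASES, , drop = FALSE]
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), depth = integer(0),
                      stringsAsFactors = FALSE)
  attr(empty, "region") <- region
  if (!nrow(raw)) return(empty)
  dt <- data.table::data.table(pos = raw$pos,
                               nucleotide = as.character(raw$nucleotide),
                               count = raw$count)
  wide <- data.table::dcast(dt, pos ~ nucleotide, value.var = "count",
                            fun.aggregate = sum, fill = 0L)
  for (b in BASES) if (!b %in% names(wide)) wide[[b]] <- 0L
  out <- data.frame(chrom = region$chrom, pos = wide$pos,
                    ref = strsplit(ref_substring(ref, region$chrom,
                                                 region$start, region$end),
                                   "")[[1]][wide$pos - region$start + 1L],
                    A = wide$A, C = wide$C, G = wide$G, T = wide$T,
                    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  out <- out[out$ref %in% BASES & out$depth >= 1L, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "region") <- region
  out
}

#' Serialize pileup columns as TSV
#'
#' Writes the `chrom, pos, ref, A, C, G, T, depth` table produced by
#' [extract_pileup()].
#'
#' @param pileup pileup data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  write_tsv(pileup[, c("chrom", "pos", "ref", "A", "C", "G", "T", "depth")],
            path)
}

#' SNP-index of an allele in pileup columns
#'
#' The SNP-index is the fraction of reads carrying `allele` among all reads
#' covering the position: `counts[allele] / depth`. Undefined (an error,
#' never silently 0) at depth 0.
#'
#' @param column one or more pileup rows (see [extract_pileup()]).
#' @param allele one of `A/C/G/T`.
#' @return numeric vector of fractions in `[0, 1]`, one per row.
#' @export
snp_index <- function(column, allele) {
  stopifnot(allele %in% BASES)
  if (any(column$depth < 1L))
    stop("SNP-index is undefined at depth 0", call. = FALSE)
  column[[allele]] / column$depth
}
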