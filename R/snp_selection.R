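#' Filters for target SNP selection
#'
#' @param min_depth minimum per-cultivar coverage depth (default 6, the
#'   minimal diploid depth separating heterozygous from homozygous calls).
#' @param max_depth maximum coverage depth; `NULL` means 3x the cultivar's
#'   mean depth over the region (guards against collapsed repeats).
#' @param tolA maximum tolerated SNP-index of any non-reference base in
#'   cultivar A ("no polymorphism"); strict 0 by default, configurable
#'   because sequencing error makes strict zero brittle at high depth.
#' @param index_B_range accepted cultivar-B SNP-index range for the variant
#'   allele, `c(lo, hi)`; default `c(1, 1)` (homozygous alternate).
#' @param index_B_exclusive treat the range bounds as open (used by the
#'   heterozygous workflow with range `(0, 1)`).
#' @param ploidy,dosage,confidence genotype model for interval-based
#'   filtering ([hetero_select()], [progeny_filter()]).
#' @return a `selection_filters` list.
#' @export
selection_filters <- function(min_depth = 6L, max_depth = NULL, tolA = 0,
                              index_B_range = c(1, 1),
                              index_B_exclusive = FALSE,
                              ploidy = 2L, dosage = 1L, confidence = 0.95) {
  stopifnot(min_depth >= 1, length(index_B_range) == 2,
            index_B_range[1] <= index_B_range[2],
            confidence > 0, confidence < 1)
  structure(list(min_depth = as.integer(min_depth), max_depth = max_depth,
                 tolA = tolA, index_B_range = index_B_range,
                 index_B_exclusive = index_B_exclusive,
                 ploidy = as.integer(ploidy), dosage = as.integer(dosage),
                 confidence = confidence),
            class = "selection_filters")
}

.resolve_max_depth <- function(max_depth, cols) {
  if (!is.null(max_depth)) return(max_depth)
  if (!nrow(cols)) return(Inf)
  3 * mean(cols$depth)
}

#' Select cultivar-B-specific SNP positions
#'
#' A position becomes a site iff (a) both cultivars have
#' `min_depth <= depth <= max_depth`; (b) every non-reference base in
#' cultivar A has SNP-index `<= tolA` (cultivar A shows no polymorphism);
#' (c) exactly one non-reference base in cultivar B rises above `tolA`
#' *and* its SNP-index lies within `index_B_range` — positions with two or
#' more non-reference bases above `tolA` in cultivar B are rejected as
#' multi-allelic, since a marker needs a single discriminating allele.
#'
#' @param colsA,colsB pileup data.frames from [extract_pileup()] over the
#'   same region (mismatched regions are an error).
#' @param reference FASTA path or `DNAStringSet` (used for sanity checks).
#' @param filters a [selection_filters()].
#' @return site data.frame with columns `chrom, pos, ref, alt, index_A,
#'   index_B, depth_A, depth_B, label`. `label` is `"homozygous"` where the
#'   variant allele is fixed in cultivar B (`index_B == 1`), `NA` otherwise
#'   (pending [hetero_select()]).
#' @export
select_target_snps <- function(colsA, colsB, reference = NULL,
                               filters = selection_filters()) {
  regA <- attr(colsA, "region"); regB <- attr(colsB, "region")
  if (!is.null(regA) && !is.null(regB) &&
      (regA$chrom != regB$chrom || regA$start != regB$start ||
       regA$end != regB$end))
    stop("pileup regions for the two cultivars do not match", call. = FALSE)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      index_A = numeric(0), index_B = numeric(0),
                      depth_A = integer(0), depth_B = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (!nrow(colsA) || !nrow(colsB)) return(empty)
  if (length(unique(colsA$chrom)) > 1 || length(unique(colsB$chrom)) > 1 ||
      colsA$chrom[1] != colsB$chrom[1])
    stop("pileup regions for the two cultivars do not match", call. = FALSE)
  maxA <- .resolve_max_depth(filters$max_depth, colsA)
  maxB <- .resolve_max_depth(filters$max_depth, colsB)
  a <- colsA[colsA$depth >= filters$min_depth & colsA$depth <= maxA, ]
  b <- colsB[colsB$depth >= filters$min_depth & colsB$depth <= maxB, ]
  m <- merge(a, b, by = c("chrom", "pos", "ref"), suffixes = c("_A", "_B"))
  if (!nrow(m)) return(empty)
  cntA <- as.matrix(m[, paste0(BASES, "_A")])
  cntB <- as.matrix(m[, paste0(BASES, "_B")])
  colnames(cntA) <- colnames(cntB) <- BASES
  ridx <- match(m$ref, BASES)
  sel <- cbind(seq_len(nrow(m)), ridx)
  idxA <- cntA / m$depth_A
  idxB <- cntB / m$depth_B
  idxA[sel] <- 0  # reference base never counts as a polymorphism
  idxB[sel] <- 0
  ok_A <- rowSums(idxA > filters$tolA) == 0L
  n_above_B <- rowSums(idxB > filters$tolA)
  lo <- filters$index_B_range[1]; hi <- filters$index_B_range[2]
  in_range <- if (filters$index_B_exclusive) idxB > lo & idxB < hi
              else idxB >= lo & idxB <= hi
  in_range[sel] <- FALSE
  n_in_range <- rowSums(in_range)
  keep <- ok_A & n_above_B <= 1L & n_in_range == 1L
  if (!any(keep)) return(empty)
  kept <- which(keep)
  alt_col <- max.col(in_range[kept, , drop = FALSE], ties.method = "first")
  out <- data.frame(chrom = m$chrom[kept], pos = m$pos[kept],
                    ref = m$ref[kept], alt = BASES[alt_col],
                    index_A = idxA[cbind(kept, alt_col)],
                    index_B = idxB[cbind(kept, alt_col)],
                    depth_A = m$depth_A[kept], depth_B = m$depth_B[kept],
                    label = NA_character_, stringsAsFactors = FALSE)
  out$label[out$index_B == 1] <- "homozygous"
  rownames(out) <- NULL
  out
}

.dosage_label <- function(ploidy, dosage) {
  if (ploidy == 2L) return("heterozygous_diploid")
  if (ploidy == 4L) return(c("simplex", "duplex", "triplex")[dosage])
  sprintf("dosage_%d_of_%d", dosage, ploidy)
}

#' Select heterozygous sites by dosage (HeteroSelect)
#'
#' Keeps a site iff its observed cultivar-B SNP-index lies within the exact
#' binomial confidence interval for the target dosage at that site's depth
#' ([snp_index_interval()]); kept sites are relabelled by dosage class.
#' Sites should come from [select_target_snps()] with a permissive open
#' range `(0, 1)`.
#'
#' @param sites site data.frame (see [select_target_snps()]).
#' @param ploidy sample ploidy; `dosage` in `[1, ploidy-1]`.
#' @param dosage target variant-allele dosage.
#' @param confidence interval coverage (default 0.95).
#' @return the retained, relabelled subset of `sites`.
#' @export
hetero_select <- function(sites, ploidy, dosage, confidence = 0.95) {
  if (dosage >= ploidy)
    stop("dosage must be smaller than ploidy", call. = FALSE)
  if (!nrow(sites)) return(sites)
  depths <- sort(unique(sites$depth_B))
  ivs <- lapply(depths, snp_index_interval, dosage = dosage, ploidy = ploidy,
                confidence = confidence)
  lo <- vapply(ivs, `[[`, numeric(1), "lo")[match(sites$depth_B, depths)]
  hi <- vapply(ivs, `[[`, numeric(1), "hi")[match(sites$depth_B, depths)]
  keep <- sites$index_B >= lo & sites$index_B <= hi
  out <- sites[keep, , drop = FALSE]
  if (nrow(out)) out$label <- .dosage_label(as.integer(ploidy), as.integer(dosage))
  rownames(out) <- NULL
  out
}

#' Keep sites segregating in a progeny bulk (ProgenySNP)
#'
#' A random bulk of progeny from the cross is expected to carry the two
#' parental alleles at equal ratio at every true SNP, i.e. to look like a
#' diploid heterozygote. A site is kept iff the bulk's SNP-index of the
#' variant allele lies within the exact binomial interval for dosage 1 of
#' ploidy 2 at the bulk's depth, and the bulk's depth is within
#' `[min_depth, max_depth]`. Sites absent from the bulk pileup are dropped.
#'
#' @param sites site data.frame.
#' @param progeny_cols pileup of the progeny bulk over the sites' region.
#' @param ploidy informational (the expected bulk allele ratio is 1/2
#'   regardless of parental ploidy); kept for interface symmetry.
#' @param confidence interval coverage.
#' @param min_depth,max_depth bulk depth bounds (`NULL` max = 3x mean).
#' @return the retained subset of `sites`.
#' @export
progeny_filter <- function(sites, progeny_cols, ploidy = 2L,
                           confidence = 0.95, min_depth = 6L,
                           max_depth = NULL) {
  if (!nrow(sites)) return(sites)
  maxP <- .resolve_max_depth(max_depth, progeny_cols)
  hit <- match(sites$pos, progeny_cols$pos)
  keep <- !is.na(hit)
  if (any(keep)) {
    rows <- progeny_cols[hit[keep], , drop = FALSE]
    depth <- rows$depth
    idx <- as.matrix(rows[, BASES])[cbind(seq_len(nrow(rows)),
                                          match(sites$alt[keep], BASES))] / depth
    depths <- sort(unique(depth))
    ivs <- lapply(depths, snp_index_interval, dosage = 1L, ploidy = 2L,
                  confidence = confidence)
    lo <- vapply(ivs, `[[`, numeric(1), "lo")[match(depth, depths)]
    hi <- vapply(ivs, `[[`, numeric(1), "hi")[match(depth, depths)]
    keep[keep] <- depth >= min_depth & depth <= maxP & idx >= lo & idx <= hi
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
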