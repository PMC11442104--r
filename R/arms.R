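#' ARMS assembly parameters
#'
#' Distance rules for combining cultivar-specific and common primers.
#' Spacing between the two specific primers of a tri-ARMS marker is
#' measured between their 3' ends (the SNP positions); the common-primer
#' windows are measured from the 3' end of the nearer specific primer
#' (tri) or from the SNP (tetra) — the common primer's footprint must lie
#' entirely within the window.
#'
#' @param spacing_min,spacing_max allowed 3'-end spacing between the two
#'   specific primers of a tri-ARMS marker (bp).
#' @param common_min,common_max common-primer window distance bounds (bp).
#' @param min_band_separation smallest resolvable product-size difference
#'   on agarose (bp).
#' @param max_product largest amplifiable product considered (bp).
#' @return an `arms_params` list.
#' @export
arms_params <- function(spacing_min = 100L, spacing_max = 300L,
                        common_min = 100L, common_max = 700L,
                        min_band_separation = 50L, max_product = 2000L) {
  structure(list(spacing_min = as.integer(spacing_min),
                 spacing_max = as.integer(spacing_max),
                 common_min = as.integer(common_min),
                 common_max = as.integer(common_max),
                 min_band_separation = as.integer(min_band_separation),
                 max_product = as.integer(max_product)),
            class = "arms_params")
}

.specifics <- function(primers) {
  primers[primers$kind %in% c("specific_A", "specific_B"), , drop = FALSE]
}

#' Assemble tri-ARMS markers
#'
#' For every pair of an A-specific and a B-specific primer in the same
#' orientation at different SNPs with 3'-end spacing within
#' `[spacing_min, spacing_max]`, attempts one common primer of the opposite
#' orientation inside the `[common_min, common_max]` window measured from
#' the nearer specific primer's 3' end, and emits at most one marker
#' (minimum summed penalty) per pair. The two specific primers of a pair
#' are re-selected at a shared length (minimum summed penalty among the
#' lengths valid at both sites); since the allele products share the
#' common primer, their band-size difference then equals the
#' specific-primer spacing exactly. Pairs involving a non-homozygous site
#' are flagged
#' `trans_risk`: without phasing, two heterozygous cultivar-specific SNPs
#' may sit in trans, in which case the marker cannot separate homozygous
#' from heterozygous genotypes.
#'
#' @param primers primer data.frame from [design_specific_primers()] (rows
#'   of other kinds are ignored).
#' @param reference FASTA path or `DNAStringSet`.
#' @param pileups optional `list(A = , B = )` pileups for the common-primer
#'   consensus/coverage checks.
#' @param params a [primer_params()] for the common primer.
#' @param arms an [arms_params()].
#' @param known_sites optional site data.frame whose positions are excluded
#'   from common-primer footprints.
#' @param best_per_interval optional bp width; when set, only the
#'   minimum-penalty marker per genomic interval is kept (genome-wide mode).
#' @return marker data.frame, one row per emitted tri-ARMS marker.
#' @export
assemble_tri_arms <- function(primers, reference, pileups = NULL,
                              params = primer_params(),
                              arms = arms_params(), known_sites = NULL,
                              best_per_interval = NULL) {
  ref <- load_reference(reference)
  sp <- .specifics(primers)
  out <- list()
  for (orientation in c("forward", "reverse")) {
    a <- sp[sp$kind == "specific_A" & sp$orientation == orientation, , drop = FALSE]
    b <- sp[sp$kind == "specific_B" & sp$orientation == orientation, , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      pa <- a[i, ]; pb <- b[j, ]
      if (pa$chrom != pb$chrom || pa$target_pos == pb$target_pos) next
      spacing <- abs(pa$target_pos - pb$target_pos)
      if (spacing < arms$spacing_min || spacing > arms$spacing_max) next
      # re-select the two specific primers at a shared length so the
      # band-size difference equals the SNP spacing exactly
      ca <- .specific_candidates(pa$chrom, pa$target_pos, pa$allele,
                                 orientation, ref, pileups, params)
      cb <- .specific_candidates(pb$chrom, pb$target_pos, pb$allele,
                                 orientation, ref, pileups, params)
      if (is.null(ca) || is.null(cb)) next
      shared <- merge(ca, cb, by = "len", suffixes = c("_a", "_b"))
      if (!nrow(shared)) next
      shared <- shared[order(shared$penalty_a + shared$penalty_b,
                             shared$len), , drop = FALSE]
      pick <- shared[1, ]
      pa$start <- pick$start_a; pa$end <- pick$end_a; pa$seq <- pick$seq_a
      pa$penalty <- pick$penalty_a
      pb$start <- pick$start_b; pb$end <- pick$end_b; pb$seq <- pick$seq_b
      pb$penalty <- pick$penalty_b
      if (orientation == "forward") {
        near3 <- max(pa$target_pos, pb$target_pos)
        win <- region_spec(pa$chrom, near3 + arms$common_min,
                           near3 + arms$common_max)
        common <- design_common_primer(win, "reverse", ref,
                                       pileups$A, pileups$B, known_sites, params)
        if (is.null(common)) next
        product_A <- common$end - pa$start + 1L
        product_B <- common$end - pb$start + 1L
        amp_start <- min(pa$start, pb$start); amp_end <- common$end
      } else {
        near3 <- min(pa$target_pos, pb$target_pos)
        win <- region_spec(pa$chrom, near3 - arms$common_max,
                           near3 - arms$common_min)
        common <- design_common_primer(win, "forward", ref,
                                       pileups$A, pileups$B, known_sites, params)
        if (is.null(common)) next
        product_A <- pa$end - common$start + 1L
        product_B <- pb$end - common$start + 1L
        amp_start <- common$start; amp_end <- max(pa$end, pb$end)
      }
      if (max(product_A, product_B) > arms$max_product) next
      out[[length(out) + 1L]] <- data.frame(
        marker_type = "tri_arms", chrom = pa$chrom,
        snp_A = pa$target_pos, snp_B = pb$target_pos,
        allele_A = pa$allele, allele_B = pb$allele,
        orientation = orientation, spacing = spacing,
        product_A = product_A, product_B = product_B,
        start_A = pa$start, end_A = pa$end, seq_A = pa$seq,
        start_B = pb$start, end_B = pb$end, seq_B = pb$seq,
        start_common = common$start, end_common = common$end,
        seq_common = common$seq,
        amp_start = amp_start, amp_end = amp_end,
        penalty = pa$penalty + pb$penalty + common$penalty,
        trans_risk = !identical(pa$target_label, "homozygous") ||
          !identical(pb$target_label, "homozygous"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_tri())
  res <- do.call(rbind, out)
  if (!is.null(best_per_interval)) res <- .best_per_interval(res, best_per_interval)
  rownames(res) <- NULL
  res
}

.empty_tri <- function() {
  data.frame(marker_type = character(0), chrom = character(0),
             snp_A = integer(0), snp_B = integer(0), allele_A = character(0),
             allele_B = character(0), orientation = character(0),
             spacing = integer(0), product_A = integer(0),
             product_B = integer(0), start_A = integer(0), end_A = integer(0),
             seq_A = character(0), start_B = integer(0), end_B = integer(0),
             seq_B = character(0), start_common = integer(0),
             end_common = integer(0), seq_common = character(0),
             amp_start = integer(0), amp_end = integer(0),
             penalty = numeric(0), trans_risk = logical(0),
             stringsAsFactors = FALSE)
}

.best_per_interval <- function(markers, interval) {
  if (!nrow(markers)) return(markers)
  pos <- if ("snp_pos" %in% names(markers)) markers$snp_pos
         else pmin(markers$snp_A, markers$snp_B)
  bin <- ceiling(pos / interval)
  keep <- unlist(lapply(split(seq_len(nrow(markers)), bin),
                        function(ix) ix[which.min(markers$penalty[ix])]))
  markers[sort(keep), , drop = FALSE]
}

#' Assemble tetra-ARMS markers
#'
#' At every SNP carrying both cultivar-specific primers in opposite
#' orientations, designs a pair of common primers in the left and right
#' flanking windows (`common_min..common_max` bp from the SNP) such that
#' the two allele products differ by at least `min_band_separation`, and
#' emits the minimum-total-penalty marker per SNP (ties broken by leftmost
#' common primer). The outer product spans the two common primers' 5' ends
#' and serves as the amplification control band. To give the band-size
#' constraint room, the best candidate from each third of both windows is
#' considered.
#'
#' @inheritParams assemble_tri_arms
#' @return marker data.frame, one row per emitted tetra-ARMS marker.
#' @export
assemble_tetra_arms <- function(primers, reference, pileups = NULL,
                                params = primer_params(),
                                arms = arms_params(), known_sites = NULL,
                                best_per_interval = NULL) {
  ref <- load_reference(reference)
  sp <- .specifics(primers)
  out <- list()
  for (pos in unique(sp$target_pos)) {
    at <- sp[sp$target_pos == pos, , drop = FALSE]
    chrom <- at$chrom[1]
    combos <- list(c(A = "forward", B = "reverse"),
                   c(A = "reverse", B = "forward"))
    reflen <- Biostrings::width(ref[names(ref) == chrom])
    lw <- region_spec(chrom, max(1L, pos - arms$common_max),
                      max(1L, pos - arms$common_min))
    rw <- region_spec(chrom, min(reflen, pos + arms$common_min),
                      min(reflen, pos + arms$common_max))
    lefts <- .subwindow_candidates(lw, "forward", ref, pileups, known_sites, params)
    rights <- .subwindow_candidates(rw, "reverse", ref, pileups, known_sites, params)
    if (is.null(lefts) || is.null(rights)) next
    best <- NULL
    for (cmb in combos) {
      pa <- at[at$kind == "specific_A" & at$orientation == cmb[["A"]], , drop = FALSE]
      pb <- at[at$kind == "specific_B" & at$orientation == cmb[["B"]], , drop = FALSE]
      if (!nrow(pa) || !nrow(pb)) next
      pa <- pa[1, ]; pb <- pb[1, ]
      fwd_sp <- if (cmb[["A"]] == "forward") pa else pb
      rev_sp <- if (cmb[["A"]] == "forward") pb else pa
      for (i in seq_len(nrow(lefts))) for (j in seq_len(nrow(rights))) {
        cl <- lefts[i, ]; cr <- rights[j, ]
        prod_fwd <- cr$end - fwd_sp$start + 1L      # fwd specific + right common
        prod_rev <- rev_sp$end - cl$start + 1L      # rev specific + left common
        product_A <- if (cmb[["A"]] == "forward") prod_fwd else prod_rev
        product_B <- if (cmb[["A"]] == "forward") prod_rev else prod_fwd
        product_outer <- cr$end - cl$start + 1L
        if (abs(product_A - product_B) < arms$min_band_separation) next
        if (product_outer > arms$max_product) next
        cand <- list(pa = pa, pb = pb, cl = cl, cr = cr,
                     product_A = product_A, product_B = product_B,
                     product_outer = product_outer,
                     penalty = pa$penalty + pb$penalty + cl$penalty + cr$penalty)
        if (is.null(best) || cand$penalty < best$penalty ||
            (cand$penalty == best$penalty &&
             (cand$cl$start < best$cl$start ||
              (cand$cl$start == best$cl$start && cand$cr$start < best$cr$start))))
          best <- cand
      }
    }
    if (is.null(best)) next
    out[[length(out) + 1L]] <- data.frame(
      marker_type = "tetra_arms", chrom = chrom, snp_pos = pos,
      ref_allele = best$pa$allele, alt_allele = best$pb$allele,
      orientation_A = best$pa$orientation,
      product_A = best$product_A, product_B = best$product_B,
      product_outer = best$product_outer,
      start_A = best$pa$start, end_A = best$pa$end, seq_A = best$pa$seq,
      start_B = best$pb$start, end_B = best$pb$end, seq_B = best$pb$seq,
      start_common_left = best$cl$start, end_common_left = best$cl$end,
      seq_common_left = best$cl$seq,
      start_common_right = best$cr$start, end_common_right = best$cr$end,
      seq_common_right = best$cr$seq,
      amp_start = best$cl$start, amp_end = best$cr$end,
      penalty = best$penalty,
      trans_risk = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_tetra())
  res <- do.call(rbind, out)
  if (!is.null(best_per_interval)) res <- .best_per_interval(res, best_per_interval)
  rownames(res) <- NULL
  res
}

.empty_tetra <- function() {
  data.frame(marker_type = character(0), chrom = character(0),
             snp_pos = integer(0), ref_allele = character(0),
             alt_allele = character(0), orientation_A = character(0),
             product_A = integer(0), product_B = integer(0),
             product_outer = integer(0), start_A = integer(0),
             end_A = integer(0), seq_A = character(0), start_B = integer(0),
             end_B = integer(0), seq_B = character(0),
             start_common_left = integer(0), end_common_left = integer(0),
             seq_common_left = character(0), start_common_right = integer(0),
             end_common_right = integer(0), seq_common_right = character(0),
             amp_start = integer(0), amp_end = integer(0),
             penalty = numeric(0), trans_risk = logical(0),
             stringsAsFactors = FALSE)
}

# best candidate from each third of a window (gives the assembly a small
# set of alternatives when band-size constraints reject the global best)
.subwindow_candidates <- function(window, orientation, ref, pileups,
                                  known_sites, params, n_sub = 3L) {
  width <- window$end - window$start + 1L
  cuts <- unique(round(seq(window$start, window$end + 1L, length.out = n_sub + 1L)))
  cand <- list()
  for (k in seq_len(length(cuts) - 1L)) {
    sub <- region_spec(window$chrom, cuts[k], cuts[k + 1L] - 1L)
    if (sub$end - sub$start + 1L < params$len_min) next
    hit <- .common_candidates(sub, orientation, ref, pileups$A, pileups$B,
                              known_sites, params, top = 1L)
    if (!is.null(hit)) cand[[length(cand) + 1L]] <- hit
  }
  if (!length(cand)) return(NULL)
  do.call(rbind, cand)
}

#' In-silico PCR product prediction
#'
#' A product is reported iff each primer anneals with its 3'-terminal base
#' matching the template perfectly and at most one internal mismatch (the
#' deliberate ARMS substitution), the primers face each other, and the
#' span is at most `max_product`. The size is the inclusive span between
#' the outer 5' ends. Serves as the validity oracle for assembled markers.
#'
#' @param fwd,rev forward / reverse primer: a primer data.frame row or a
#'   plain 5'->3' sequence string.
#' @param template full-length haplotype sequence (string), e.g. from
#'   [fixture_haplotypes()].
#' @param max_product largest reportable span (default 2000 bp).
#' @return product size in bp, or `NULL` when no product forms. More than
#'   one amplification locus is an error (non-specific primer pair).
#' @export
in_silico_pcr <- function(fwd, rev, template, max_product = 2000L) {
  fseq <- if (is.character(fwd)) fwd else fwd$seq
  rseq <- if (is.character(rev)) rev else rev$seq
  subj <- Biostrings::DNAString(template)
  fm <- Biostrings::matchPattern(Biostrings::DNAString(fseq), subj,
                                 max.mismatch = 1)
  f_ok <- Biostrings::end(fm)[substr(rep(template, length(fm)),
                                     Biostrings::end(fm),
                                     Biostrings::end(fm)) ==
                              substr(fseq, nchar(fseq), nchar(fseq))]
  rc <- revcomp(rseq)
  rm_ <- Biostrings::matchPattern(Biostrings::DNAString(rc), subj,
                                  max.mismatch = 1)
  r_ok <- Biostrings::start(rm_)[substr(rep(template, length(rm_)),
                                        Biostrings::start(rm_),
                                        Biostrings::start(rm_)) ==
                                 substr(rc, 1, 1)]
  if (!length(f_ok) || !length(r_ok)) return(NULL)
  products <- integer(0)
  for (f3 in f_ok) {
    fstart <- f3 - nchar(fseq) + 1L
    for (r3 in r_ok) {
      rend <- r3 + nchar(rseq) - 1L
      span <- rend - fstart + 1L
      if (r3 >= f3 && rend >= f3 &&
          span >= max(nchar(fseq), nchar(rseq)) && span <= max_product)
        products <- c(products, span)
    }
  }
  if (!length(products)) return(NULL)
  if (length(products) > 1L)
    stop("primer pair amplifies ", length(products),
         " loci on the template (non-specific)", call. = FALSE)
  products
}

#' Marker counts by SNP density
#'
#' Tabulates, per genomic bin, the number of selected SNP sites and the
#' number of markers of each type, supporting the observation that
#' tri-ARMS availability rises with SNP density while tetra-ARMS markers
#' remain available at low density (a tri-ARMS marker needs two nearby
#' cultivar-specific SNPs; a tetra-ARMS marker needs one).
#'
#' @param markers a marker data.frame or a list of them (any mix of tri,
#'   tetra, CAPS outputs).
#' @param sites site data.frame.
#' @param bin_size bin width in bp (default 1 Mb).
#' @return data.frame with `bin, bin_start, bin_end, n_snps` and one
#'   `n_<type>` column per marker type present; empty inputs give an empty
#'   table.
#' @export
marker_density_profile <- function(markers, sites, bin_size = 1e6) {
  if (is.data.frame(markers)) markers <- list(markers)
  markers <- markers[vapply(markers, nrow, integer(1)) > 0]
  if ((is.null(sites) || !nrow(sites)) && !length(markers))
    return(data.frame(bin = integer(0), bin_start = numeric(0),
                      bin_end = numeric(0), n_snps = integer(0)))
  mpos <- lapply(markers, function(m) {
    pos <- if ("snp_pos" %in% names(m)) m$snp_pos else pmin(m$snp_A, m$snp_B)
    data.frame(type = m$marker_type, pos = pos, stringsAsFactors = FALSE)
  })
  mpos <- if (length(mpos)) do.call(rbind, mpos)
          else data.frame(type = character(0), pos = integer(0))
  all_pos <- c(if (!is.null(sites)) sites$pos, mpos$pos)
  bins <- seq_len(max(ceiling(all_pos / bin_size)))
  out <- data.frame(bin = bins, bin_start = (bins - 1) * bin_size + 1,
                    bin_end = bins * bin_size)
  out$n_snps <- if (is.null(sites)) 0L else
    as.integer(table(factor(ceiling(sites$pos / bin_size), levels = bins)))
  for (tp in unique(mpos$type))
    out[[paste0("n_", tp)]] <- as.integer(table(factor(
      ceiling(mpos$pos[mpos$type == tp] / bin_size), levels = bins)))
  out
}
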