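IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

#' Read a restriction-enzyme table
#'
#' TSV with columns `name`, `recognition` (IUPAC), `cut_offset` (position
#' of the top-strand cut within the recognition site: AluI `AG^CT` has
#' offset 2, EcoRI `G^AATTC` offset 1). The table shipped with the package
#' preloads AluI and EcoRI; users may extend it.
#'
#' @param path TSV path; default is the bundled table.
#' @return data.frame `name, recognition, cut_offset`.
#' @export
read_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                            package = "armscaps")) {
  enz <- read_tsv(path)
  stopifnot(all(c("name", "recognition", "cut_offset") %in% names(enz)))
  enz$recognition <- toupper(enz$recognition)
  enz$cut_offset <- as.integer(enz$cut_offset)
  bad <- nchar(enz$recognition) < 4 | enz$cut_offset < 0 |
    enz$cut_offset > nchar(enz$recognition)
  if (any(bad))
    stop("invalid enzyme definition: ",
         paste(enz$name[bad], collapse = ", "), call. = FALSE)
  enz
}

# exact IUPAC match of a concrete ACGT window against a recognition string
.iupac_match <- function(window, recognition) {
  if (nchar(window) != nchar(recognition)) return(FALSE)
  w <- strsplit(window, "")[[1]]
  r <- strsplit(recognition, "")[[1]]
  all(mapply(function(b, code) b %in% IUPAC_SETS[[code]], w, r))
}

.iupac_revcomp <- function(recognition) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(recognition)))
}

.is_palindromic <- function(recognition) {
  identical(recognition, .iupac_revcomp(recognition))
}

#' Find enzymes whose recognition site discriminates a SNP's alleles
#'
#' Slides every window of recognition-site width across the SNP and tests
#' the IUPAC match against the reference-allele and variant-allele
#' sequences (both strands for non-palindromic enzymes). An enzyme
#' discriminates iff at least one window overlapping the SNP matches for
#' exactly one allele and no window matches for the other allele.
#'
#' @param site one site row (`chrom`, `pos`, `ref`, `alt`).
#' @param reference FASTA path or `DNAStringSet`.
#' @param enzymes enzyme data.frame (see [read_enzymes()]).
#' @return data.frame `enzyme, recognition, cut_offset, window_start,
#'   cut_allele` (one row per matching window); zero rows when no enzyme
#'   discriminates.
#' @export
find_discriminating_enzymes <- function(site, reference,
                                        enzymes = read_enzymes()) {
  ref <- load_reference(reference)
  chrom <- site$chrom[1]; pos <- as.integer(site$pos[1])
  out <- list()
  for (e in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[e]
    L <- nchar(rec)
    reflen <- Biostrings::width(ref[names(ref) == chrom])
    if (pos - L + 1L < 1L || pos + L - 1L > reflen) next
    ctx_ref <- ref_substring(ref, chrom, pos - L + 1L, pos + L - 1L)
    ctx_alt <- ctx_ref
    substr(ctx_alt, L, L) <- site$alt[1]
    if (substr(ctx_ref, L, L) != site$ref[1])
      stop("site ref allele disagrees with the reference sequence",
           call. = FALSE)
    pats <- rec
    if (!.is_palindromic(rec)) pats <- c(rec, .iupac_revcomp(rec))
    hit_ref <- hit_alt <- logical(L)
    for (i in seq_len(L)) {
      w_ref <- substr(ctx_ref, i, i + L - 1L)
      w_alt <- substr(ctx_alt, i, i + L - 1L)
      hit_ref[i] <- any(vapply(pats, .iupac_match, logical(1), window = w_ref))
      hit_alt[i] <- any(vapply(pats, .iupac_match, logical(1), window = w_alt))
    }
    if (xor(any(hit_ref), any(hit_alt))) {
      cut_allele <- if (any(hit_ref)) "ref" else "alt"
      wins <- which(if (any(hit_ref)) hit_ref else hit_alt)
      out[[length(out) + 1L]] <- data.frame(
        enzyme = enzymes$name[e], recognition = rec,
        cut_offset = enzymes$cut_offset[e],
        window_start = pos - L + wins, cut_allele = cut_allele,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(enzyme = character(0), recognition = character(0),
                      cut_offset = integer(0), window_start = integer(0),
                      cut_allele = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Predict restriction fragments of a PCR product
#'
#' Cuts at every IUPAC match of the recognition site (both strands, with
#' the offset mirrored, when the site is not palindromic) and returns the
#' fragment lengths in positional order (left to right along the product).
#' A product with no site is returned whole.
#'
#' @param product_sequence product sequence over `A/C/G/T`.
#' @param enzyme one enzyme row (`recognition`, `cut_offset`).
#' @return integer vector of fragment lengths summing to the product size.
#' @export
digest <- function(product_sequence, enzyme) {
  rec <- enzyme$recognition[1]
  off <- as.integer(enzyme$cut_offset[1])
  len <- nchar(product_sequence)
  subj <- Biostrings::DNAString(product_sequence)
  cut_at <- function(pattern, offset) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subj,
                                  fixed = FALSE)
    Biostrings::start(m) - 1L + offset
  }
  cuts <- cut_at(rec, off)
  if (!.is_palindromic(rec))
    cuts <- c(cuts, cut_at(.iupac_revcomp(rec), nchar(rec) - off))
  cuts <- sort(unique(cuts[cuts >= 1L & cuts <= len - 1L]))
  as.integer(diff(c(0L, cuts, len)))
}

#' CAPS design parameters
#'
#' @param product_min,product_max allowed PCR product size (bp).
#' @param flank_min,flank_max primer-window distance from the SNP (bp).
#' @param min_band_separation smallest resolvable fragment-size difference
#'   between the two allele patterns (bp).
#' @return a `caps_params` list.
#' @export
caps_params <- function(product_min = 200L, product_max = 1000L,
                        flank_min = 100L, flank_max = 450L,
                        min_band_separation = 50L) {
  structure(list(product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 flank_min = as.integer(flank_min),
                 flank_max = as.integer(flank_max),
                 min_band_separation = as.integer(min_band_separation)),
            class = "caps_params")
}

# every fragment unique to one allele's pattern must sit at least min_sep
# away from every fragment of the other pattern ("distinguishable bands")
.bands_distinguishable <- function(f1, f2, min_sep) {
  u1 <- .multiset_diff(f1, f2)
  u2 <- .multiset_diff(f2, f1)
  if (!length(u1) && !length(u2)) return(FALSE)
  ok1 <- !length(u1) || all(vapply(u1, function(x) min(abs(x - f2)) >= min_sep,
                                   logical(1)))
  ok2 <- !length(u2) || all(vapply(u2, function(x) min(abs(x - f1)) >= min_sep,
                                   logical(1)))
  ok1 && ok2
}

.multiset_diff <- function(a, b) {
  for (x in b) {
    i <- match(x, a)
    if (!is.na(i)) a <- a[-i]
  }
  a
}

#' Design a CAPS marker at a discriminated SNP
#'
#' Designs polymorphism-free, depth-valid flanking primers (via
#' [design_common_primer()], searching the best candidate in each third of
#' both flank windows), keeps primer pairs whose product size lies within
#' `[product_min, product_max]`, predicts the fragment patterns of both
#' allele products with [digest()] (counting every site of the enzyme in
#' the product, invariant and discriminating), rejects candidates whose
#' band patterns are not distinguishable at `min_band_separation`, and
#' returns the minimum-penalty accepted marker across all discriminating
#' enzymes.
#'
#' @param site one site row.
#' @param enzyme_hits result of [find_discriminating_enzymes()] for `site`.
#' @param reference FASTA path or `DNAStringSet`.
#' @param pileups optional `list(A = , B = )` pileups.
#' @param params a [primer_params()].
#' @param caps a [caps_params()].
#' @param known_sites optional site data.frame excluded from primer
#'   footprints (defaults to the target site itself).
#' @return one-row marker data.frame, or `NULL` when no design is
#'   acceptable. `fragments_ref` / `fragments_alt` are sorted,
#'   comma-joined bp lists.
#' @export
design_caps_marker <- function(site, enzyme_hits, reference, pileups = NULL,
                               params = primer_params(),
                               caps = caps_params(), known_sites = NULL) {
  if (is.null(enzyme_hits) || !nrow(enzyme_hits)) return(NULL)
  ref <- load_reference(reference)
  chrom <- site$chrom[1]; pos <- as.integer(site$pos[1])
  reflen <- Biostrings::width(ref[names(ref) == chrom])
  if (is.null(known_sites))
    known_sites <- data.frame(pos = pos)
  lw <- region_spec(chrom, max(1L, pos - caps$flank_max),
                    max(1L, pos - caps$flank_min))
  rw <- region_spec(chrom, min(reflen, pos + caps$flank_min),
                    min(reflen, pos + caps$flank_max))
  lefts <- .subwindow_candidates(lw, "forward", ref, pileups, known_sites, params)
  rights <- .subwindow_candidates(rw, "reverse", ref, pileups, known_sites, params)
  if (is.null(lefts) || is.null(rights)) return(NULL)
  best <- NULL
  for (ename in unique(enzyme_hits$enzyme)) {
    hit <- enzyme_hits[enzyme_hits$enzyme == ename, , drop = FALSE][1, ]
    for (i in seq_len(nrow(lefts))) for (j in seq_len(nrow(rights))) {
      fwd <- lefts[i, ]; rev <- rights[j, ]
      size <- rev$end - fwd$start + 1L
      if (size < caps$product_min || size > caps$product_max) next
      prod_ref <- ref_substring(ref, chrom, fwd$start, rev$end)
      prod_alt <- prod_ref
      substr(prod_alt, pos - fwd$start + 1L, pos - fwd$start + 1L) <- site$alt[1]
      fr_ref <- digest(prod_ref, hit)
      fr_alt <- digest(prod_alt, hit)
      if (!.bands_distinguishable(fr_ref, fr_alt, caps$min_band_separation)) next
      penalty <- fwd$penalty + rev$penalty
      cand <- list(fwd = fwd, rev = rev, hit = hit, size = size,
                   fr_ref = fr_ref, fr_alt = fr_alt, penalty = penalty)
      if (is.null(best) || cand$penalty < best$penalty ||
          (cand$penalty == best$penalty && cand$fwd$start < best$fwd$start))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  data.frame(marker_type = "caps", chrom = chrom, snp_pos = pos,
             ref_allele = site$ref[1], alt_allele = site$alt[1],
             enzyme = best$hit$enzyme, recognition = best$hit$recognition,
             cut_allele = best$hit$cut_allele,
             product_size = best$size,
             fragments_ref = paste(sort(best$fr_ref), collapse = ","),
             fragments_alt = paste(sort(best$fr_alt), collapse = ","),
             start_fwd = best$fwd$start, end_fwd = best$fwd$end,
             seq_fwd = best$fwd$seq,
             start_rev = best$rev$start, end_rev = best$rev$end,
             seq_rev = best$rev$seq,
             amp_start = best$fwd$start, amp_end = best$rev$end,
             penalty = best$penalty, stringsAsFactors = FALSE)
}
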