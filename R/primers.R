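# Deliberate-mismatch substitution applied to the primer-strand base two
# positions upstream of the 3' terminus. Never reproduces the original base
# and never complements the template there; purine<->pyrimidine swaps bias
# toward destabilization.
.MISMATCH_SUB <- c(A = "C", C = "A", G = "T", T = "G")

#' Primer design parameters
#'
#' Thermodynamic and coverage constraints every primer candidate must meet.
#' Length/Tm/GC defaults mirror the usual PCR primer-design defaults; the
#' coverage bounds apply to every position of a primer's genomic footprint
#' in both cultivars.
#'
#' @param len_min,len_opt,len_max primer length bounds/optimum (nt).
#' @param tm_min,tm_opt,tm_max melting temperature bounds/optimum (deg C,
#'   see [melting_temperature()] for the model and assay conditions).
#' @param gc_min,gc_max GC content bounds (percent).
#' @param max_single_base_run longest tolerated homopolymer run.
#' @param min_depth,max_depth footprint coverage bounds (reads).
#' @param tolA SNP-index above which a non-reference base marks a position
#'   polymorphic (footprint exclusion and common-primer consensus check).
#'   Defaults to 0.1 — unlike site *selection*, where strict 0 enforces
#'   cultivar specificity, the footprint screen must tolerate the stray
#'   error reads any real alignment carries, or at realistic depths most
#'   windows would contain at least one spuriously "polymorphic" base.
#' @return a `primer_params` list.
#' @export
primer_params <- function(len_min = 18L, len_opt = 22L, len_max = 28L,
                          tm_min = 57, tm_opt = 60, tm_max = 63,
                          gc_min = 30, gc_max = 70,
                          max_single_base_run = 4L,
                          min_depth = 6L, max_depth = Inf, tolA = 0.1) {
  stopifnot(len_min <= len_opt, len_opt <= len_max,
            tm_min <= tm_opt, tm_opt <= tm_max, len_min >= 8)
  structure(list(len_min = as.integer(len_min), len_opt = as.integer(len_opt),
                 len_max = as.integer(len_max), tm_min = tm_min,
                 tm_opt = tm_opt, tm_max = tm_max, gc_min = gc_min,
                 gc_max = gc_max,
                 max_single_base_run = as.integer(max_single_base_run),
                 min_depth = min_depth, max_depth = max_depth, tolA = tolA),
            class = "primer_params")
}

#' Penalty of a primer candidate
#'
#' `|tm - tm_opt| + 0.5 * |len - len_opt|`. Candidates violating hard
#' constraints never reach scoring; among valid candidates the minimum
#' penalty wins, ties broken by smaller start coordinate, then by
#' lexicographically smaller sequence.
#'
#' @param candidate list or data.frame row with `tm` and either `len` or
#'   `seq`.
#' @param params a [primer_params()].
#' @return non-negative score.
#' @export
primer_penalty <- function(candidate, params = primer_params()) {
  len <- if (!is.null(candidate$len)) candidate$len else nchar(candidate$seq)
  abs(candidate$tm - params$tm_opt) + 0.5 * abs(len - params$len_opt)
}

# per-row maximum non-reference SNP-index of a pileup; cached as an
# attribute by prepare_pileups() so repeated footprint screens over a large
# region stay O(footprint), not O(region)
.pileup_summary <- function(pileup) {
  s <- attr(pileup, "summary")
  if (!is.null(s)) return(s)
  if (is.null(pileup) || !nrow(pileup))
    return(list(pos = integer(0), depth = integer(0),
                max_nonref = numeric(0)))
  cnt <- as.matrix(pileup[, BASES])
  cnt[cbind(seq_len(nrow(pileup)), match(pileup$ref, BASES))] <- 0L
  list(pos = pileup$pos, depth = pileup$depth,
       max_nonref = do.call(pmax, as.data.frame(cnt)) / pileup$depth)
}

#' Precompute footprint-screening summaries for a pileup set
#'
#' Attaches a per-position summary (depth, maximum non-reference
#' SNP-index) to each pileup so that repeated primer-footprint screens do
#' not rescan the whole region. Purely an optimization; results are
#' identical with or without it.
#'
#' @param pileups `list(A = , B = )` of pileup data.frames.
#' @return the same list with summaries attached.
#' @export
prepare_pileups <- function(pileups) {
  for (nm in names(pileups)) {
    if (is.null(pileups[[nm]])) next
    attr(pileups[[nm]], "summary") <- NULL
    attr(pileups[[nm]], "summary") <- .pileup_summary(pileups[[nm]])
  }
  pileups
}

# positions where any non-reference base rises above tolA in a pileup
.polymorphic_positions <- function(pileup, tolA) {
  s <- .pileup_summary(pileup)
  s$pos[s$max_nonref > tolA]
}

# per-position validity masks over [start, end]: masks$bad[i] is TRUE when
# position start+i-1 is polymorphic or has out-of-range depth in either
# cultivar. With no pileups supplied, coverage checks are skipped.
.footprint_masks <- function(pileups, start, end, params,
                             known_pos = integer(0)) {
  n <- end - start + 1L
  bad <- logical(n)
  inb <- function(p) p[p >= start & p <= end] - start + 1L
  bad[inb(known_pos)] <- TRUE
  for (pu in pileups) {
    if (is.null(pu)) next
    s <- .pileup_summary(pu)
    i1 <- findInterval(start - 1L, s$pos) + 1L
    i2 <- findInterval(end, s$pos)
    depth <- integer(n)
    if (i2 >= i1) {
      sl <- i1:i2
      bad[s$pos[sl][s$max_nonref[sl] > params$tolA] - start + 1L] <- TRUE
      depth[s$pos[sl] - start + 1L] <- s$depth[sl]
    }
    bad[depth < params$min_depth | depth > params$max_depth] <- TRUE
  }
  bad
}

.empty_primers <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             orientation = character(0), kind = character(0),
             target_pos = integer(0), target_label = character(0),
             allele = character(0), seq = character(0), tm = numeric(0),
             gc = numeric(0), penalty = numeric(0), mismatch_pos = integer(0),
             stringsAsFactors = FALSE)
}

# all valid allele-specific candidates (one per acceptable length) for one
# (site, allele, orientation) slot; shared by design_specific_primers and
# by tri-ARMS assembly, which re-selects a common length for each pair so
# that the band-size difference equals the SNP spacing exactly
.specific_candidates <- function(chrom, pos, allele, orientation, ref,
                                 pileups, params) {
  reflen <- Biostrings::width(ref[names(ref) == chrom])
  lo <- max(1L, pos - params$len_max)
  hi <- min(reflen, pos + params$len_max)
  bad <- .footprint_masks(pileups, lo, hi, params)
  bad[pos - lo + 1L] <- FALSE  # the target SNP itself is allowed
  ctx <- ref_substring(ref, chrom, lo, hi)
  out <- list()
  for (len in params$len_min:params$len_max) {
    if (orientation == "forward") {
      fs <- pos - len + 1L; fe <- pos
    } else {
      fs <- pos; fe <- pos + len - 1L
    }
    if (fs < 1L || fe > reflen) next
    if (any(bad[(fs - lo + 1L):(fe - lo + 1L)])) next
    tmpl <- substr(ctx, fs - lo + 1L, fe - lo + 1L)
    if (orientation == "forward") {
      s <- tmpl
      substr(s, len, len) <- allele
    } else {
      substr(tmpl, 1L, 1L) <- allele
      s <- revcomp(tmpl)
    }
    orig <- substr(s, len - 2L, len - 2L)
    substr(s, len - 2L, len - 2L) <- .MISMATCH_SUB[[orig]]
    if (max_base_run(s) > params$max_single_base_run) next
    gc <- gc_percent(s)
    if (gc < params$gc_min || gc > params$gc_max) next
    tm <- melting_temperature(s)
    if (tm < params$tm_min || tm > params$tm_max) next
    out[[length(out) + 1L]] <- data.frame(
      len = len, start = fs, end = fe, seq = s, tm = tm, gc = gc,
      penalty = primer_penalty(list(tm = tm, len = len), params),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Design cultivar-specific ARMS primers at a SNP site
#'
#' Attempts forward and reverse primers for each of the two alleles (up to
#' four per site). A candidate's 3' end is fixed on the SNP with the
#' terminal base equal to the targeted allele on the primer strand; the
#' base at 3'-offset 3 (two bases upstream of the terminus) carries the
#' deliberate destabilizing substitution (`A->C, C->A, G->T, T->G`, applied
#' to the primer-strand base). Lengths `len_min..len_max` are scanned;
#' candidates violating Tm/GC/run-length constraints, overlapping another
#' polymorphic position, or with out-of-range footprint coverage are
#' rejected; the minimum-penalty candidate per (allele, orientation) is
#' returned.
#'
#' @param site one site row (see [select_target_snps()]); needs `chrom`,
#'   `pos`, `ref`, `alt` (and optionally `label`).
#' @param reference FASTA path or `DNAStringSet`.
#' @param pileups optional `list(A = , B = )` of pileups for coverage and
#'   polymorphism screening (`NULL` skips those checks).
#' @param params a [primer_params()].
#' @return primer data.frame (0-4 rows): `chrom, start, end, orientation,
#'   kind, target_pos, target_label, allele, seq, tm, gc, penalty,
#'   mismatch_pos` (`mismatch_pos` is the fixed 3'-offset, 3). Footprint
#'   coordinates are always on the reference strand; `seq` is 5'->3' on the
#'   primer strand.
#' @export
design_specific_primers <- function(site, reference, pileups = NULL,
                                    params = primer_params()) {
  ref <- load_reference(reference)
  chrom <- site$chrom[1]; pos <- as.integer(site$pos[1])
  label <- if (!is.null(site$label)) site$label[1] else NA_character_
  out <- list()
  for (allele in c(site$ref[1], site$alt[1])) {
    kind <- if (allele == site$ref[1]) "specific_A" else "specific_B"
    for (orientation in c("forward", "reverse")) {
      cand <- .specific_candidates(chrom, pos, allele, orientation, ref,
                                   pileups, params)
      if (is.null(cand)) next
      cand <- cand[order(cand$penalty, cand$start, cand$seq), , drop = FALSE]
      best <- cand[1, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = best$start, end = best$end,
        orientation = orientation, kind = kind, target_pos = pos,
        target_label = label, allele = allele, seq = best$seq,
        tm = best$tm, gc = best$gc, penalty = best$penalty,
        mismatch_pos = 3L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_primers())
  do.call(rbind, out)
}

# enumerate valid common-primer candidates in a window; returns a
# data.frame sorted by (penalty, start, seq), possibly empty
.common_candidates <- function(window, orientation, ref, pileups_A, pileups_B,
                               known_sites, params, top = 1L) {
  chrom <- window$chrom
  reflen <- Biostrings::width(ref[names(ref) == chrom])
  ws <- max(1L, window$start); we <- min(reflen, window$end)
  if (we - ws + 1L < params$len_min) return(NULL)
  known_pos <- if (!is.null(known_sites)) as.integer(known_sites$pos) else integer(0)
  bad <- .footprint_masks(list(pileups_A, pileups_B), ws, we, params, known_pos)
  win <- ref_substring(ref, chrom, ws, we)
  n <- we - ws + 1L
  lens <- params$len_min:params$len_max
  grid <- expand.grid(start = seq_len(n), len = lens)
  grid <- grid[grid$start + grid$len - 1L <= n, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  # footprints containing any bad position are invalid
  cum_bad <- c(0L, cumsum(bad))
  nbad <- cum_bad[grid$start + grid$len] - cum_bad[grid$start]
  grid <- grid[nbad == 0L, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  st <- .window_candidate_stats(win, grid$start, grid$len)
  ok <- st$tm >= params$tm_min & st$tm <= params$tm_max &
    st$gc >= params$gc_min & st$gc <= params$gc_max &
    st$max_run <= params$max_single_base_run
  if (!any(ok)) return(NULL)
  grid <- grid[ok, , drop = FALSE]; st <- st[ok, , drop = FALSE]
  pen <- abs(st$tm - params$tm_opt) + 0.5 * abs(grid$len - params$len_opt)
  fs <- ws + grid$start - 1L
  fe <- fs + grid$len - 1L
  seqs <- substring(win, grid$start, grid$start + grid$len - 1L)
  if (orientation == "reverse") seqs <- revcomp(seqs)
  o <- order(pen, fs, seqs)
  take <- o[seq_len(min(top, length(o)))]
  data.frame(chrom = chrom, start = fs[take], end = fe[take],
             orientation = orientation, kind = "common",
             target_pos = NA_integer_, target_label = NA_character_,
             allele = NA_character_, seq = seqs[take], tm = st$tm[take],
             gc = st$gc[take], penalty = pen[take], mismatch_pos = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Design a common primer on polymorphism-free consensus sequence
#'
#' Finds the minimum-penalty primer whose footprint lies within `window`,
#' matches the reference exactly, contains no position where either
#' cultivar shows a non-reference base above `tolA` (nor any position in
#' `known_sites`), and whose footprint depth is within
#' `[min_depth, max_depth]` for both cultivars.
#'
#' @param window a [region_spec()].
#' @param orientation `"forward"` or `"reverse"` (reverse primers are
#'   reported 5'->3' on their own strand; footprints stay on the reference
#'   strand).
#' @param reference FASTA path or `DNAStringSet`.
#' @param pileups_A,pileups_B optional cultivar pileups.
#' @param known_sites optional data.frame of positions (`pos`) to exclude,
#'   e.g. selected SNP sites.
#' @param params a [primer_params()].
#' @return a one-row primer data.frame, or `NULL` when no candidate is
#'   valid.
#' @export
design_common_primer <- function(window, orientation, reference,
                                 pileups_A = NULL, pileups_B = NULL,
                                 known_sites = NULL,
                                 params = primer_params()) {
  stopifnot(inherits(window, "region_spec"),
            orientation %in% c("forward", "reverse"))
  ref <- load_reference(reference)
  .common_candidates(window, orientation, ref, pileups_A, pileups_B,
                     known_sites, params, top = 1L)
}
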