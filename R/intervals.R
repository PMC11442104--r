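#' Exact binomial confidence interval of the SNP-index
#'
#' For a position sequenced to `depth` reads in a sample of the given
#' `ploidy` carrying `dosage` copies of the variant allele, the observed
#' SNP-index is `X / depth` with `X ~ Binomial(depth, dosage/ploidy)`.
#' The central interval is taken on the exact quantile grid: `lo = q/depth`
#' where `q` is the smallest `k` with `CDF(k) >= (1-confidence)/2`, and
#' `hi = r/depth` where `r` is the smallest `k` with
#' `CDF(k) >= 1-(1-confidence)/2`. This is R's type-1 `qbinom()` convention,
#' stated explicitly so results are bit-reproducible.
#'
#' @param depth coverage depth (reads), integer >= 1.
#' @param dosage variant-allele copies, in `[1, ploidy-1]`.
#' @param ploidy sample ploidy, integer >= 2.
#' @param confidence central coverage, in (0, 1). Default 0.95.
#' @return a `snp_index_interval` list with fields `depth`, `dosage`,
#'   `ploidy`, `confidence`, `lo`, `hi` (both multiples of `1/depth`).
#' @seealso [monte_carlo_interval()], [min_depth_excluding_homozygous()],
#'   [min_discernible_depth()]
#' @export
#' @examples
#' snp_index_interval(6, 1, 2)   # (1/6, 5/6): heterozygous diploid at depth 6
#' snp_index_interval(5, 1, 2)   # [0, 1]: depth 5 cannot exclude homozygotes
snp_index_interval <- function(depth, dosage, ploidy, confidence = 0.95) {
  depth <- as.integer(depth); dosage <- as.integer(dosage); ploidy <- as.integer(ploidy)
  stopifnot(depth >= 1L, ploidy >= 2L)
  if (dosage < 1L || dosage >= ploidy)
    stop("dosage must lie in [1, ploidy-1]", call. = FALSE)
  if (!(confidence > 0 && confidence < 1))
    stop("confidence must lie strictly inside (0, 1)", call. = FALSE)
  p <- dosage / ploidy
  a <- (1 - confidence) / 2
  lo <- qbinom(a, depth, p) / depth
  hi <- qbinom(1 - a, depth, p) / depth
  structure(list(depth = depth, dosage = dosage, ploidy = ploidy,
                 confidence = confidence, lo = lo, hi = hi),
            class = "snp_index_interval")
}

#' Monte-Carlo confidence interval of the SNP-index
#'
#' Simulates SNP-index draws `X/depth`, `X ~ Binomial(depth, dosage/ploidy)`,
#' and takes the empirical central quantiles with the inverse-ECDF (type 1)
#' convention — the smallest draw whose empirical CDF reaches the target —
#' matching the exact-quantile construction of [snp_index_interval()] on
#' the `1/depth` grid. Retained as a stochastic cross-check of the exact
#' interval. Note the agreement guarantee is asymptotic: when the exact
#' binomial CDF sits within sampling noise of a quantile target (gaps of
#' order `1e-4` occur around depth 59), the empirical quantile can land one
#' grid step away; choose `replicates` so the Monte-Carlo standard error
#' `sqrt(target*(1-target)/replicates)` is several times smaller than the
#' smallest such gap.
#'
#' @inheritParams snp_index_interval
#' @param replicates number of simulated draws, >= 10000.
#' @param seed integer RNG seed (caller RNG state is restored).
#' @return a `snp_index_interval` list (same fields as the exact version).
#' @export
monte_carlo_interval <- function(depth, dosage, ploidy, confidence = 0.95,
                                 replicates = 1e5, seed = 1L) {
  if (replicates < 1e4)
    stop("replicates must be at least 10,000", call. = FALSE)
  stopifnot(depth >= 1, ploidy >= 2, dosage >= 1, dosage < ploidy,
            confidence > 0, confidence < 1)
  p <- dosage / ploidy
  x <- with_seed(seed, rbinom(replicates, depth, p))
  # inverse empirical CDF on the 0..depth grid (equivalent to the type-1
  # sample quantile, without sorting the draws)
  ecdf_steps <- cumsum(tabulate(x + 1L, nbins = depth + 1L)) / replicates
  a <- (1 - confidence) / 2
  lo <- (which(ecdf_steps >= a)[1] - 1L) / depth
  hi <- (which(ecdf_steps >= 1 - a)[1] - 1L) / depth
  structure(list(depth = as.integer(depth), dosage = as.integer(dosage),
                 ploidy = as.integer(ploidy), confidence = confidence,
                 lo = lo, hi = hi),
            class = "snp_index_interval")
}

#' Minimal depth at which heterozygous and homozygous calls separate
#'
#' Smallest coverage depth whose SNP-index confidence interval for the given
#' heterozygous dosage excludes both homozygous indices (0 and 1), i.e.
#' `lo > 0` and `hi < 1`. Below this depth a homozygous position cannot be
#' reliably distinguished from a heterozygous one.
#'
#' @inheritParams snp_index_interval
#' @param max_depth scan bound (defensive; the result is small in practice).
#' @return the minimal depth (integer).
#' @export
#' @examples
#' min_depth_excluding_homozygous(2, 1)  # 6 for a diploid heterozygote
min_depth_excluding_homozygous <- function(ploidy = 2, dosage = 1,
                                           confidence = 0.95, max_depth = 10000L) {
  if (confidence >= 1 || confidence <= 0)
    stop("confidence must lie strictly inside (0, 1)", call. = FALSE)
  for (d in seq_len(max_depth)) {
    iv <- snp_index_interval(d, dosage, ploidy, confidence)
    if (iv$lo > 0 && iv$hi < 1) return(d)
  }
  stop("no depth up to ", max_depth, " separates the genotypes", call. = FALSE)
}

#' Minimal depth at which all heterozygous dosage classes are discernible
#'
#' Smallest depth at which the SNP-index confidence intervals for dosages
#' `1..ploidy-1` are pairwise disjoint as closed intervals (the `hi` of each
#' lower dosage strictly below the `lo` of the next). Disjointness of closed
#' intervals is the strictest reading of "discernible" and is stated
#' explicitly because the notion is otherwise convention-dependent.
#'
#' @inheritParams snp_index_interval
#' @param max_depth scan bound.
#' @return the minimal depth (integer).
#' @export
#' @examples
#' min_discernible_depth(4)  # simplex/duplex/triplex in an autotetraploid
min_discernible_depth <- function(ploidy = 4, confidence = 0.95,
                                  max_depth = 10000L) {
  ploidy <- as.integer(ploidy)
  if (ploidy < 3L)
    stop("ploidy must be >= 3 (a diploid has a single heterozygous class; ",
         "see min_depth_excluding_homozygous)", call. = FALSE)
  for (d in 2:max_depth) {
    ivs <- lapply(seq_len(ploidy - 1L), snp_index_interval,
                  depth = d, ploidy = ploidy, confidence = confidence)
    his <- vapply(ivs, `[[`, numeric(1), "hi")
    los <- vapply(ivs, `[[`, numeric(1), "lo")
    if (all(his[-length(his)] < los[-1])) return(d)
  }
  stop("no depth up to ", max_depth, " makes all dosages discernible",
       call. = FALSE)
}

#' Tabulate SNP-index intervals over a depth range
#'
#' @param depths integer vector of depths.
#' @param ploidy sample ploidy.
#' @param dosages dosage classes to tabulate (default all heterozygous).
#' @param confidence central coverage.
#' @return data.frame with columns depth, dosage, ploidy, lo, hi.
#' @export
snp_index_interval_table <- function(depths, ploidy = 2,
                                     dosages = seq_len(ploidy - 1),
                                     confidence = 0.95) {
  grid <- expand.grid(depth = depths, dosage = dosages)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    iv <- snp_index_interval(grid$depth[i], grid$dosage[i], ploidy, confidence)
    data.frame(depth = iv$depth, dosage = iv$dosage, ploidy = iv$ploidy,
               lo = iv$lo, hi = iv$hi)
  })
  do.call(rbind, rows)
}

#' @export
print.snp_index_interval <- function(x, ...) {
  cat(sprintf("SNP-index %.0f%% interval: depth %d, dosage %d/%d -> [%.4f, %.4f]\n",
              100 * x$confidence, x$depth, x$dosage, x$ploidy, x$lo, x$hi))
  invisible(x)
}
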