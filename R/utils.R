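#' @keywords internal
"_PACKAGE"

#' @importFrom stats pbinom qbinom quantile rbinom runif
#' @importFrom utils read.delim write.table
#' @importFrom methods is
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# reverse complement of a plain character string (thin wrapper so that
# sequence strings never need to round-trip through XString in hot loops)
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

gc_percent <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

max_base_run <- function(seq) {
  max(rle(strsplit(seq, "")[[1]])$lengths)
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Read or load a reference genome
#'
#' Accepts either a FASTA file path or an already-loaded
#' [Biostrings::DNAStringSet].
#'
#' @param reference path to a FASTA file, or a `DNAStringSet`.
#' @return a `DNAStringSet` keyed by sequence name.
#' @export
load_reference <- function(reference) {
  if (is(reference, "DNAStringSet")) return(reference)
  ref <- Biostrings::readDNAStringSet(reference)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

# extract reference subsequence [start, end] (1-based inclusive) as a string
ref_substring <- function(reference, chrom, start, end) {
  if (!chrom %in% names(reference))
    stop("sequence '", chrom, "' not present in the reference", call. = FALSE)
  as.character(Biostrings::subseq(reference[[chrom]], start, end))
}

#' Specify a genomic region
#'
#' @param chrom sequence name.
#' @param start,end 1-based inclusive bounds, `end >= start >= 1`.
#' @return a `region_spec` list.
#' @export
region_spec <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(chrom) == 1, start >= 1L, end >= start)
  structure(list(chrom = chrom, start = start, end = end), class = "region_spec")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
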