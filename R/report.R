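# primer footprints of a marker row, by marker type
.marker_primers <- function(marker) {
  switch(marker$marker_type,
    tri_arms = data.frame(
      name = c("specific_A", "specific_B", "common"),
      start = c(marker$start_A, marker$start_B, marker$start_common),
      end = c(marker$end_A, marker$end_B, marker$end_common),
      seq = c(marker$seq_A, marker$seq_B, marker$seq_common),
      stringsAsFactors = FALSE),
    tetra_arms = data.frame(
      name = c("specific_A", "specific_B", "common_left", "common_right"),
      start = c(marker$start_A, marker$start_B, marker$start_common_left,
                marker$start_common_right),
      end = c(marker$end_A, marker$end_B, marker$end_common_left,
              marker$end_common_right),
      seq = c(marker$seq_A, marker$seq_B, marker$seq_common_left,
              marker$seq_common_right),
      stringsAsFactors = FALSE),
    caps = data.frame(
      name = c("forward", "reverse"),
      start = c(marker$start_fwd, marker$start_rev),
      end = c(marker$end_fwd, marker$end_rev),
      seq = c(marker$seq_fwd, marker$seq_rev),
      stringsAsFactors = FALSE),
    stop("unknown marker type: ", marker$marker_type, call. = FALSE))
}

.marker_snps <- function(marker) {
  if (marker$marker_type == "tri_arms") c(marker$snp_A, marker$snp_B)
  else marker$snp_pos
}

.marker_products <- function(marker) {
  switch(marker$marker_type,
    tri_arms = c(product_A = marker$product_A, product_B = marker$product_B),
    tetra_arms = c(product_A = marker$product_A, product_B = marker$product_B,
                   product_outer = marker$product_outer),
    caps = c(product = marker$product_size))
}

#' Annotate a marker's amplicon with polymorphism and coverage flags
#'
#' Flags every amplicon position that is polymorphic (either cultivar
#' shows a non-reference base above `tolA`) or whose coverage depth lies
#' outside `[min_depth, max_depth]` in either cultivar — the positions a
#' user should inspect before trusting the marker.
#'
#' @param marker one marker row (tri/tetra/CAPS output).
#' @param reference FASTA path or `DNAStringSet`.
#' @param pileups_A,pileups_B cultivar pileups; they must cover the
#'   amplicon (an error otherwise).
#' @param params a [primer_params()] supplying `tolA` and the depth range.
#' @return a `marker_annotation` list: `chrom`, `amp_start`, `amp_end`,
#'   `seq`, logical vectors `polymorphic` and `depth_out_of_range` (one
#'   element per amplicon position), `primers` (footprint table),
#'   `snp_pos`, `products`, and the `marker` row itself.
#' @export
annotate_marker <- function(marker, reference, pileups_A, pileups_B,
                            params = primer_params()) {
  stopifnot(nrow(marker) == 1)
  ref <- load_reference(reference)
  amp_start <- marker$amp_start; amp_end <- marker$amp_end
  for (pu in list(pileups_A, pileups_B)) {
    reg <- attr(pu, "region")
    covered <- if (!is.null(reg))
      reg$chrom == marker$chrom && reg$start <= amp_start && reg$end >= amp_end
    else nrow(pu) > 0 && min(pu$pos) <= amp_start && max(pu$pos) >= amp_end
    if (!covered)
      stop("pileup does not cover the amplicon [", amp_start, ", ",
           amp_end, "]", call. = FALSE)
  }
  n <- amp_end - amp_start + 1L
  poly <- logical(n); oob <- logical(n)
  for (pu in list(pileups_A, pileups_B)) {
    pp <- .polymorphic_positions(pu, params$tolA)
    pp <- pp[pp >= amp_start & pp <= amp_end]
    poly[pp - amp_start + 1L] <- TRUE
    depth <- integer(n)
    hit <- pu$pos >= amp_start & pu$pos <= amp_end
    depth[pu$pos[hit] - amp_start + 1L] <- pu$depth[hit]
    oob[depth < params$min_depth | depth > params$max_depth] <- TRUE
  }
  structure(list(marker = marker, chrom = marker$chrom,
                 amp_start = amp_start, amp_end = amp_end,
                 seq = ref_substring(ref, marker$chrom, amp_start, amp_end),
                 polymorphic = poly, depth_out_of_range = oob,
                 primers = .marker_primers(marker),
                 snp_pos = .marker_snps(marker),
                 products = .marker_products(marker)),
            class = "marker_annotation")
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# amplicon sequence as character spans with CSS classes:
#   snp   — targeted SNP position(s)
#   poly  — position polymorphic in either cultivar
#   oob   — coverage depth outside the configured range
#   primer — inside a primer footprint
.render_amplicon <- function(ann) {
  n <- nchar(ann$seq)
  cls <- character(n)
  in_primer <- logical(n)
  for (k in seq_len(nrow(ann$primers))) {
    i <- (max(ann$primers$start[k], ann$amp_start):
          min(ann$primers$end[k], ann$amp_end)) - ann$amp_start + 1L
    in_primer[i] <- TRUE
  }
  add <- function(cur, tag, on) ifelse(on, paste(cur, tag), cur)
  cls <- add(cls, "primer", in_primer)
  cls <- add(cls, "poly", ann$polymorphic)
  cls <- add(cls, "oob", ann$depth_out_of_range)
  snp_i <- ann$snp_pos - ann$amp_start + 1L
  cls[snp_i] <- paste(cls[snp_i], "snp")
  cls <- trimws(cls)
  bases <- strsplit(ann$seq, "")[[1]]
  spans <- ifelse(cls == "", bases,
                  sprintf('<span class="%s">%s</span>', cls, bases))
  chunks <- tapply(spans, (seq_len(n) - 1L) %/% 60L, paste, collapse = "")
  paste0("<div class=\"amplicon\"><code>",
         paste(chunks, collapse = "<br/>"), "</code></div>")
}

.render_marker_section <- function(ann) {
  m <- ann$marker
  title <- sprintf("%s %s:%d-%d", m$marker_type, ann$chrom,
                   ann$amp_start, ann$amp_end)
  prods <- paste(sprintf("%s = %d bp", names(ann$products), ann$products),
                 collapse = ", ")
  rows <- sprintf(
    "<tr><td>%s</td><td><code>%s</code></td><td>%d</td><td>%d</td></tr>",
    ann$primers$name, .html_escape(ann$primers$seq),
    ann$primers$start, ann$primers$end)
  extra <- ""
  if (m$marker_type == "caps")
    extra <- sprintf(
      "<p>enzyme %s (%s), cut allele: %s; fragments ref: %s; fragments alt: %s</p>",
      m$enzyme, m$recognition, m$cut_allele, m$fragments_ref, m$fragments_alt)
  if (!is.null(m$trans_risk) && isTRUE(m$trans_risk))
    extra <- paste0(extra, "<p class=\"warn\">heterozygous site pair: ",
                    "cis/trans phase unverified</p>")
  paste0(
    "<section class=\"marker\">\n",
    "<h2>", title, "</h2>\n",
    "<p>target SNP position(s): ", paste(ann$snp_pos, collapse = ", "),
    "; product size(s): ", prods, "</p>\n", extra,
    "<table><tr><th>primer</th><th>sequence 5'&rarr;3'</th>",
    "<th>start</th><th>end</th></tr>\n",
    paste(rows, collapse = "\n"), "\n</table>\n",
    .render_amplicon(ann), "\n</section>")
}

#' Render the marker report as a self-contained HTML document
#'
#' Lists, per marker, the amplified region, product size(s), the target
#' SNP position(s) and all primer sequences; amplicon positions that are
#' polymorphic or outside the coverage-depth range carry the documented
#' CSS classes `poly` and `oob` (primer footprints `primer`, the targeted
#' SNP `snp`). Byte-deterministic for fixed inputs: run metadata is
#' isolated in a single header block.
#'
#' @param annotations list of [annotate_marker()] results.
#' @param metadata named list rendered in the report header.
#' @return the HTML document as a single character string.
#' @export
render_html <- function(annotations, metadata = list()) {
  meta <- if (length(metadata))
    paste(sprintf("<li>%s: %s</li>", .html_escape(names(metadata)),
                  .html_escape(as.character(unlist(metadata)))),
          collapse = "\n")
  else ""
  css <- paste(
    "body{font-family:sans-serif;margin:2em}",
    "code{letter-spacing:1px}",
    ".poly{background:#f6c6c6}",
    ".oob{color:#b36b00;text-decoration:underline}",
    ".primer{background:#d6e4f0}",
    ".snp{font-weight:bold;background:#c9e8c9}",
    ".warn{color:#a00}",
    "table{border-collapse:collapse} td,th{border:1px solid #999;padding:2px 6px}",
    sep = "\n")
  sections <- vapply(annotations, .render_marker_section, character(1))
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>marker report</title>\n<style>\n", css, "\n</style>\n</head>\n",
    "<body>\n<h1>ARMS/CAPS marker report</h1>\n",
    "<div class=\"metadata\"><ul>\n", meta, "\n</ul></div>\n",
    if (length(sections)) paste(sections, collapse = "\n") else "",
    "\n</body>\n</html>\n")
}

#' Write the marker report to a file
#'
#' @inheritParams render_html
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_html_report <- function(annotations, path, metadata = list()) {
  writeLines(render_html(annotations, metadata), path, sep = "")
  invisible(path)
}
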