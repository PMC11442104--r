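# Nearest-neighbor duplex thermodynamics, unified DNA parameters
# (Allawi & SantaLucia 1997). dH in kcal/mol, dS in cal/(mol K).
.NN_H <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
.NN_S <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9)
# duplex initiation per terminal base pair
.INIT_H <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.INIT_S <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

.GAS_R <- 1.987          # cal/(mol K)
.TM_NA_M <- 0.05         # 50 mM monovalent salt
.TM_CT_M <- 50e-9        # 50 nM total oligo; effective concentration CT/4

#' Nearest-neighbor melting temperature of an oligonucleotide
#'
#' Computes the duplex melting temperature under the unified nearest-neighbor
#' model with entropic salt correction, at fixed assay conditions: 50 mM
#' monovalent salt and 50 nM total oligonucleotide (effective annealing
#' concentration CT/4 = 12.5 nM). Deterministic; used for all primer
#' candidate screening.
#'
#' @param seq primer sequence, 5'->3', `A/C/G/T` only, length >= 8.
#' @return melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("GATCGGAAGAGCACACGTCT")
melting_temperature <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  b <- strsplit(seq, "")[[1]]
  if (length(b) < 8) stop("sequence shorter than 8 nt", call. = FALSE)
  if (!all(b %in% BASES))
    stop("ambiguous or non-ACGT base in sequence", call. = FALSE)
  n <- length(b)
  din <- paste0(b[-n], b[-1])
  dH <- sum(.NN_H[din]) + .INIT_H[[b[1]]] + .INIT_H[[b[n]]]
  dS <- sum(.NN_S[din]) + .INIT_S[[b[1]]] + .INIT_S[[b[n]]]
  dS <- dS + 0.368 * (n - 1) * log(.TM_NA_M)
  1000 * dH / (dS + .GAS_R * log(.TM_CT_M / 4)) - 273.15
}

# Vectorized Tm/GC/run screening for all exact-reference candidates in a
# window: cumulative sums over the window's stacks make enumeration O(window)
# instead of O(window x candidates). `win` is the window sequence (string),
# `starts`/`lens` parallel integer vectors of candidate offsets (1-based
# within `win`) and lengths. Returns data.frame(tm, gc, max_run).
.window_candidate_stats <- function(win, starts, lens) {
  b <- strsplit(win, "")[[1]]
  n <- length(b)
  din <- paste0(b[-n], b[-1])
  cumH <- c(0, cumsum(.NN_H[din]))
  cumS <- c(0, cumsum(.NN_S[din]))
  cumGC <- c(0, cumsum(b %in% c("G", "C")))
  ends <- starts + lens - 1L
  dH <- cumH[ends] - cumH[starts] + .INIT_H[b[starts]] + .INIT_H[b[ends]]
  dS <- cumS[ends] - cumS[starts] + .INIT_S[b[starts]] + .INIT_S[b[ends]] +
    0.368 * (lens - 1) * log(.TM_NA_M)
  tm <- 1000 * dH / (dS + .GAS_R * log(.TM_CT_M / 4)) - 273.15
  gc <- 100 * (cumGC[ends + 1L] - cumGC[starts]) / lens
  # longest homopolymer run fully inside [start, end]
  r <- rle(b)
  rend <- cumsum(r$lengths)
  rstart <- rend - r$lengths + 1L
  max_run <- vapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- ends[i]
    idx <- which(rend >= s & rstart <= e)
    max(pmin(rend[idx], e) - pmax(rstart[idx], s) + 1L)
  }, integer(1))
  data.frame(tm = tm, gc = gc, max_run = max_run)
}
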