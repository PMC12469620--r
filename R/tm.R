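#' Nearest-neighbor oligonucleotide melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor
#' thermodynamic parameters (SantaLucia 1998), with the entropic salt
#' correction `dS + 0.368 * (N - 1) * ln[Na+]` and the excess-primer
#' approximation `Tm = 1000 * dH / (dS' + R * ln(C/4)) - 273.15`.
#' Defaults (50 nM oligo, 50 mM monovalent cation) match the customary
#' design-engine settings, so a 20-mer at 50% GC lands near 60 degrees.
#'
#' @param seq character vector of primer sequences, 5'->3', A/C/G/T only
#' @param oligoConc oligo concentration in mol/L
#' @param naConc monovalent cation concentration in mol/L
#' @return numeric vector of melting temperatures in Celsius
#' @export
#' @examples
#' primerTm("AGCGTACGTTAGCCTAGGAT")
primerTm <- function(seq, oligoConc = 50e-9, naConc = 0.05) {
  vapply(seq, primerTm1, 0.0,
         oligoConc = oligoConc, naConc = naConc, USE.NAMES = FALSE)
}

# dH in kcal/mol, dS in cal/(mol K); propagation keys are 5'->3' top-strand
# dinucleotides, complements filled in by symmetry.
.nnDH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nnDS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

primerTm1 <- function(seq, oligoConc, naConc) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) return(NA_real_)
  n <- nchar(seq)
  if (n < 2L) return(NA_real_)
  ch <- strsplit(seq, "")[[1]]
  steps <- paste0(ch[-n], ch[-1])
  dH <- sum(.nnDH[steps])
  dS <- sum(.nnDS[steps])
  for (end in c(ch[1], ch[n])) {
    if (end %in% c("G", "C")) {
      dH <- dH + 0.1; dS <- dS - 2.8
    } else {
      dH <- dH + 2.3; dS <- dS + 4.1
    }
  }
  dSsalt <- dS + 0.368 * (n - 1) * log(naConc)
  1000 * dH / (dSsalt + 1.987 * log(oligoConc / 4)) - 273.15
}
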