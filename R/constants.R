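# Shared constant tables: canonical residues, monoisotopic masses, human
# proteome-like background frequencies, and a hydropathy propensity scale.

#' Canonical amino-acid alphabet
#'
#' The 20 proteinogenic one-letter codes, in alphabetical order. Sequences
#' containing any other character are flagged non-scorable throughout the
#' package.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Monoisotopic residue masses (Da); water and proton added where needed.
AA_MONO_MASS <- c(
  A = 71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G = 57.021464, H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P = 97.052764, Q = 128.058578, R = 156.101111, S = 87.032028,
  T = 101.047679, V = 99.068414, W = 186.079313, Y = 163.063329
)

MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276466
MASS_OXIDATION <- 15.994915

#' Background amino-acid frequencies
#'
#' Approximate residue frequencies of the human proteome, normalized to sum
#' to one. Used as the default background for the stand-in binding predictor
#' and the synthetic sequence generator.
#'
#' @return Named numeric vector over [amino_acids()], summing to 1.
#' @export
aa_background_freqs <- function() {
  f <- c(
    A = 0.0702, C = 0.0230, D = 0.0473, E = 0.0710, F = 0.0365,
    G = 0.0657, H = 0.0263, I = 0.0433, K = 0.0573, L = 0.0996,
    M = 0.0213, N = 0.0359, P = 0.0631, Q = 0.0477, R = 0.0564,
    S = 0.0833, T = 0.0536, V = 0.0597, W = 0.0122, Y = 0.0266
  )
  f / sum(f)
}

#' Default residue propensity scale for the immunogenicity stand-in
#'
#' Kyte-Doolittle hydropathy values, centered so the vector sums to zero.
#' Hydrophobic/aromatic residues score positive, polar/charged negative; the
#' centered scale keeps the stand-in's decision boundary at zero.
#'
#' @return Named numeric vector over [amino_acids()], summing to 0.
#' @export
default_propensities <- function() {
  kd <- c(
    A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
    G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
    M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
  )
  kd - mean(kd)
}

# Frequent affinity-purification contaminants (keratins, serum proteins,
# proteases) used as the bundled default contaminant accession list.
BUNDLED_CONTAMINANTS <- c(
  "P04264", "P35908", "P13645", "P35527", "P02533", "P08779", "P04259",
  "P02538", "P19013", "Q15323", "P00761", "P07477", "P02768", "P00883"
)

#' Bundled contaminant accessions
#'
#' A short list of protein accessions recurrently observed in
#' affinity-purification controls (keratins, albumin, trypsin). Used as the
#' default contaminant list by the synthetic generator and available as a
#' fallback for decontamination when no CRAPome-style table is supplied.
#'
#' @return Character vector of UniProt accessions.
#' @export
bundled_contaminants <- function() BUNDLED_CONTAMINANTS
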