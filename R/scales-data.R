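#' Hydropathy scales and residue constants
#'
#' Per-residue hydropathy score tables used by [hydropathy_profile()].
#' `"miyazawa"` is the Miyazawa-Jernigan (1985) contact-energy derived
#' hydrophobicity scale; `"kyte_doolittle"` is the Kyte & Doolittle (1982)
#' hydropathy index. Both cover the 20 standard one-letter codes.
#'
#' @param name Scale name, one of `"miyazawa"` or `"kyte_doolittle"`.
#' @return Named numeric vector of length 20 (names are one-letter residue
#'   codes).
#' @examples
#' hydropathy_scale("miyazawa")[["W"]]
#' @export
hydropathy_scale <- function(name = c("miyazawa", "kyte_doolittle")) {
  name <- match.arg(name)
  .hydropathy_scales[[name]]
}

.hydropathy_scales <- list(
  # Miyazawa & Jernigan (1985), hydrophobicity from inter-residue contact
  # energies (ProtScale parameterization).
  miyazawa = c(
    A = 5.33, R = 4.18, N = 3.71, D = 3.59, C = 7.93,
    Q = 3.87, E = 3.65, G = 4.48, H = 5.10, I = 8.83,
    L = 8.47, K = 2.95, M = 8.95, F = 9.03, P = 3.87,
    S = 4.09, T = 4.49, W = 7.66, Y = 5.89, V = 7.63
  ),
  # Kyte & Doolittle (1982) hydropathy index.
  kyte_doolittle = c(
    A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
  )
)

# Average (not monoisotopic) residue masses in Da; peptide mass = sum +
# one water.
.residue_avg_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.water_avg_mass <- 18.0153
.proton_mass <- 1.007276

# Formal side-chain charges at neutral pH, used by the disorder proxy.
.residue_charge <- c(D = -1, E = -1, K = 1, R = 1)

#' Default hydrophobic residue set
#'
#' The bulky hydrophobic one-letter codes \{A, C, F, I, L, M, V, W\} used as
#' the default classification in [hydrophobic_fraction()]. Under this set the
#' coreMYC peptide (c-MYC residues 101-150) is exactly 50 percent
#' hydrophobic (25 of 50 residues).
#'
#' @return Character vector of one-letter codes.
#' @export
hydrophobic_residues <- function() c("A", "C", "F", "I", "L", "M", "V", "W")

#' The coreMYC peptide sequence
#'
#' c-MYC residues 101-150, the conformational-switch epitope containing MYC
#' Box II. The sequence is the mature peptide of the MGHis6-coreMYC
#' expression construct (without the N-terminal MGHHHHHH tag).
#'
#' @param tagged If `TRUE`, return the full MGHis6-coreMYC construct
#'   sequence (58 residues) instead of the bare 50-residue epitope.
#' @return A [protein_sequence] object.
#' @examples
#' hydrophobic_fraction(coremyc_sequence())
#' @export
coremyc_sequence <- function(tagged = FALSE) {
  core <- "MVTELLGGDMVNQSFICDPDDETFIKNIIIQDCMWSGFSAAAKLVSEKLA"
  if (tagged) {
    protein_sequence(paste0("MGHHHHHH", core), id = "MGHis6-coreMYC")
  } else {
    protein_sequence(core, id = "coreMYC", offset = 101L)
  }
}

#' The TRRAP 2038-2087 peptide sequence
#'
#' The 50-residue TRRAP-derived peptide that forms a 1:1 complex with
#' coreMYC. As synthesized it is N-terminally acetylated and C-terminally
#' amidated; pass `nterm = "acetyl"`, `cterm = "amide"` to
#' [peptide_average_mass()] to reproduce that species.
#'
#' @return A [protein_sequence] object.
#' @export
trrap_sequence <- function() {
  protein_sequence("GVNSVSSSIKRGLSVDSAQEVKRFRTATGAISAVFGRSQSLPGADSLLAK",
    id = "TRRAP_2038-2087", offset = 2038L
  )
}

#' Synthetic 439-residue c-MYC-like scaffold
#'
#' A synthetic stand-in for the full-length 439-residue c-MYC sequence used
#' in tiling and screening examples. Positions 101-150 carry the real,
#' published coreMYC sequence; the remainder is a deterministic
#' low-hydrophobicity filler with IDP-like composition (S/P/Q/E/K/T/D/N/A/G
#' repeats). It reproduces the published tile inventory (which depends only
#' on the length, 439) but is not the real c-MYC sequence outside 101-150.
#'
#' @return A [protein_sequence] object of length 439, id
#'   `"MYC_scaffold_synthetic"`.
#' @export
myc_scaffold_synthetic <- function() {
  filler <- function(n) {
    pool <- c("S", "P", "Q", "E", "K", "T", "D", "N", "A", "G")
    paste(rep_len(pool, n), collapse = "")
  }
  core <- paste(residues(coremyc_sequence()), collapse = "")
  protein_sequence(paste0(filler(100), core, filler(289)),
    id = "MYC_scaffold_synthetic"
  )
}
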