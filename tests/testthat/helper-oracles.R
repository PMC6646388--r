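# Independent oracles, written against the definitions rather than the
# package implementation.

# Regex-based tryptic cleavage: split on the PCRE boundary, then join
# consecutive fragments for missed-cleavage products.
oracle_digest <- function(sequence, missed_cleavages = 0L,
                          proline_rule = TRUE) {
  pat <- if (proline_rule) "(?<=[KR])(?!P)" else "(?<=[KR])"
  pieces <- strsplit(sequence, pat, perl = TRUE)[[1]]
  out <- character(0)
  for (i in seq_along(pieces)) {
    for (j in i:min(length(pieces), i + missed_cleavages)) {
      out <- c(out, paste(pieces[i:j], collapse = ""))
    }
  }
  out
}

# Independently typed monoisotopic residue table (standard published
# values) used only for oracle summation.
ORACLE_RESIDUE <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276
ORACLE_CAM <- 57.02146

oracle_mass <- function(peptide, carbamidomethyl = TRUE) {
  chars <- strsplit(peptide, "")[[1]]
  m <- sum(ORACLE_RESIDUE[chars]) + ORACLE_WATER
  if (carbamidomethyl) m <- m + ORACLE_CAM * sum(chars == "C")
  unname(m)
}

oracle_y_mz <- function(peptide, index, carbamidomethyl = TRUE) {
  frag <- substring(peptide, nchar(peptide) - index + 1L, nchar(peptide))
  oracle_mass(frag, carbamidomethyl) + ORACLE_PROTON
}

# Textbook Pearson correlation from the sum formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

random_protein_seq <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# The 16 peptide sequences of the published biomarker panel.
PANEL_PEPTIDES <- c(
  "ALGIVYLDSQAR", "YFGASSVGAIK", "STVAATPVFNSFFR", "DGVITIEESR",
  "TTLTAAITR", "ELTSLGLK", "GTELISVDCR", "SELEVISSLFSR", "SELEVISSLLSR",
  "TDNNTNYSYINAIK", "TDTNDYSYVNAIK", "LEGDEATGVSIVR", "NSFPGDEIPIVR",
  "GSAGEYPVICTTVR", "ILDTAEPGDAVGLLLR", "AGIIDVPATADDATK")
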