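# Physical constants: Se isotopes, amino acid residue masses, modifications.

# Selenium isotope masses (u) and natural isotopic abundances.
# CIAAW/IUPAC isotopic compositions of the elements; standard atomic
# weight of selenium 78.971.
.se_isotopes <- data.frame(
  isotope   = c(74L, 76L, 77L, 78L, 80L, 82L),
  mass      = c(73.922476, 75.919214, 76.919914, 77.917309,
                79.916522, 81.916700),
  abundance = c(0.0089, 0.0937, 0.0763, 0.2377, 0.4961, 0.0873)
)

.se_atomic_weight <- 78.971

.proton_mass <- 1.00727646688
.water_mono  <- 18.0105646863
.water_avg   <- 18.01528

#' Selenium isotope table
#'
#' Isotope masses (u) and natural abundances of the six stable selenium
#' isotopes, as bundled with the package (CIAAW/IUPAC values). The five
#' isotopes monitored by the ICP-QQQ method (74, 76, 77, 78, 80) are a
#' subset; 82Se is carried so abundance vectors sum to one.
#'
#' @return A data.frame with columns `isotope`, `mass`, `abundance`.
#' @export
#' @examples
#' se_isotopes()
se_isotopes <- function() .se_isotopes

# Monoisotopic residue masses (Da) of the 20 standard amino acids plus
# selenocysteine (U). Standard values as used throughout proteomics
# (e.g. the Unimod/ExPASy tables); residue = amino acid minus water.
.aa_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931, U = 150.95364
)

# Average residue masses (Da); conventional values.
.aa_avg <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594,
  N = 114.1038, D = 115.0886, Q = 128.1307, K = 128.1741,
  E = 129.1155, M = 131.1926, H = 137.1411, F = 147.1766,
  R = 156.1875, Y = 163.1760, W = 186.2132, U = 150.0500
)

# Bundled modifications. Deltas in Da; `target` is the residue the
# modification applies to.
#  - carbamidomethyl: iodoacetamide alkylation of cysteine, +C2H3NO.
#  - sec_to_dha: selenocysteine degraded to dehydroalanine, loss of
#    H2Se (the Se tag is lost from the peptide).
.modifications <- data.frame(
  name   = c("carbamidomethyl", "sec_to_dha"),
  target = c("C", "U"),
  mono   = c(57.02146, -81.93217),
  avg    = c(57.0513, -80.9868),
  stringsAsFactors = FALSE
)

#' Bundled peptide modifications
#'
#' Mass deltas for the two modifications relevant to selenoprotein
#' tryptic digests: fixed carbamidomethylation of cysteine
#' (iodoacetamide, +57.02146 Da monoisotopic) and the degradation of
#' selenocysteine to dehydroalanine (loss of H2Se, -81.93217 Da).
#' Additional modifications can be supplied to [peptide_mass()] via its
#' `custom` argument.
#'
#' @return A data.frame with columns `name`, `target`, `mono`, `avg`.
#' @export
modifications <- function() .modifications

# Canonical species labels in elution order.
.species_levels <- c("GPx", "SMT", "SELENOP", "SELENOW_plus_others", "SeAlb")
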