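# Physical constants and embedded reference geometry.

#' Gas constant in kcal mol^-1 K^-1
#'
#' Used throughout for Boltzmann factors and thermal-energy thresholds.
#' @export
R_KCAL <- 0.0019872041

#' Thermal energy RT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return RT in kcal/mol.
#' @export
rt_kcal <- function(temperature = 300) R_KCAL * temperature

# Standard reference-base coordinates (Angstrom) in the standard (Tsukuba
# convention) base reference frame: origin at the pair center, x toward the
# major groove, y along the pseudo-dyad toward the attached strand, z along
# the helix normal.  An ideal Watson-Crick pair is obtained by placing the
# complementary base with its frame rotated 180 degrees about x.
# Ring/exocyclic heavy atoms plus C1' for each deoxynucleotide.
.STD_BASE <- list(
  A = rbind(
    `C1'` = c(-2.479, 5.346, 0.000),
    N9    = c(-1.291, 4.498, 0.000),
    C8    = c( 0.024, 4.897, 0.000),
    N7    = c( 0.877, 3.902, 0.000),
    C5    = c( 0.071, 2.771, 0.000),
    C6    = c( 0.369, 1.398, 0.000),
    N6    = c( 1.611, 0.909, 0.000),
    N1    = c(-0.668, 0.532, 0.000),
    C2    = c(-1.912, 1.023, 0.000),
    N3    = c(-2.320, 2.290, 0.000),
    C4    = c(-1.267, 3.124, 0.000)
  ),
  C = rbind(
    `C1'` = c(-2.477, 5.402, 0.000),
    N1    = c(-1.285, 4.542, 0.000),
    C2    = c(-1.472, 3.158, 0.000),
    O2    = c(-2.628, 2.709, 0.000),
    N3    = c(-0.391, 2.344, 0.000),
    C4    = c( 0.837, 2.868, 0.000),
    N4    = c( 1.875, 2.027, 0.000),
    C5    = c( 1.056, 4.275, 0.000),
    C6    = c(-0.023, 5.068, 0.000)
  ),
  G = rbind(
    `C1'` = c(-2.477, 5.399, 0.000),
    N9    = c(-1.289, 4.551, 0.000),
    C8    = c( 0.023, 4.962, 0.000),
    N7    = c( 0.870, 3.969, 0.000),
    C5    = c( 0.071, 2.833, 0.000),
    C6    = c( 0.424, 1.460, 0.000),
    O6    = c( 1.554, 0.955, 0.000),
    N1    = c(-0.700, 0.641, 0.000),
    C2    = c(-1.999, 1.087, 0.000),
    N2    = c(-2.949, 0.139, -0.001),
    N3    = c(-2.342, 2.364, 0.001),
    C4    = c(-1.265, 3.177, 0.000)
  ),
  T = rbind(
    `C1'` = c(-2.481, 5.354, 0.000),
    N1    = c(-1.284, 4.500, 0.000),
    C2    = c(-1.462, 3.135, 0.000),
    O2    = c(-2.562, 2.608, 0.000),
    N3    = c(-0.298, 2.407, 0.000),
    C4    = c( 1.005, 2.897, 0.000),
    O4    = c( 1.935, 2.097, -0.001),
    C5    = c( 1.056, 4.338, 0.000),
    C7    = c( 2.466, 4.961, 0.001),
    C6    = c(-0.024, 5.057, 0.000)
  )
)

# Ring atoms used for the least-squares frame fit.
.RING_ATOMS <- list(
  A = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
  G = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.PURINES <- c("A", "G")

# Atomic masses (u) for center-of-mass calculations.
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973762)

# Watson-Crick complement.
.WC_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

# Hydrogen-bond donor / acceptor heavy atoms per base (amino/imino donors,
# carbonyl and ring-nitrogen acceptors).
.HB_ROLES <- list(
  A = list(donors = "N6",            acceptors = c("N1", "N3", "N7")),
  C = list(donors = "N4",            acceptors = c("O2", "N3")),
  G = list(donors = c("N1", "N2"),   acceptors = c("O6", "N3", "N7")),
  T = list(donors = "N3",            acceptors = c("O2", "O4"))
)

# Sugar-phosphate backbone heavy-atom names (default RMSD target selection).
.BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'",
                     "C2'", "C1'", "O4'")

#' Normalize a nucleotide residue name to a one-letter base code
#'
#' Accepts both PDB deoxynucleotide dialects (DA/DC/DG/DT) and bare letters.
#'
#' @param residue_name Character vector of residue names.
#' @return Character vector over "A", "C", "G", "T".
#' @export
base_code <- function(residue_name) {
  x <- toupper(sub("^D", "", as.character(residue_name)))
  bad <- !(x %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop("unknown nucleotide residue name(s): ",
         paste(unique(residue_name[bad]), collapse = ", "))
  }
  x
}

#' Standard reference coordinates of a base
#'
#' Returns the embedded standard-frame heavy-atom coordinates of one of the
#' four deoxynucleobases (plus C1').
#'
#' @param base One of "A", "C", "G", "T" (or DA/DC/DG/DT).
#' @return Matrix with one named row per atom, columns x, y, z (Angstrom).
#' @export
standard_base_coords <- function(base) {
  .STD_BASE[[base_code(base)]]
}

.element_from_name <- function(name) {
  # First alphabetic character of a PDB atom name identifies the element for
  # the organic H/C/N/O/P set used here.
  el <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", name)), 1, 1))
  el
}
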