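## Physical constants and unit conversions used throughout.

#' Unit conversion constants
#'
#' `ANG_PER_BOHR` converts bohr to angstrom; `COULOMB_KCAL` is the Coulomb
#' constant in kcal mol^-1 A e^-2 (practical units used by the PB solver).
#' Potentials are reported in atomic units (hartree/e) by the MEP module and
#' in kcal/mol/e internally by the PB module.
#'
#' @name units
#' @keywords internal
NULL

ANG_PER_BOHR <- 1.8897259886   # 1 Angstrom = 1.8897259886 bohr
COULOMB_KCAL <- 332.06         # kcal * Angstrom / (mol * e^2)

# Recognized element symbols for protein atoms
.ELEMENTS <- c("H", "C", "N", "O", "S")

# default van der Waals radii by element (Amber-like), Angstrom
.DEFAULT_VDW <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# standard link-atom bond lengths by donor element, Angstrom
.LINK_BOND <- c(C = 1.090, N = 1.010)
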