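# Element mass constants embedded so that mass arithmetic is reproducible
# independent of any chemistry toolkit version.
#
# Monoisotopic masses are the masses of the most abundant isotope
# (CODATA/AME2020, u); standard atomic weights follow the IUPAC 2021
# abridged values (conventional value for elements with an interval).

.MONOISOTOPIC <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  Na = 22.9897692809,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Br = 78.9183371,
  I  = 126.904473
)

.STANDARD_WEIGHT <- c(
  H  = 1.008,
  C  = 12.011,
  N  = 14.007,
  O  = 15.999,
  F  = 18.998403163,
  Na = 22.98976928,
  P  = 30.973761998,
  S  = 32.06,
  Cl = 35.45,
  K  = 39.0983,
  Br = 79.904,
  I  = 126.90447
)

# mass of the electron in u; only used when ion arithmetic is asked to
# account for the charge carrier explicitly
.ELECTRON_MASS <- 0.000548579909

#' Elements with embedded mass constants
#'
#' @return Character vector of element symbols for which both a
#'   monoisotopic mass and a standard atomic weight are embedded.
#' @export
supported_elements <- function() names(.MONOISOTOPIC)
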