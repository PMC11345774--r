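# Element data used throughout: standard atomic masses, Bondi van der Waals
# radii, and default valences for implicit-hydrogen bookkeeping.

.ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453,
  Br = 79.904, I = 126.904
)

# Bondi (1964) radii in Angstrom; used for the Gaussian shape model.
.VDW_RADIUS <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
  F = 1.47, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
  Br = 1.85, I = 1.98
)

# Default valences for neutral atoms (organic subset).
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
  Si = 4, P = 3, S = 2, Cl = 1, Br = 1, I = 1
)

.HALOGENS <- c("F", "Cl", "Br", "I")

atomic_mass <- function(element) {
  m <- .ATOMIC_MASS[element]
  if (anyNA(m)) stop("unknown element(s): ", paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

vdw_radius <- function(element) {
  r <- .VDW_RADIUS[element]
  if (anyNA(r)) stop("no van der Waals radius for element(s): ",
                     paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

# Implicit hydrogen count for one atom given its element, formal charge and
# the sum of its explicit bond orders (aromatic bonds counted as 1.5).
implicit_h_count <- function(element, charge, bond_order_sum) {
  v <- .DEFAULT_VALENCE[element]
  v[is.na(v)] <- 0
  # charge adjustment: N+ has valence 4, O- has 1, N- has 2, C- has 3, S+ 3 ...
  v <- v + ifelse(element %in% c("N", "P", "S", "O"), charge,
                  ifelse(element %in% c("C", "B"), -abs(charge), 0))
  h <- v - ceiling(bond_order_sum)
  as.integer(pmax(0, round(h)))
}
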