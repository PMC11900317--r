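# Element data for the restricted organic chemistry space handled by the
# package: the allowed-element list used during curation plus a handful of
# extras (Na, K, Ca, Mg, As, ...) that may appear in raw inputs as
# counter-ions or disallowed elements and must still parse.

.kp_elements <- local({
  tab <- data.frame(
    symbol = c("H", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P", "S",
               "Cl", "K", "Ca", "As", "Se", "Br", "I", "Li", "Zn", "Fe"),
    number = c(1, 5, 6, 7, 8, 9, 11, 12, 14, 15, 16,
               17, 19, 20, 33, 34, 35, 53, 3, 30, 26),
    mass = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
             28.086, 30.974, 32.06, 35.45, 39.098, 40.078, 74.922, 78.971,
             79.904, 126.904, 6.94, 65.38, 55.845),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$symbol
  tab
})

# Elements permitted in curated structures (dataset construction rule).
.kp_allowed_elements <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                          "Cl", "Se", "Br", "I")

# SMILES organic subset: atoms writable without brackets.
.kp_organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# Elements that may carry the aromatic (lowercase) flag.
.kp_aromatic_ok <- c("B", "C", "N", "O", "P", "S", "Se")

.kp_atomic_number <- function(symbol) {
  n <- .kp_elements[symbol, "number"]
  if (any(is.na(n))) stop("unknown element: ",
                          paste(symbol[is.na(n)], collapse = ", "))
  n
}

.kp_atomic_mass <- function(symbol) .kp_elements[symbol, "mass"]

# Base valence alternatives per element (neutral form); charge shifts are
# applied in .kp_allowed_valences().
.kp_base_valence <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L,
  Se = c(2L, 4L, 6L), Br = 1L, I = 1L
)

# Valence alternatives for an element with a formal charge.  Pragmatic rules
# covering the charge states seen in drug-like structures: N/O/P/S shift with
# the charge sign (e.g. N+ -> 4, O- -> 1), C and B lose a bonding slot in
# either ionic direction except borate-like B- (4).
.kp_allowed_valences <- function(symbol, charge = 0L) {
  base <- .kp_base_valence[[symbol]]
  if (is.null(base)) return(integer(0))
  if (charge == 0L) return(base)
  v <- switch(symbol,
    N = , O = , P = , S = , Se = base + charge,
    C = base - abs(charge),
    B = base - charge,
    base
  )
  v[v >= 0L]
}
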