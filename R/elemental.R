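#' Elemental CHN composition of a dried plant sample
#'
#' @param pct_c,pct_h,pct_n mass percent carbon, hydrogen, nitrogen, each in
#'   `[0, 100]`, summing to at most 100.
#' @return an object of class `elemental_composition`.
#' @examples
#' flower <- elemental_composition(43.75, 6.32, 3.37)
#' elemental_ratios(flower)
#' @export
elemental_composition <- function(pct_c, pct_h, pct_n) {
  for (p in list(pct_c, pct_h, pct_n)) check_scalar(p, "mass percent")
  if (any(c(pct_c, pct_h, pct_n) < 0) || any(c(pct_c, pct_h, pct_n) > 100))
    stop_radkin("mass percents must lie in [0, 100]", "radkin_validation_error")
  if (pct_c + pct_h + pct_n > 100 + 1e-9)
    stop_radkin("mass percents must sum to <= 100", "radkin_validation_error")
  structure(list(pct_c = pct_c, pct_h = pct_h, pct_n = pct_n),
            class = "elemental_composition")
}

# IUPAC standard atomic weights
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007)

#' Hydrogen-to-carbon and nitrogen-to-carbon ratios
#'
#' Returns both the mass-basis ratios (direct quotients of the mass
#' percents) and the molar-basis ratios (each percent divided by the atomic
#' mass first). Mass basis is the default reporting convention here since
#' the inputs are mass percents.
#'
#' @param comp an [elemental_composition()] with `pct_c > 0`.
#' @return list with components `mass` and `molar`, each a named vector
#'   `c(h_over_c =, n_over_c =)`.
#' @export
elemental_ratios <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  if (comp$pct_c <= 0)
    stop_radkin("pct_c must be > 0 to form ratios",
                "radkin_invalid_composition_error")
  mass <- c(h_over_c = comp$pct_h / comp$pct_c,
            n_over_c = comp$pct_n / comp$pct_c)
  mol_c <- comp$pct_c / .atomic_mass[["C"]]
  molar <- c(h_over_c = (comp$pct_h / .atomic_mass[["H"]]) / mol_c,
             n_over_c = (comp$pct_n / .atomic_mass[["N"]]) / mol_c)
  list(mass = mass, molar = molar)
}
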