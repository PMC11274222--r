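#' Dilution-scheme specification for one assayed sample
#'
#' Encodes one row of the assay's dilution scheme: a starting infusion
#' (1 g dried flower or fruit brewed in 100 mL water) diluted with water to
#' 10 mL total, of which a 0.5 mL aliquot is mixed with 3.0 mL of radical
#' solution. The four dilution levels are 1.0, 1.5, 2.0 and 2.5 x 10^-3
#' g/mL, corresponding to 1.0-2.5 mL infusion topped up to 10 mL.
#'
#' @param source `"FLOWER"` or `"FRUIT"` (acronym prefix K or O).
#' @param dilution_level one of `1.0e-3`, `1.5e-3`, `2.0e-3`, `2.5e-3`
#'   (g/mL).
#' @param infusion_volume_ml,water_volume_ml mL of infusion and water making
#'   the 10 mL dilution; defaults follow the dilution level.
#' @param radical_solution_ml mL of radical solution (fixed at 3.0).
#' @param aliquot_ml mL of dilution added to the radical solution (fixed at
#'   0.5).
#' @return an object of class `sample_spec`.
#' @examples
#' sample_spec("FLOWER", 1.0e-3)
#' @export
sample_spec <- function(source = c("FLOWER", "FRUIT"),
                        dilution_level,
                        infusion_volume_ml = dilution_level * 1e3,
                        water_volume_ml = 10 - infusion_volume_ml,
                        radical_solution_ml = 3.0,
                        aliquot_ml = 0.5) {
  source <- match.arg(source)
  levels <- c(1.0e-3, 1.5e-3, 2.0e-3, 2.5e-3)
  if (!isTRUE(any(abs(dilution_level - levels) < 1e-12)))
    stop_radkin("dilution_level must be one of {1.0, 1.5, 2.0, 2.5} x 10^-3 g/mL",
                "radkin_validation_error")
  if (abs(infusion_volume_ml + water_volume_ml - 10.0) > 1e-9)
    stop_radkin("infusion + water volumes must total 10 mL",
                "radkin_validation_error")
  if (abs(infusion_volume_ml - dilution_level * 1e3) > 1e-9)
    stop_radkin("infusion volume must match the dilution level (1 mL per 1e-3 g/mL)",
                "radkin_validation_error")
  if (radical_solution_ml != 3.0 || aliquot_ml != 0.5)
    stop_radkin("assay fixes 0.5 mL aliquot + 3.0 mL radical solution",
                "radkin_validation_error")
  structure(list(source = source, dilution_level = dilution_level,
                 infusion_volume_ml = infusion_volume_ml,
                 water_volume_ml = water_volume_ml,
                 radical_solution_ml = radical_solution_ml,
                 aliquot_ml = aliquot_ml),
            class = "sample_spec")
}

#' Sample acronym in the assay's naming convention
#'
#' Flower samples are prefixed `K`, fruit samples `O`; the radical token is
#' `DPPH` or `GL`; the suffix is the dilution level in 10^-3 g/mL, e.g.
#' `KDPPH1.0`, `OGL2.5`.
#'
#' @param spec a [sample_spec()].
#' @param radical `"DPPH"` or `"GLV"`.
#' @return character acronym.
#' @export
sample_acronym <- function(spec, radical = c("DPPH", "GLV")) {
  stopifnot(inherits(spec, "sample_spec"))
  radical <- match.arg(radical)
  prefix <- if (spec$source == "FLOWER") "K" else "O"
  paste0(prefix, radical_constants(radical)$acronym,
         sprintf("%.1f", spec$dilution_level * 1e3))
}
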