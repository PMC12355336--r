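#' Reference cohort: 12 Czech pilot farms
#'
#' Published characteristics of the 12-farm Czech pilot cohort (reporting
#' year 2022) used throughout the examples and tests: turnover (thousand
#' EUR), farm area (ha), employees and main production for sale, together
#' with each farm's share of animal husbandry (SoAH) as reported, rounded
#' to 2 decimals. The farms span roughly three orders of magnitude in every
#' size variable and SoAH values from 0 (pure crop farms) to 0.80.
#'
#' @return A list with two tibbles: `characteristics` (farm, turnover_keur,
#'   area_ha, employees, production) and `soah` (farm, soah).
#' @examples
#' reference_cohort()$soah
#' @export
reference_cohort <- function() {
  characteristics <- tibble::tibble(
    farm = 1:12,
    turnover_keur = c(24.4, 577.4, 724.6, 958.9, 1834.7, 3256.7, 4463.7,
                      4694.5, 6839.0, 8859.2, 9191.7, 33368.7),
    area_ha = c(24, 356, 378, 176, 1673, 1295, 1208, 1391, 1844, 2252,
                3528, 5024),
    employees = c(1, 9, 5, 12, 28, 9, 21, 22, 55, 66, 58, 156),
    production = c(
      "Fruit, mutton meat", "Cow milk", "Cereals, pork meat", "Grapes",
      "Cereals, cow milk", "Cereals, soya, rapeseed, sugar beet",
      "Cereals, rapeseed, hop, cow milk",
      "Cereals, sunflower seed, beef meat, cow milk",
      "Cereals, rapeseed, poppy seed, beef meat, cow milk",
      "Cereals, rapeseed, poppy seed, beef meat, cow milk",
      "Cereals, rapeseed, beef meat, cow milk",
      "Cereals, rapeseed, poppy seed, vegetables, beef meat, pork meat")
  )
  soah <- tibble::tibble(
    farm = 1:12,
    soah = c(0.46, 0.77, 0.20, 0, 0.80, 0, 0.38, 0.45, 0.37, 0.47, 0.54,
             0.39)
  )
  list(characteristics = characteristics, soah = soah)
}
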