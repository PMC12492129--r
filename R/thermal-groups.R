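# Thermal-group classification and native simulation temperatures

THERMAL_GROUPS <- c("psychrophile", "mesophile", "thermophile", "hyperthermophile")

# Kelvin at which each group's structures are simulated ("native" temperature)
NATIVE_TEMPERATURE_K <- c(
  psychrophile = 280, mesophile = 300, thermophile = 330, hyperthermophile = 355
)

#' Classify a species by optimal growth temperature
#'
#' Groups follow the standard prokaryotic convention: psychrophiles up to
#' 20 degC, mesophiles in (20, 40], thermophiles in (40, 80], and
#' hyperthermophiles above 80 degC. Boundary values go to the colder group.
#'
#' @param ogt Optimal growth temperature(s), degrees Celsius; must lie in
#'   (-20, 130) as a sanity bound. Vectorised.
#' @return Character vector of thermal groups.
#' @export
classify_thermal_group <- function(ogt) {
  if (any(!is.finite(ogt))) abort("ogt must be finite")
  if (any(ogt <= -20 | ogt >= 130)) {
    abort(sprintf(
      "ogt out of sane bounds (-20, 130) degC: %s",
      paste(ogt[ogt <= -20 | ogt >= 130], collapse = ", ")
    ))
  }
  out <- cut(
    ogt,
    breaks = c(-Inf, 20, 40, 80, Inf),
    labels = THERMAL_GROUPS,
    right = TRUE
  )
  as.character(out)
}

#' Native simulation temperature for a thermal group
#'
#' Each thermal group is simulated at one fixed temperature: 280 K
#' (psychrophiles), 300 K (mesophiles), 330 K (thermophiles), 355 K
#' (hyperthermophiles).
#'
#' @param thermal_group Character vector of group names.
#' @return Numeric vector, Kelvin.
#' @export
native_temperature <- function(thermal_group) {
  bad <- setdiff(unique(thermal_group), THERMAL_GROUPS)
  if (length(bad) > 0) abort(paste0("unknown thermal group(s): ", paste(bad, collapse = ", ")))
  unname(NATIVE_TEMPERATURE_K[thermal_group])
}

#' Convert Kelvin to degrees Celsius
#' @param kelvin Temperature(s) in Kelvin.
#' @return degrees Celsius.
#' @export
kelvin_to_celsius <- function(kelvin) kelvin - 273.15

#' Convert degrees Celsius to Kelvin
#' @param celsius Temperature(s) in degrees Celsius.
#' @return Kelvin.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15
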